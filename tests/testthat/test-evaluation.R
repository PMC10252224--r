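test_that("the scaled error metric equals the mm-frame distance", {
  expect_equal(landmarkErrorMm(c(0.01, 0, 0) + c(0.2, 0.2, 0.2),
                               c(0.2, 0.2, 0.2), 100), 1.0)
  expect_equal(landmarkErrorMm(c(1, 2, 3), c(1, 2, 3), 50), 0)
  expect_error(landmarkErrorMm(c(0, 0, 0), c(1, 1, 1), -2), "positive")
  # dual-path oracle: normalized-frame metric vs plain mm distance
  set.seed(40)
  p <- matrix(rnorm(300, sd = 40), 100, 3)
  nc <- normalizeCloud(p)
  tr <- normTransform(nc)
  a <- matrix(runif(30, -1, 1), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.05), 10, 3)
  viaMetric <- landmarkErrorMm(a, b, tr@scale)
  viaMm <- sqrt(rowSums((toMm(a, tr) - toMm(b, tr))^2))
  expect_equal(viaMetric, viaMm, tolerance = 1e-9)
})

test_that("summaries report per-landmark, overall and coverage statistics", {
  tab <- data.frame(face_id = "f1", landmark = "Pronasale", organ = "nose",
                    laterality = "midline", error_mm = 2.0)
  s <- summarizeErrors(tab)
  expect_equal(s$overall$mean, 2.0)
  expect_equal(s$overall$sd, 0)
  # coverage counts landmark means against the threshold
  tab2 <- rbind(
    data.frame(face_id = "f1", landmark = "Pronasale", organ = "nose",
               laterality = "midline", error_mm = 2.4),
    data.frame(face_id = "f1", landmark = "Menton", organ = "chin",
               laterality = "midline", error_mm = 2.6))
  s2 <- summarizeErrors(tab2, thresholds = 2.5)
  expect_equal(s2$coverage$frac_landmark_means_within, 0.5)
  expect_error(summarizeErrors(tab[0, ]), "empty")
})

test_that("overall mean and sd match a flat-loop oracle with sample sd", {
  set.seed(41)
  tab <- data.frame(face_id = rep(sprintf("f%d", 1:5), each = 32),
                    landmark = rep(landmarkRegistry()$name, 5),
                    organ = rep(landmarkRegistry()$organ, 5),
                    laterality = rep(landmarkRegistry()$laterality, 5),
                    error_mm = rexp(160, rate = 0.5))
  s <- summarizeErrors(tab)
  tot <- 0
  for (i in seq_len(nrow(tab))) tot <- tot + tab$error_mm[i]
  mu <- tot / nrow(tab)
  ss <- 0
  for (i in seq_len(nrow(tab))) ss <- ss + (tab$error_mm[i] - mu)^2
  expect_equal(s$overall$mean, mu, tolerance = 1e-12)
  expect_equal(s$overall$sd, sqrt(ss / (nrow(tab) - 1)), tolerance = 1e-12)
  expect_equal(nrow(s$perLandmark), 32L)
  expect_equal(nrow(s$perOrgan), 6L)
  # Tukey quartiles per region
  nose <- tab$error_mm[tab$organ == "nose"]
  expect_equal(s$perOrgan$median[s$perOrgan$organ == "nose"],
               unname(quantile(nose, 0.5)))
})

test_that("symmetry report measures left/right mean-error gaps per pair", {
  reg <- landmarkRegistry()
  tab <- data.frame(face_id = "f1", landmark = reg$name, organ = reg$organ,
                    laterality = reg$laterality, error_mm = 1.0)
  sym <- symmetryReport(tab)
  expect_equal(nrow(sym), 10L)
  expect_true(all(sym$abs_diff_mm == 0))
  # a known asymmetric pair: means 2.12 vs 1.72 give a 0.40 mm gap
  tab$error_mm[tab$landmark == "Endocanthion_right"] <- 2.12
  tab$error_mm[tab$landmark == "Endocanthion_left"] <- 1.72
  sym2 <- symmetryReport(tab)
  expect_equal(sym2$abs_diff_mm[sym2$abbreviation == "En"], 0.40)
})

test_that("rescaling a face rescales every landmark error by the same factor", {
  # stub predictor: perturb the true landmarks by a fixed normalized offset
  f <- smallFace(seed = 21)
  offset <- c(0.01, -0.02, 0.015)
  errOf <- function(scaleFactor) {
    cl <- faceCloud(cloudPoints(f@cloud) * scaleFactor)
    lmm <- landmarkCoords(f) * scaleFactor
    nc <- normalizeCloud(cl)
    lmn <- toNormalized(lmm, normTransform(nc))
    pred <- sweep(lmn, 2, offset, "+")
    landmarkErrorMm(pred, lmn, normTransform(nc)@scale)
  }
  e1 <- errOf(1)
  e3 <- errOf(3)
  expect_equal(e3, 3 * e1, tolerance = 1e-9)
})
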