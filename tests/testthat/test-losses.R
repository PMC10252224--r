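# Independent scalar-loop oracles for every loss, written before the
# implementations were exercised; all comparisons are against these.

oracleDetection <- function(p, t, l1, l2, sizeTerm = "squared_diff") {
  tot <- 0
  for (i in 1:6) {
    ctr <- 0
    for (j in 1:3) ctr <- ctr + (p[i, j] - t[i, j])^2
    sz <- 0
    for (j in 4:6) {
      sz <- sz + if (sizeTerm == "squared_diff") (p[i, j] - t[i, j])^2
                 else abs(t[i, j]^2 - p[i, j]^2)
    }
    tot <- tot + l1 * ctr + l2 * sz
  }
  tot / 6
}

oracleMean <- function(p, t) {
  s <- 0
  for (i in seq_len(nrow(p))) s <- s + sum((p[i, ] - t[i, ])^2)
  s / nrow(p)
}

oracleMax <- function(p, t) {
  best <- 0
  for (i in seq_len(nrow(p))) best <- max(best, sum((p[i, ] - t[i, ])^2))
  best
}

test_that("detection loss matches hand arithmetic and its oracle", {
  b <- randomBoxMat()
  expect_equal(detectionLoss(b, b), 0)
  # one center displaced by (0.3, 0, 0) with equal weights: 0.5 * 0.09 / 6
  b2 <- b
  b2[3, 1] <- b2[3, 1] + 0.3
  expect_equal(detectionLoss(b2, b, 0.5, 0.5), 0.5 * 0.09 / 6)
  set.seed(30)
  for (rep in 1:40) {
    p <- randomBoxMat(); t <- randomBoxMat()
    l1 <- runif(1)
    expect_equal(detectionLoss(p, t, l1, 1 - l1),
                 oracleDetection(p, t, l1, 1 - l1), tolerance = 1e-6)
    expect_equal(detectionLoss(p, t, l1, 1 - l1, "diff_of_squares_abs"),
                 oracleDetection(p, t, l1, 1 - l1, "diff_of_squares_abs"),
                 tolerance = 1e-6)
  }
  expect_error(detectionLoss(b, b, 0.5, 0.6), "sum to 1")
})

test_that("lambda weights isolate center and size contributions", {
  b <- randomBoxMat()
  szOnly <- b; szOnly[, 4:6] <- szOnly[, 4:6] + 0.1
  ctrOnly <- b; ctrOnly[, 1:3] <- ctrOnly[, 1:3] + 0.1
  expect_equal(detectionLoss(szOnly, b, lambda1 = 1, lambda2 = 0), 0)
  expect_equal(detectionLoss(ctrOnly, b, lambda1 = 0, lambda2 = 1), 0)
  expect_gt(detectionLoss(szOnly, b, lambda1 = 0, lambda2 = 1), 0)
  expect_gt(detectionLoss(ctrOnly, b, lambda1 = 1, lambda2 = 0), 0)
})

test_that("detection loss is monotone in any single coordinate error and order-sensitive", {
  set.seed(31)
  p <- randomBoxMat(); t <- randomBoxMat()
  base <- detectionLoss(p, t, 0.4, 0.6)
  for (i in c(1, 4)) for (j in 1:6) {
    worse <- p
    worse[i, j] <- t[i, j] + 2 * (p[i, j] - t[i, j])  # double the error
    expect_gte(detectionLoss(worse, t, 0.4, 0.6), base - 1e-12)
  }
  # region order is meaningful: permuting one side changes the loss
  perm <- p[c(2:6, 1), ]
  expect_false(isTRUE(all.equal(detectionLoss(perm, t, 0.5), base)))
})

test_that("landmark losses match hand arithmetic and their oracles", {
  p <- randomCoords(2)
  t <- p
  t[1, ] <- t[1, ] + c(0.1, 0, 0)   # squared distance 0.01
  t[2, ] <- t[2, ] + c(0, 0.2, 0)   # squared distance 0.04
  expect_equal(lossMean(p, p), 0)
  expect_equal(lossMean(p, t), 0.025)
  expect_equal(lossMax(p, t), 0.04)
  expect_equal(lossCombined(p, t, 0.5), 0.5 * 0.025 + 0.5 * 0.04)
  expect_equal(lossCombined(p, t, 1, 0), lossMean(p, t))
  expect_equal(lossCombined(p, t, 0, 1), lossMax(p, t))
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(2:9, 1)
    a <- randomCoords(n); b <- randomCoords(n)
    expect_equal(lossMean(a, b), oracleMean(a, b), tolerance = 1e-9)
    expect_equal(lossMax(a, b), oracleMax(a, b), tolerance = 1e-9)
    l1 <- runif(1)
    lc <- lossCombined(a, b, l1, 1 - l1)
    expect_gte(lc, lossMean(a, b) - 1e-12)
    expect_lte(lc, lossMax(a, b) + 1e-12)
  }
  expect_error(lossMean(randomCoords(3), randomCoords(4)), "shape")
  expect_error(lossCombined(p, t, 0.7, 0.7), "sum to 1")
})

test_that("combined loss is monotone in the max-weight when max exceeds mean", {
  set.seed(33)
  a <- randomCoords(5); b <- randomCoords(5)
  ls <- sapply(seq(0, 1, by = 0.1), function(l2) lossCombined(a, b, 1 - l2, l2))
  expect_true(all(diff(ls) >= -1e-12))
})

test_that("box IoU has the right fixed points and closed-form overlap", {
  a <- c(0, 0, 0, 0.5, 0.5, 0.5)  # unit cube
  expect_equal(boxIoU(a, a), 1)
  expect_equal(boxIoU(a, c(5, 5, 5, 0.5, 0.5, 0.5)), 0)
  # shift by half an edge: overlap 0.5, union 1.5 -> 1/3
  expect_equal(boxIoU(a, c(0.5, 0, 0, 0.5, 0.5, 0.5)), 1 / 3)
  set.seed(34)
  for (rep in 1:20) {
    x <- randomBoxMat()[1, ]; y <- randomBoxMat()[2, ]
    v <- boxIoU(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, boxIoU(y, x))
  }
})
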