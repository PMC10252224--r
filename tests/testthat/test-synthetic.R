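test_that("generation is deterministic under a fixed seed", {
  f1 <- generateFace(faceParams(K = 1500, seed = 77))
  f2 <- generateFace(faceParams(K = 1500, seed = 77))
  expect_identical(cloudPoints(f1@cloud), cloudPoints(f2@cloud))
  expect_identical(landmarkCoords(f1), landmarkCoords(f2))
  f3 <- generateFace(faceParams(K = 1500, seed = 78))
  expect_false(identical(cloudPoints(f1@cloud), cloudPoints(f3@cloud)))
})

test_that("an unposed symmetric face has exactly mirrored landmark pairs", {
  f <- generateFace(faceParams(K = 1500, seed = 3, asymmetry = 0,
                               poseAngles = c(0, 0, 0)))
  lm <- landmarkCoords(f)
  pairs <- symmetricPairs()
  for (i in seq_len(nrow(pairs))) {
    l <- lm[pairs$left[i], ]
    r <- lm[pairs$right[i], ]
    expect_equal(l * c(-1, 1, 1), r, tolerance = 1e-12)
  }
  # midline landmarks sit exactly on the midsagittal plane
  mids <- landmarkRegistry()$name[landmarkRegistry()$laterality == "midline"]
  expect_true(all(abs(lm[mids, 1]) < 1e-12))
})

test_that("landmarks lie on the sampled surface when noise is zero", {
  f <- generateFace(faceParams(K = 4000, seed = 9, noiseSd = 0))
  lm <- landmarkCoords(f)
  p <- cloudPoints(f@cloud)
  spacing <- 2 * sqrt(f@params$surfaceArea / f@params$K)
  for (i in seq_len(nrow(lm))) {
    d <- sqrt(min(colSums((t(p) - lm[i, ])^2)))
    expect_lt(d, spacing)
  }
})

test_that("every region's landmarks sit strictly inside its ground-truth box", {
  for (seed in c(1, 42)) {
    f <- generateFace(faceParams(K = 1500, seed = seed))
    lmn <- toNormalized(landmarkCoords(f), f@transform)
    bm <- boxMatrix(f@boxes)
    reg <- landmarkRegistry()
    for (org in organNames()) {
      m <- lmn[reg$name[reg$organ == org], , drop = FALSE]
      ok <- abs(sweep(m, 2, bm[org, 1:3])) < rep(bm[org, 4:6], each = nrow(m))
      expect_true(all(ok))
    }
  }
})

test_that("voxelize/devoxelize moves landmarks by at most the stated grid accuracy", {
  f <- generateFace(faceParams(K = 1500, seed = 5))
  S <- f@transform@scale
  lmn <- toNormalized(landmarkCoords(f), f@transform)
  for (M in c(32, 200)) {
    idx0 <- pmin(pmax(floor((lmn + 1) / 2 * M), 0), M - 1)
    ctr <- (idx0 + 0.5) * 2 / M - 1
    expect_true(all(abs(ctr - lmn) * S <= 2 * S / M + 1e-12))
  }
})

test_that("degenerate generator parameters are rejected", {
  expect_error(faceParams(noseHeight = 60, headAxes = c(70, 95, 80)),
               "degenerate")
  expect_error(faceParams(K = 500), "at least 1000")
  expect_error(faceParams(asymmetry = 0.5), "asymmetry")
  expect_error(faceParams(noseWidth = -3), "positive")
})

test_that("dataset split follows the 7:2:1 train:test:val ratio with remainder to train", {
  ds <- tinyDataset(10, seed = 5)
  expect_length(ds$train, 7L)
  expect_length(ds$val, 1L)
  expect_length(ds$test, 2L)
  # partition: every face appears in exactly one split
  counts <- table(ds$manifest$split)
  expect_equal(as.integer(counts[c("train", "test", "val")]), c(7L, 2L, 1L))
  # 11 faces: the extra face goes to train
  ds11 <- generateDataset(11, seed = 6, baseParams = faceParams(K = 1200))
  expect_length(ds11$train, 8L)
  expect_length(ds11$test, 2L)
  expect_length(ds11$val, 1L)
})

test_that("dataset generation is reproducible and ranges are validated", {
  d1 <- generateDataset(10, seed = 123, baseParams = faceParams(K = 1200))
  d2 <- generateDataset(10, seed = 123, baseParams = faceParams(K = 1200))
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(cloudPoints(d1$train[[3]]@cloud),
                   cloudPoints(d2$train[[3]]@cloud))
  expect_error(generateDataset(10, paramsRanges = list(noseHeight = numeric(0))),
               "empty range")
  expect_error(generateDataset(10, paramsRanges = list(noseHeight = c(5, 2))),
               "invalid range")
  expect_error(generateDataset(5), "nFaces")
})

test_that("dataset export writes readable clouds, landmarks and a manifest", {
  ds <- tinyDataset(10, seed = 5)
  dir <- withr::local_tempdir()
  exportFaceDataset(ds, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 10L)
  id <- man$face_id[man$split == "train"][1]
  cl <- readPointCloud(file.path(dir, paste0(id, ".ply")))
  expect_identical(cloudPoints(cl), cloudPoints(ds$train[[1]]@cloud))
  lm <- readLandmarks(file.path(dir, paste0(id, "_landmarks.json")))
  expect_equal(landmarkCoords(lm), landmarkCoords(ds$train[[1]]),
               tolerance = 1e-12)
})
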