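test_that("detection network maps any batch to B x 36 outputs", {
  net <- buildDetectionNet(list(M = 16, nBlocks = 3, channels = c(2, 3, 4),
                                fcWidths = 8), seed = 1)
  for (B in c(1, 3)) {
    X <- array(as.numeric(runif(16^3 * B) < 0.1), dim = c(16^3, 1, B))
    out <- netForward(net, X)$out
    expect_equal(dim(out), c(B, 36L))
  }
  # pooling below 1^3 is rejected at build time
  expect_error(buildDetectionNet(list(M = 8, nBlocks = 4,
                                      channels = c(2, 2, 2, 2), fcWidths = 4)),
               "collapse")
})

test_that("prediction networks emit 3N outputs per region", {
  for (org in c("eyes", "chin")) {
    net <- buildPredictionNet(list(M = 8, nBlocks = 2, channels = c(2, 3),
                                   fcWidths = 8, nResBlocks = 2, organ = org),
                              seed = 2)
    X <- array(as.numeric(runif(8^3) < 0.1), dim = c(8^3, 1, 1))
    out <- netForward(net, X)$out
    expect_equal(ncol(out), 3L * organSpec(org)$n_landmarks)
  }
  expect_equal(3L * organSpec("eyes")$n_landmarks, 24L)
  expect_equal(3L * organSpec("chin")$n_landmarks, 12L)
})

test_that("a freshly built residual block is an exact identity", {
  set.seed(3)
  blk <- facemark3d:::.newResBlock(C = 3, D = 4)
  X <- array(rnorm(4^3 * 3 * 2), dim = c(4^3, 3, 2))
  for (train in c(TRUE, FALSE)) {
    r <- facemark3d:::.layerForward(blk, X, train)
    expect_equal(r$Y, X, tolerance = 1e-12)
  }
})

test_that("decoded boxes are always geometrically valid", {
  set.seed(4)
  raw <- matrix(rnorm(5 * 36, sd = 3), 5, 36)
  dec <- decodeBoxes(raw)
  ctr <- facemark3d:::.boxCenterCols
  expect_true(all(abs(dec[, ctr]) < 1))
  expect_true(all(dec[, -ctr] > 0))
})

test_that("forward passes are deterministic in evaluation mode", {
  net <- buildDetectionNet(list(M = 8, nBlocks = 2, channels = c(2, 3),
                                fcWidths = 4), seed = 5)
  X <- array(as.numeric(runif(8^3) < 0.2), dim = c(8^3, 1, 1))
  expect_identical(netForward(net, X)$out, netForward(net, X)$out)
})

test_that("a zero learning rate leaves the weights untouched", {
  ds <- tinyDataset(10, seed = 5)
  dd <- prepareDetectionData(ds$train[1:2], 8)
  net <- buildDetectionNet(list(M = 8, nBlocks = 2, channels = c(2, 3),
                                fcWidths = 4), seed = 6)
  res <- trainDetector(net, dd$grids, dd$boxes, epochs = 1, lr = 0, seed = 7)
  expect_equal(res$net@layers[[1]]$W, net@layers[[1]]$W)
  expect_equal(res$net@layers[[10]]$W, net@layers[[10]]$W)
})

test_that("training histories are identical under identical seeds", {
  ds <- tinyDataset(10, seed = 5)
  dd <- prepareDetectionData(ds$train[1:4], 8)
  run <- function() {
    net <- buildDetectionNet(list(M = 8, nBlocks = 2, channels = c(2, 3),
                                  fcWidths = 4), seed = 8)
    trainDetector(net, dd$grids, dd$boxes, epochs = 3, lr = 1e-3,
                  batchSize = 2, seed = 9)$history
  }
  expect_identical(run(), run())
})

test_that("training rejects empty or mismatched datasets", {
  net <- buildDetectionNet(list(M = 8, nBlocks = 2, channels = c(2, 3),
                                fcWidths = 4), seed = 10)
  expect_error(trainDetector(net, list(), list(), epochs = 1), "empty")
  ds <- tinyDataset(10, seed = 5)
  dd <- prepareDetectionData(ds$train[1:2], 8)
  expect_error(trainDetector(net, dd$grids, dd$boxes[1], epochs = 1),
               "same length")
})

test_that("checkpoints archive the weights, config, seed and epoch", {
  net <- buildDetectionNet(list(M = 8, nBlocks = 2, channels = c(2, 3),
                                fcWidths = 4), seed = 11)
  f <- withr::local_tempfile(fileext = ".rds")
  saveNetCheckpoint(net, f, seed = 42, epoch = 7)
  ck <- loadNetCheckpoint(f)
  expect_equal(ck$seed, 42)
  expect_equal(ck$epoch, 7)
  expect_equal(ck$config$M, 8)
  X <- array(as.numeric(runif(8^3) < 0.2), dim = c(8^3, 1, 1))
  expect_identical(netForward(ck$net, X)$out, netForward(net, X)$out)
})

test_that("validation data drives checkpoint selection and early stopping", {
  ds <- tinyDataset(10, seed = 5)
  dd <- prepareDetectionData(ds$train[1:4], 8)
  dv <- prepareDetectionData(ds$test, 8)
  net <- buildDetectionNet(list(M = 8, nBlocks = 2, channels = c(2, 3),
                                fcWidths = 4), seed = 12)
  res <- trainDetector(net, dd$grids, dd$boxes, epochs = 6, lr = 1e-3,
                       seed = 13, valGrids = dv$grids, valBoxes = dv$boxes)
  expect_length(res$valHistory, length(res$history))
  expect_equal(res$bestEpoch, which.min(res$valHistory))
  # impatient run stops before the full epoch budget when validation stalls
  res2 <- trainDetector(net, dd$grids, dd$boxes, epochs = 50, lr = 0,
                        seed = 13, valGrids = dv$grids, valBoxes = dv$boxes,
                        patience = 2)
  expect_lt(length(res2$history), 50L)
})
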