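# Shared fixtures, built in code once per run and cached across test files.
.fixtures <- new.env(parent = emptyenv())

# A single small face (K kept low for speed; still >= generator minimum).
smallFace <- function(seed = 1, ...) {
  key <- paste0("face_", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateFace(faceParams(K = 1500, seed = seed, ...))
  .fixtures[[key]]
}

tinyDataset <- function(n = 10, seed = 5, K = 1200) {
  key <- sprintf("ds_%d_%d_%d", n, seed, K)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateDataset(n, seed = seed,
                                        baseParams = faceParams(K = K))
  .fixtures[[key]]
}

# Random valid 6 x 6 box matrix (centers in [-0.8, 0.8], positive extents).
randomBoxMat <- function() {
  m <- cbind(matrix(runif(18, -0.8, 0.8), 6, 3),
             matrix(runif(18, 0.05, 0.6), 6, 3))
  colnames(m) <- c("x", "y", "z", "xl", "yl", "zl")
  rownames(m) <- organNames()
  m
}

# Random N x 3 coordinate matrix.
randomCoords <- function(n, lim = 1) matrix(runif(n * 3, -lim, lim), n, 3)

# Untrained tiny networks for structural / pipeline-contract tests.
tinyNets <- function(M = 16, seed = 99) {
  key <- sprintf("nets_%d_%d", M, seed)
  if (is.null(.fixtures[[key]])) {
    det <- buildDetectionNet(list(M = M, nBlocks = 2, channels = c(2, 4),
                                  fcWidths = 8), seed = seed)
    preds <- lapply(stats::setNames(organNames(), organNames()), function(org)
      buildPredictionNet(list(M = M, nBlocks = 2, channels = c(2, 4),
                              fcWidths = 8, nResBlocks = 1, organ = org),
                         seed = seed + match(org, organNames())))
    .fixtures[[key]] <- list(det = det, preds = preds)
  }
  .fixtures[[key]]
}
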