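# Training losses: the detection box loss (weighted center / size squared
# errors averaged over the six regions) and the landmark regression losses
# (mean squared distance, max squared distance, and their convex
# combination), plus the volumetric box IoU used to evaluate detection.

.asBoxMat <- function(x) {
  if (is(x, "OrganBoxSet")) return(boxMatrix(x))
  x <- as.matrix(x)
  if (!identical(dim(x), c(6L, 6L))) stop("expected 6 boxes of 6 values")
  x
}

.checkLambdas <- function(lambda1, lambda2) {
  if (lambda1 < 0 || lambda2 < 0 || abs(lambda1 + lambda2 - 1) > 1e-9)
    stop("lambda1 and lambda2 must be nonnegative and sum to 1")
}

#' Detection loss over the six region boxes
#'
#' Mean over the six regions of a weighted sum of the squared center error
#' and the box-size error:
#' (1/6) * sum_i [ lambda1 * ||center_i - center_hat_i||^2 +
#'                 lambda2 * sizeError_i ].
#' With the default \code{sizeTerm = "squared_diff"} the size error is the
#' sum of squared half-extent differences. The alternative
#' \code{"diff_of_squares_abs"} uses |xl^2 - xl_hat^2| + ... instead (the
#' difference-of-squares form made sign-definite with absolute values).
#'
#' @param pred,true \linkS4class{OrganBoxSet} objects or 6 x 6 matrices
#'   (rows regions, columns x, y, z, xl, yl, zl).
#' @param lambda1,lambda2 center / size weights; must sum to 1.
#' @param sizeTerm "squared_diff" or "diff_of_squares_abs".
#' @return nonnegative scalar; zero iff pred equals true (for the default
#'   size term).
#' @export
detectionLoss <- function(pred, true, lambda1 = 0.5, lambda2 = 1 - lambda1,
                          sizeTerm = c("squared_diff", "diff_of_squares_abs")) {
  sizeTerm <- match.arg(sizeTerm)
  .checkLambdas(lambda1, lambda2)
  p <- .asBoxMat(pred); t <- .asBoxMat(true)
  ctr <- rowSums((p[, 1:3] - t[, 1:3])^2)
  sz <- if (sizeTerm == "squared_diff") rowSums((p[, 4:6] - t[, 4:6])^2)
        else rowSums(abs(t[, 4:6]^2 - p[, 4:6]^2))
  mean(lambda1 * ctr + lambda2 * sz)
}

# Vectorized batch version on decoded B x 36 matrices (organ-major rows of
# flattenBoxes). Returns per-batch mean loss and gradient wrt pred.
.detectionLossBatch <- function(pred, true, lambda1, lambda2,
                                sizeTerm = "squared_diff") {
  diff <- pred - true
  ctr <- .boxCenterCols
  w <- rep(lambda2 / 6, 36)
  w[ctr] <- lambda1 / 6
  W <- matrix(w, nrow(pred), 36, byrow = TRUE)
  if (sizeTerm == "squared_diff") {
    loss <- rowSums(W * diff^2)
    grad <- 2 * W * diff / nrow(pred)
  } else {
    sq <- pred^2 - true^2
    v <- diff^2
    v[, -ctr] <- abs(sq[, -ctr])
    loss <- rowSums(W * v)
    grad <- 2 * W * diff
    grad[, -ctr] <- W[, -ctr] * sign(sq[, -ctr]) * 2 * pred[, -ctr]
    grad <- grad / nrow(pred)
  }
  list(loss = mean(loss), grad = grad)
}

.asCoordMat <- function(x) {
  if (is(x, "LandmarkSet")) return(landmarkCoords(x))
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("expected an N x 3 coordinate matrix")
  x
}

#' Mean squared-distance landmark loss
#'
#' (1/N) * sum_i ||p_i - p_hat_i||^2 over the N landmarks of one region;
#' minimizing it drives the average error down.
#'
#' @param pred,true N x 3 coordinate matrices (or \linkS4class{LandmarkSet}).
#' @return nonnegative scalar.
#' @export
lossMean <- function(pred, true) {
  p <- .asCoordMat(pred); t <- .asCoordMat(true)
  if (!all(dim(p) == dim(t))) stop("pred and true must have identical shape")
  mean(rowSums((p - t)^2))
}

#' Maximum squared-distance landmark loss
#'
#' max_i ||p_i - p_hat_i||^2; minimizing it drives the worst-case error down.
#'
#' @inheritParams lossMean
#' @return nonnegative scalar; always >= \code{lossMean(pred, true)}.
#' @export
lossMax <- function(pred, true) {
  p <- .asCoordMat(pred); t <- .asCoordMat(true)
  if (!all(dim(p) == dim(t))) stop("pred and true must have identical shape")
  max(rowSums((p - t)^2))
}

#' Combined mean/max landmark loss
#'
#' lambda1 * lossMean + lambda2 * lossMax with lambda1 + lambda2 = 1; lies
#' between the mean and max losses for any valid weights.
#'
#' @inheritParams lossMean
#' @param lambda1,lambda2 weights, nonnegative, summing to 1.
#' @return nonnegative scalar.
#' @export
lossCombined <- function(pred, true, lambda1 = 0.5, lambda2 = 1 - lambda1) {
  .checkLambdas(lambda1, lambda2)
  lambda1 * lossMean(pred, true) + lambda2 * lossMax(pred, true)
}

# Gradient of the combined loss wrt pred (N x 3). The max term is handled by
# its subgradient at the (first) argmax landmark.
.combinedLossGrad <- function(pred, true, lambda1, lambda2) {
  d <- pred - true
  sq <- rowSums(d^2)
  g <- (2 * lambda1 / nrow(pred)) * d
  i <- which.max(sq)
  g[i, ] <- g[i, ] + 2 * lambda2 * d[i, ]
  g
}

#' Volumetric intersection-over-union of two boxes
#'
#' @param a,b length-6 box vectors (x, y, z, xl, yl, zl): center plus
#'   per-axis half-extents.
#' @return IoU in [0, 1]; 1 iff the boxes coincide, 0 if disjoint.
#' @export
boxIoU <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  loA <- a[1:3] - a[4:6]; hiA <- a[1:3] + a[4:6]
  loB <- b[1:3] - b[4:6]; hiB <- b[1:3] + b[4:6]
  ov <- pmax(0, pmin(hiA, hiB) - pmax(loA, loB))
  inter <- prod(ov)
  union <- prod(hiA - loA) + prod(hiB - loB) - inter
  if (union <= 0) return(0)
  inter / union
}
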