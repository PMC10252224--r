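# Coordinate-frame machinery: normalization to [-1,1]^3 with a recorded
# isotropic scale, voxelization onto the M^3 occupancy grid, region cropping,
# and the statistical outlier filter.

#' Construct a FaceCloud
#'
#' @param points numeric K x 3 matrix (mm), K >= 4, all finite.
#' @return a \linkS4class{FaceCloud}.
#' @export
faceCloud <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  new("FaceCloud", points = points)
}

#' Map normalized coordinates back to millimetres
#'
#' @param points numeric N x 3 matrix (or 3-vector) in the normalized frame.
#' @param transform a \linkS4class{NormTransform}.
#' @return coordinates in mm, same shape as the input.
#' @export
toMm <- function(points, transform) {
  if (is.null(dim(points))) return(points * transform@scale + transform@translation)
  sweep(points * transform@scale, 2, transform@translation, "+")
}

#' Map millimetre coordinates into the normalized frame
#'
#' @inheritParams toMm
#' @param points numeric N x 3 matrix (or 3-vector) in mm.
#' @return normalized coordinates, same shape as the input.
#' @export
toNormalized <- function(points, transform) {
  if (is.null(dim(points))) return((points - transform@translation) / transform@scale)
  sweep(points, 2, transform@translation, "-") / transform@scale
}

#' Normalize a point cloud to the unit cube
#'
#' Maps the cloud into [-1, 1]^3 with a single isotropic scale: the
#' translation t is the bounding-box midpoint and the scale S is half the
#' largest bounding-box edge (mm per normalized unit). S is recorded so that
#' normalized-frame distances can be restored to mm; an isotropic S is
#' required for that restoration to be a single multiplier.
#'
#' @param cloud a \linkS4class{FaceCloud} (or K x 3 matrix).
#' @return a \linkS4class{NormalizedFaceCloud}.
#' @export
normalizeCloud <- function(cloud) {
  p <- if (is(cloud, "FaceCloud")) cloud@points else as.matrix(cloud)
  dimnames(p) <- NULL
  rng <- apply(p, 2, range)
  tr <- (rng[1, ] + rng[2, ]) / 2
  S <- max(rng[2, ] - rng[1, ]) / 2
  if (S <= 0) stop("cannot normalize: all points are identical (scale would be 0)")
  q <- sweep(p, 2, tr, "-") / S
  q[q > 1] <- 1
  q[q < -1] <- -1
  new("NormalizedFaceCloud", points = q,
      transform = new("NormTransform", scale = S, translation = tr))
}

# 0-based voxel index per axis for normalized coordinates.
.voxelIndex0 <- function(coords, M) {
  idx <- floor((coords + 1) / 2 * M)
  idx[idx < 0] <- 0
  idx[idx > M - 1] <- M - 1
  idx
}

#' Voxelize a normalized cloud
#'
#' Converts the normalized cloud into an M^3 binary occupancy tensor. Each
#' point maps per axis to cell floor((c + 1)/2 * M), clamped to [0, M-1] so
#' the c = +1 boundary belongs to the last cell; cells holding at least one
#' point are set to 1. The per-axis precision of this representation is 2S/M
#' mm.
#'
#' @param ncloud a \linkS4class{NormalizedFaceCloud} (or K x 3 matrix in
#'   [-1, 1]).
#' @param M grid side, integer >= 2.
#' @return a \linkS4class{VoxelGrid}.
#' @export
voxelize <- function(ncloud, M) {
  stopifnot(M >= 2)
  p <- if (is(ncloud, "NormalizedFaceCloud")) ncloud@points else as.matrix(ncloud)
  idx <- .voxelIndex0(p, M)
  lin <- 1 + idx[, 1] + M * idx[, 2] + M * M * idx[, 3]
  occ <- array(0, dim = c(M, M, M))
  occ[unique(lin)] <- 1
  new("VoxelGrid", occupancy = occ)
}

#' Center of a voxel in normalized coordinates
#'
#' Inverse of the voxelization index mapping. Indices are 1-based, matching R
#' array indexing of the occupancy tensor.
#'
#' @param i,j,k 1-based voxel indices in 1..M (vectors allowed, recycled).
#' @param M grid side.
#' @return numeric matrix n x 3 (or 3-vector for scalar input) of normalized
#'   coordinates.
#' @examples
#' voxelCenter(1, 1, 1, 2)  # (-0.5, -0.5, -0.5)
#' @export
voxelCenter <- function(i, j, k, M) {
  idx <- cbind(i, j, k)
  if (any(idx < 1 | idx > M)) stop("voxel indices must be in 1..", M)
  ctr <- (idx - 1 + 0.5) * 2 / M - 1
  if (nrow(ctr) == 1L) as.numeric(ctr) else unname(ctr)
}

#' Remove statistical outlier points
#'
#' Approximates occlusion cleaning with a k-nearest-neighbour statistical
#' filter: points whose mean distance to their k nearest neighbours exceeds
#' mean + sigmaMult * sd (over the whole cloud) are dropped. As a guard, at
#' most 20\% of the points (the most extreme ones) are ever removed.
#' Degenerate clouds (fewer than kNeighbors + 1 points) pass through
#' unchanged.
#'
#' @param cloud a \linkS4class{FaceCloud}.
#' @param kNeighbors number of neighbours, >= 1.
#' @param sigmaMult threshold multiplier; \code{Inf} disables filtering.
#' @return a \linkS4class{FaceCloud} whose points are a subset of the input.
#' @export
outlierFilter <- function(cloud, kNeighbors = 8, sigmaMult = 2) {
  stopifnot(kNeighbors >= 1)
  p <- cloud@points
  K <- nrow(p)
  if (K <= kNeighbors || !is.finite(sigmaMult)) return(cloud)
  d <- knn_mean_dist_cpp(p, as.integer(kNeighbors))
  thr <- mean(d) + sigmaMult * stats::sd(d)
  drop <- which(d > thr)
  maxDrop <- floor(0.2 * K)
  if (length(drop) > maxDrop)
    drop <- drop[order(d[drop], decreasing = TRUE)][seq_len(maxDrop)]
  if (length(drop) == 0L) return(cloud)
  faceCloud(p[-drop, , drop = FALSE])
}

#' Crop a facial region and re-voxelize it
#'
#' Selects the points of one region from a normalized face cloud using an
#' axis-aligned box (closed interval, half-extents enlarged by \code{margin}
#' to tolerate detection error), re-normalizes the selection to [-1, 1]^3
#' with its own isotropic transform, and voxelizes it at \code{MOrgan}. The
#' returned transform is the composition of the region-level and face-level
#' transforms, so region-frame coordinates map straight back to mm.
#'
#' @param ncloud a \linkS4class{NormalizedFaceCloud}.
#' @param box numeric length-6 box vector (x, y, z, xl, yl, zl) in the
#'   normalized frame, or one row of \code{boxMatrix()}.
#' @param margin multiplier >= 1 applied to the half-extents.
#' @param MOrgan grid side for the region grid, >= 2.
#' @return list with \code{grid} (\linkS4class{VoxelGrid}), \code{transform}
#'   (\linkS4class{NormTransform}, region frame to mm), \code{local}
#'   (\linkS4class{NormTransform}, region frame to face-normalized frame) and
#'   \code{points} (the selected points in the region frame).
#' @export
cropOrgan <- function(ncloud, box, margin = 1.1, MOrgan = 32) {
  stopifnot(margin >= 1, MOrgan >= 2)
  box <- as.numeric(box)
  if (length(box) != 6L) stop("box must have 6 values: x, y, z, xl, yl, zl")
  ctr <- box[1:3]
  he <- box[4:6] * margin
  if (any(he <= 0)) stop("box half-extents must be positive")
  p <- ncloud@points
  sel <- abs(sweep(p, 2, ctr, "-")) <= rep(he, each = nrow(p))
  keep <- rowSums(sel) == 3L
  if (!any(keep)) {
    cond <- simpleError(paste0("empty organ crop: no point inside box center (",
                               paste(sprintf("%.3f", ctr), collapse = ", "),
                               ") with margin ", margin))
    class(cond) <- c("facemark3d_empty_crop", class(cond))
    stop(cond)
  }
  sub <- p[keep, , drop = FALSE]
  rng <- apply(sub, 2, range)
  t2 <- (rng[1, ] + rng[2, ]) / 2
  S2 <- max(rng[2, ] - rng[1, ]) / 2
  if (S2 <= 0) {
    cond <- simpleError("empty organ crop: selected points are degenerate")
    class(cond) <- c("facemark3d_empty_crop", class(cond))
    stop(cond)
  }
  q <- sweep(sub, 2, t2, "-") / S2
  q[q > 1] <- 1
  q[q < -1] <- -1
  face <- ncloud@transform
  composed <- new("NormTransform", scale = face@scale * S2,
                  translation = face@scale * t2 + face@translation)
  list(grid = voxelize(q, MOrgan),
       transform = composed,
       local = new("NormTransform", scale = S2, translation = t2),
       points = q)
}
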