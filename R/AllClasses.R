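#' @import methods
NULL

#' Facial surface point cloud
#'
#' A set of surface samples from a 3D facial scan, stored as a K x 3 numeric
#' matrix of millimetre coordinates. The vertex count K is arbitrary (it
#' differs between scans) but must be at least 4, and all coordinates must be
#' finite.
#'
#' @slot points numeric matrix, K x 3, columns x/y/z in mm.
#' @export
setClass("FaceCloud", representation(points = "matrix"))

setValidity("FaceCloud", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L) return("points must be a numeric K x 3 matrix")
  if (nrow(p) < 4L) return("a point cloud needs at least 4 points")
  if (!all(is.finite(p))) return("points contain non-finite coordinates")
  TRUE
})

#' Normalization transform
#'
#' Records the isotropic mapping between millimetre coordinates and the
#' normalized [-1, 1] cube: mm = scale * normalized + translation. The scale S
#' (mm per normalized unit) is kept so that errors measured in the normalized
#' frame can be restored to millimetres.
#'
#' @slot scale positive scalar, mm per normalized unit.
#' @slot translation numeric 3-vector, mm.
#' @export
setClass("NormTransform", representation(scale = "numeric", translation = "numeric"))

setValidity("NormTransform", function(object) {
  if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
    return("scale must be a single positive finite number")
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    return("translation must be a finite 3-vector")
  TRUE
})

#' Point cloud normalized to the unit cube
#'
#' A point cloud mapped into [-1, 1]^3 together with the transform needed to
#' invert the mapping. Scaling is tight: at least one coordinate attains
#' magnitude 1.
#'
#' @slot points numeric K x 3 matrix in [-1, 1].
#' @slot transform the \linkS4class{NormTransform} back to mm.
#' @export
setClass("NormalizedFaceCloud",
         representation(points = "matrix", transform = "NormTransform"))

setValidity("NormalizedFaceCloud", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L) return("points must be a numeric K x 3 matrix")
  m <- max(abs(p))
  if (m > 1 + 1e-9) return("normalized coordinates exceed [-1, 1]")
  if (m < 1 - 1e-6) return("scaling is not tight: no coordinate attains magnitude 1")
  TRUE
})

#' Binary voxel occupancy grid
#'
#' An M x M x M occupancy tensor over the normalized cube: cell (i, j, k) is 1
#' when at least one point falls inside it, 0 otherwise. The grid precision is
#' 2S/M mm per axis, where S is the normalization scale.
#'
#' @slot occupancy numeric M x M x M array with values in \{0, 1\}.
#' @export
setClass("VoxelGrid", representation(occupancy = "array"))

setValidity("VoxelGrid", function(object) {
  a <- object@occupancy
  d <- dim(a)
  if (length(d) != 3L || length(unique(d)) != 1L)
    return("occupancy must be a cubic M x M x M array")
  if (d[1] < 2L) return("grid side M must be at least 2")
  if (!all(a %in% c(0, 1))) return("occupancy values must be 0 or 1")
  TRUE
})

#' Set of six facial-region boxes
#'
#' Axis-aligned boxes for the six facial regions, in the fixed order eyes,
#' nose, lips, chin, right_face, left_face. Each box is encoded as
#' [x, y, z, xl, yl, zl]: center plus per-axis center-to-face half-extents, in
#' normalized coordinates. Flattened row-wise this is the 36-vector the
#' detection network regresses.
#'
#' @slot boxes numeric 6 x 6 matrix; rows are regions, columns
#'   x, y, z, xl, yl, zl.
#' @export
setClass("OrganBoxSet", representation(boxes = "matrix"))

setValidity("OrganBoxSet", function(object) {
  b <- object@boxes
  if (!is.numeric(b) || !identical(dim(b), c(6L, 6L)))
    return("boxes must be a numeric 6 x 6 matrix")
  if (!all(is.finite(b))) return("boxes contain non-finite values")
  if (any(b[, 4:6] <= 0)) return("half-extents must be strictly positive")
  if (any(abs(b[, 1:3]) > 1 + 1e-9)) return("box centers must lie in [-1, 1]^3")
  TRUE
})

#' Named landmark coordinate set
#'
#' Coordinates for named facial landmarks: an N x 3 matrix with landmark names
#' as row names. Typically holds all 32 registry landmarks in mm, but subsets
#' and other frames (normalized, region frame) are allowed; the \code{unit}
#' slot documents the frame.
#'
#' @slot coords numeric N x 3 matrix with row names.
#' @slot unit character, e.g. "mm" or "normalized".
#' @export
setClass("LandmarkSet", representation(coords = "matrix", unit = "character"))

setValidity("LandmarkSet", function(object) {
  cc <- object@coords
  if (!is.numeric(cc) || ncol(cc) != 3L) return("coords must be a numeric N x 3 matrix")
  if (is.null(rownames(cc)) || anyDuplicated(rownames(cc)))
    return("coords must have unique landmark row names")
  if (!all(is.finite(cc))) return("coords contain non-finite values")
  TRUE
})

#' Synthetic face with known ground truth
#'
#' A generated face: the sampled point cloud (mm, with measurement noise), the
#' exact landmark positions on the noise-free surface (mm), the six region
#' boxes derived from the landmarks in the face's normalized frame, and the
#' normalization transform tying the two frames together.
#'
#' @slot cloud \linkS4class{FaceCloud} in mm.
#' @slot landmarks \linkS4class{LandmarkSet}, all 32 landmarks, mm.
#' @slot boxes \linkS4class{OrganBoxSet} in the normalized frame.
#' @slot transform \linkS4class{NormTransform} of the generated cloud.
#' @slot params list of generator parameters (includes the seed).
#' @export
setClass("SyntheticFace",
         representation(cloud = "FaceCloud", landmarks = "LandmarkSet",
                        boxes = "OrganBoxSet", transform = "NormTransform",
                        params = "list"))

#' Volumetric network
#'
#' A stack of volumetric layers (3D convolution, max pooling, batch
#' normalization, activation, optional residual stage, fully connected head)
#' mapping an occupancy grid to a coordinate vector. \code{kind} is
#' "detection" (36 box values) or "prediction" (3N landmark coordinates for
#' one region).
#'
#' @slot layers list of layer parameter lists.
#' @slot config list: grid side M, channel widths, head widths, output size.
#' @slot kind character, "detection" or "prediction".
#' @export
setClass("VolNet",
         representation(layers = "list", config = "list", kind = "character"))

setMethod("show", "FaceCloud", function(object) {
  cat(sprintf("FaceCloud: %d points (mm)\n", nrow(object@points)))
  r <- apply(object@points, 2, range)
  cat(sprintf("  extent x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
})

setMethod("show", "NormalizedFaceCloud", function(object) {
  cat(sprintf("NormalizedFaceCloud: %d points in [-1,1]^3, S = %.3f mm/unit\n",
              nrow(object@points), object@transform@scale))
})

setMethod("show", "NormTransform", function(object) {
  cat(sprintf("NormTransform: S = %.4f mm/unit, t = (%.2f, %.2f, %.2f) mm\n",
              object@scale, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "VoxelGrid", function(object) {
  M <- dim(object@occupancy)[1]
  cat(sprintf("VoxelGrid: %d^3, %d occupied voxels\n", M, sum(object@occupancy)))
})

setMethod("show", "OrganBoxSet", function(object) {
  cat("OrganBoxSet (normalized frame):\n")
  print(round(object@boxes, 3))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d landmarks (%s)\n", nrow(object@coords), object@unit))
})

setMethod("show", "SyntheticFace", function(object) {
  cat(sprintf("SyntheticFace: %d points, %d landmarks, seed %s\n",
              nrow(object@cloud@points), nrow(object@landmarks@coords),
              as.character(object@params$seed)))
})

setMethod("show", "VolNet", function(object) {
  cat(sprintf("VolNet (%s): M = %d, output %d, %d layers\n", object@kind,
              object@config$M, object@config$outDim, length(object@layers)))
})
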