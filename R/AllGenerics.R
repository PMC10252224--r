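#' Extract point coordinates
#'
#' @param x a \linkS4class{FaceCloud} or \linkS4class{NormalizedFaceCloud}.
#' @return numeric K x 3 matrix.
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))

#' @rdname cloudPoints
setMethod("cloudPoints", "FaceCloud", function(x) x@points)

#' @rdname cloudPoints
setMethod("cloudPoints", "NormalizedFaceCloud", function(x) x@points)

#' Extract the normalization transform
#'
#' @param x a \linkS4class{NormalizedFaceCloud} or \linkS4class{SyntheticFace}.
#' @return a \linkS4class{NormTransform}.
#' @export
setGeneric("normTransform", function(x) standardGeneric("normTransform"))

#' @rdname normTransform
setMethod("normTransform", "NormalizedFaceCloud", function(x) x@transform)

#' @rdname normTransform
setMethod("normTransform", "SyntheticFace", function(x) x@transform)

#' Extract the occupancy tensor
#'
#' @param x a \linkS4class{VoxelGrid}.
#' @return numeric M x M x M array of 0/1 values.
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname occupancy
setMethod("occupancy", "VoxelGrid", function(x) x@occupancy)

#' Grid side length M
#'
#' @param x a \linkS4class{VoxelGrid}.
#' @return integer M.
#' @export
setGeneric("gridSide", function(x) standardGeneric("gridSide"))

#' @rdname gridSide
setMethod("gridSide", "VoxelGrid", function(x) dim(x@occupancy)[1])

#' Extract the 6 x 6 box matrix
#'
#' @param x an \linkS4class{OrganBoxSet}.
#' @return numeric 6 x 6 matrix (rows regions, columns x, y, z, xl, yl, zl).
#' @export
setGeneric("boxMatrix", function(x) standardGeneric("boxMatrix"))

#' @rdname boxMatrix
setMethod("boxMatrix", "OrganBoxSet", function(x) x@boxes)

#' Extract landmark coordinates
#'
#' @param x a \linkS4class{LandmarkSet} or \linkS4class{SyntheticFace}.
#' @return numeric N x 3 matrix with landmark row names.
#' @export
setGeneric("landmarkCoords", function(x) standardGeneric("landmarkCoords"))

#' @rdname landmarkCoords
setMethod("landmarkCoords", "LandmarkSet", function(x) x@coords)

#' @rdname landmarkCoords
setMethod("landmarkCoords", "SyntheticFace", function(x) x@landmarks@coords)
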