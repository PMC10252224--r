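# Parametric synthetic faces with analytically known landmark ground truth.
# The face is a height field z = f(x, y) over an elliptical domain: a
# half-ellipsoid "head" plus smooth Gaussian features (nose ridge, eye
# bulges, two lip lobes, chin boss). All 32 landmarks are placed at fixed
# parametric (x, y) positions and evaluated through the same f, so they lie
# exactly on the noise-free surface; an asymmetry warp, a pose rotation and
# additive Gaussian measurement noise are applied afterwards (noise to the
# cloud only, never to the recorded landmarks).

#' Synthetic face generator parameters
#'
#' All sizes are in millimetres. Defaults emulate an adult face captured by
#' surface stereophotogrammetry.
#'
#' @param headAxes half-axes (a, b, c) of the head ellipsoid: half-width,
#'   half-height, depth.
#' @param noseHeight nose ridge prominence.
#' @param noseWidth nose base width.
#' @param eyeOffset (x, y) position of each eye center relative to the face
#'   midline.
#' @param mouthWidth mouth width (cheilion-to-cheilion).
#' @param jawAngle mandibular angle in degrees; controls gonion placement.
#' @param asymmetry dimensionless left-right asymmetry factor in [0, 0.1].
#' @param poseAngles rotation angles (degrees) about x, y, z applied to the
#'   whole face (mild pose perturbation).
#' @param noiseSd isotropic Gaussian measurement noise sd, mm.
#' @param K number of surface points to sample, >= 1000.
#' @param seed integer RNG seed; identical seed + params give bit-identical
#'   output.
#' @return validated parameter list of class "faceParams".
#' @export
faceParams <- function(headAxes = c(70, 95, 80), noseHeight = 14,
                       noseWidth = 18, eyeOffset = c(32, 35),
                       mouthWidth = 52, jawAngle = 120, asymmetry = 0.02,
                       poseAngles = c(0, 0, 0), noiseSd = 0.3, K = 20000,
                       seed = 1) {
  p <- list(headAxes = as.numeric(headAxes), noseHeight = noseHeight,
            noseWidth = noseWidth, eyeOffset = as.numeric(eyeOffset),
            mouthWidth = mouthWidth, jawAngle = jawAngle,
            asymmetry = asymmetry, poseAngles = as.numeric(poseAngles),
            noiseSd = noiseSd, K = as.integer(K), seed = as.integer(seed))
  sizes <- c(p$headAxes, p$noseHeight, p$noseWidth, p$eyeOffset,
             p$mouthWidth, p$jawAngle)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all size parameters must be positive and finite")
  if (p$asymmetry < 0 || p$asymmetry > 0.1)
    stop("asymmetry must lie in [0, 0.1]")
  if (p$K < 1000) stop("K must be at least 1000")
  if (p$noiseSd < 0) stop("noiseSd must be nonnegative")
  if (p$noseHeight >= p$headAxes[3] / 2 || p$noseWidth >= p$headAxes[1] / 2 ||
      p$mouthWidth >= 1.6 * p$headAxes[1] ||
      p$eyeOffset[1] >= 0.75 * p$headAxes[1] ||
      p$eyeOffset[2] >= 0.75 * p$headAxes[2])
    stop("degenerate parameter combination: facial features too large for the head")
  class(p) <- "faceParams"
  p
}

# Height-field definition: base half-ellipsoid plus Gaussian bumps.
# The domain is restricted to (x/a)^2 + (y/b)^2 <= 0.96 to avoid the rim
# where the surface turns vertical.
.faceSurface <- function(p) {
  a <- p$headAxes[1]; b <- p$headAxes[2]; cc <- p$headAxes[3]
  yN <- 0.105 * b                       # nose tip height on the face
  yM <- -0.40 * b                       # mouth line
  bumps <- rbind(
    c(p$noseHeight, 0, yN, p$noseWidth / 2, 18),            # nose ridge
    c(4, -p$eyeOffset[1], p$eyeOffset[2], 9, 6),            # right eye bulge
    c(4, p$eyeOffset[1], p$eyeOffset[2], 9, 6),             # left eye bulge
    c(3.5, 0, yM + 5, p$mouthWidth / 2.6, 4),               # upper lip lobe
    c(3.0, 0, yM - 5, p$mouthWidth / 3.0, 4),               # lower lip lobe
    c(8, 0, -0.74 * b, 14, 12))                             # chin boss
  colnames(bumps) <- c("amp", "x0", "y0", "sx", "sy")
  R2 <- 0.96
  f <- function(x, y) {
    u <- pmin((x / a)^2 + (y / b)^2, R2)
    z <- cc * sqrt(1 - u)
    for (i in seq_len(nrow(bumps))) {
      z <- z + bumps[i, 1] *
        exp(-(x - bumps[i, 2])^2 / (2 * bumps[i, 4]^2) -
             (y - bumps[i, 3])^2 / (2 * bumps[i, 5]^2))
    }
    z
  }
  grad <- function(x, y) {
    u <- pmin((x / a)^2 + (y / b)^2, R2)
    s <- sqrt(1 - u)
    inside <- (x / a)^2 + (y / b)^2 < R2
    fx <- ifelse(inside, -cc * (x / a^2) / s, 0)
    fy <- ifelse(inside, -cc * (y / b^2) / s, 0)
    for (i in seq_len(nrow(bumps))) {
      g <- bumps[i, 1] *
        exp(-(x - bumps[i, 2])^2 / (2 * bumps[i, 4]^2) -
             (y - bumps[i, 3])^2 / (2 * bumps[i, 5]^2))
      fx <- fx - g * (x - bumps[i, 2]) / bumps[i, 4]^2
      fy <- fy - g * (y - bumps[i, 3]) / bumps[i, 5]^2
    }
    cbind(fx, fy)
  }
  list(f = f, grad = grad, R2 = R2, a = a, b = b)
}

# Parametric (x, y) landmark positions in canonical registry order.
# "right" landmarks sit at negative x (+x is the subject's left).
.landmarkXY <- function(p) {
  a <- p$headAxes[1]; b <- p$headAxes[2]
  xe <- p$eyeOffset[1]; ye <- p$eyeOffset[2]
  we <- 0.2 * a; he <- 7
  yN <- 0.105 * b; yM <- -0.40 * b
  xGo <- 0.72 * a * sin(p$jawAngle * pi / 180 / 2)
  lr <- function(x, y) rbind(c(-x, y), c(x, y))  # right row then left row
  xy <- rbind(
    lr(xe - we, ye),                 # Endocanthion
    lr(xe + we, ye),                 # Exocanthion
    lr(xe, ye + he),                 # Palpebrale superius
    lr(xe, ye - he),                 # Palpebrale inferius
    c(0, yN + 45), c(0, yN + 30), c(0, yN),          # G, Na, Pn
    c(0, yN - 22), c(0, yN - 30),                    # Sn, A
    lr(0.75 * p$noseWidth, yN - 14),                 # Alare
    c(0, yM + 6), c(0, yM), c(0, yM - 6),            # Ls, Sto, Li
    lr(p$mouthWidth / 6, yM + 5),                    # Christa philtra
    lr(p$mouthWidth / 2, yM),                        # Cheilion
    c(0, -0.55 * b), c(0, -0.74 * b),                # B, Pg
    c(0, -0.81 * b), c(0, -0.88 * b),                # Gn, Me
    c(-0.93 * a, 0), c(-0.88 * a, 0.18 * b), c(-xGo, -0.45 * b),  # right face
    c(0.93 * a, 0), c(0.88 * a, 0.18 * b), c(xGo, -0.45 * b))     # left face
  rownames(xy) <- landmarkRegistry()$name
  xy
}

.rotationMatrix <- function(anglesDeg) {
  r <- anglesDeg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

.asymWarp <- function(pts, af, a) {
  if (af == 0) return(pts)
  pts[, 1] <- pts[, 1] * (1 + af * tanh(pts[, 1] / (0.5 * a)))
  pts
}

# Region boxes from landmark bounding boxes in the normalized frame: each
# half-extent is enlarged by inflation/2 times the box diagonal (so the box
# side grows by inflation * diagonal in total) and floored at minHalfExtent.
.trueBoxes <- function(lmNorm, inflation, minHalfExtent) {
  reg <- landmarkRegistry()
  b <- matrix(0, 6, 6, dimnames = list(organNames(),
                                       c("x", "y", "z", "xl", "yl", "zl")))
  for (org in organNames()) {
    m <- lmNorm[reg$name[reg$organ == org], , drop = FALSE]
    lo <- apply(m, 2, min); hi <- apply(m, 2, max)
    d <- sqrt(sum((hi - lo)^2))
    he <- pmax((hi - lo) / 2 + inflation * d / 2, minHalfExtent)
    b[org, ] <- c((lo + hi) / 2, he)
  }
  new("OrganBoxSet", boxes = b)
}

#' Generate one synthetic face
#'
#' Samples K points area-uniformly (by rejection on the surface-area element)
#' from the analytic face surface, applies the asymmetry warp, the pose
#' rotation and additive Gaussian noise, and records the exact landmark
#' images under the same warp and rotation (without noise). Ground-truth
#' region boxes are the per-region landmark bounding boxes in the face's
#' normalized frame, inflated by a fraction of the box diagonal with a
#' minimum half-extent.
#'
#' @param params a \code{\link{faceParams}} list.
#' @param boxInflation diagonal fraction by which each region box is grown.
#' @param minHalfExtent half-extent floor in normalized units.
#' @return a \linkS4class{SyntheticFace}.
#' @export
generateFace <- function(params = faceParams(), boxInflation = 0.25,
                         minHalfExtent = 0.05) {
  if (!inherits(params, "faceParams")) params <- do.call(faceParams, params)
  surf <- .faceSurface(params)
  set.seed(params$seed)
  # area-element upper bound on a deterministic grid (5% safety margin)
  gx <- seq(-surf$a * sqrt(surf$R2), surf$a * sqrt(surf$R2), length.out = 61)
  gy <- seq(-surf$b * sqrt(surf$R2), surf$b * sqrt(surf$R2), length.out = 61)
  gg <- expand.grid(x = gx, y = gy)
  inDom <- (gg$x / surf$a)^2 + (gg$y / surf$b)^2 <= surf$R2
  gr <- surf$grad(gg$x[inDom], gg$y[inDom])
  gvals <- sqrt(1 + gr[, 1]^2 + gr[, 2]^2)
  gmax <- 1.05 * max(gvals)
  cellA <- diff(gx)[1] * diff(gy)[1]
  surfaceArea <- sum(gvals) * cellA
  K <- params$K
  pts <- matrix(0, 0, 2)
  while (nrow(pts) < K) {
    n <- max(2L * (K - nrow(pts)), 1000L)
    r <- sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
    x <- surf$a * sqrt(surf$R2) * r * cos(th)
    y <- surf$b * sqrt(surf$R2) * r * sin(th)
    gr <- surf$grad(x, y)
    g <- sqrt(1 + gr[, 1]^2 + gr[, 2]^2)
    keep <- stats::runif(n) < g / gmax
    pts <- rbind(pts, cbind(x[keep], y[keep]))
  }
  pts <- pts[seq_len(K), , drop = FALSE]
  P <- cbind(pts, surf$f(pts[, 1], pts[, 2]))
  lmXY <- .landmarkXY(params)
  L <- cbind(lmXY, surf$f(lmXY[, 1], lmXY[, 2]))
  P <- .asymWarp(P, params$asymmetry, surf$a)
  L <- .asymWarp(L, params$asymmetry, surf$a)
  R <- .rotationMatrix(params$poseAngles)
  P <- P %*% t(R)
  L <- L %*% t(R)
  if (params$noiseSd > 0)
    P <- P + matrix(stats::rnorm(length(P), sd = params$noiseSd), nrow(P), 3)
  cloud <- faceCloud(P)
  nc <- normalizeCloud(cloud)
  lmNorm <- toNormalized(L, nc@transform)
  rownames(lmNorm) <- rownames(lmXY)
  boxes <- .trueBoxes(lmNorm, boxInflation, minHalfExtent)
  params$surfaceArea <- surfaceArea
  new("SyntheticFace", cloud = cloud,
      landmarks = landmarkSet(L, unit = "mm"),
      boxes = boxes, transform = nc@transform,
      params = unclass(params))
}

#' Generate a train/validation/test dataset of synthetic faces
#'
#' Per-face parameters are drawn uniformly from \code{paramsRanges};
#' everything is deterministic under \code{seed}. The dataset is split
#' train : test : validation = 7 : 2 : 1 by default, sizes floor-based with
#' the remainder assigned to the training split.
#'
#' @param nFaces number of faces, >= 10.
#' @param paramsRanges named list of parameter ranges: scalar parameters as
#'   c(lo, hi), vector parameters as rbind(lo, hi). Parameters not listed
#'   keep the value in \code{baseParams}.
#' @param split named fractions (train, test, val) summing to 1.
#' @param seed integer master seed; per-face seeds are drawn from it.
#' @param baseParams a \code{\link{faceParams}} list of defaults.
#' @return list with elements \code{train}, \code{val}, \code{test} (lists of
#'   \linkS4class{SyntheticFace}) and a \code{manifest} data.frame (face id,
#'   split, seed).
#' @export
generateDataset <- function(nFaces,
                            paramsRanges = defaultParamRanges(),
                            split = c(train = 0.7, test = 0.2, val = 0.1),
                            seed = 1, baseParams = faceParams()) {
  stopifnot(nFaces >= 10)
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  normRange <- function(rg, nm) {
    if (length(rg) == 0) stop("empty range for parameter '", nm, "'")
    if (!is.matrix(rg)) {
      if (length(rg) != 2) stop("scalar range for '", nm, "' must be c(lo, hi)")
      rg <- matrix(rg, 2, 1)
    }
    if (nrow(rg) != 2 || any(rg[2, ] < rg[1, ]))
      stop("invalid range for parameter '", nm, "'")
    rg
  }
  for (nm in names(paramsRanges))
    paramsRanges[[nm]] <- normRange(paramsRanges[[nm]], nm)
  set.seed(seed)
  faceSeeds <- sample.int(2147483646L, nFaces)
  draws <- lapply(seq_len(nFaces), function(i) {
    p <- unclass(baseParams)
    for (nm in names(paramsRanges)) {
      rg <- paramsRanges[[nm]]
      p[[nm]] <- stats::runif(ncol(rg), rg[1, ], rg[2, ])
      if (nm %in% c("K", "seed")) p[[nm]] <- as.integer(round(p[[nm]]))
    }
    p$seed <- faceSeeds[i]
    do.call(faceParams, p[setdiff(names(p), "surfaceArea")])
  })
  nTest <- floor(unname(split["test"]) * nFaces)
  nVal <- floor(unname(split["val"]) * nFaces)
  nTrain <- nFaces - nTest - nVal
  ord <- sample.int(nFaces)
  assign <- rep(c("train", "test", "val"), times = c(nTrain, nTest, nVal))[order(ord)]
  faces <- lapply(draws, generateFace)
  manifest <- data.frame(face_id = sprintf("face_%03d", seq_len(nFaces)),
                         split = assign, seed = faceSeeds,
                         stringsAsFactors = FALSE)
  list(train = faces[assign == "train"],
       val = faces[assign == "val"],
       test = faces[assign == "test"],
       manifest = manifest)
}

#' Default per-face parameter variation ranges
#'
#' Mild anatomical variation around the \code{\link{faceParams}} defaults:
#' head size within about 8\%, nose/mouth proportions within about 15\%,
#' pose within 5 degrees per axis, asymmetry up to 0.06.
#'
#' @return named list of ranges suitable for \code{\link{generateDataset}}.
#' @export
defaultParamRanges <- function() {
  list(headAxes = rbind(c(64, 88, 74), c(76, 102, 86)),
       noseHeight = c(11, 17),
       noseWidth = c(15, 21),
       eyeOffset = rbind(c(29, 32), c(35, 38)),
       mouthWidth = c(46, 58),
       jawAngle = c(105, 135),
       asymmetry = c(0, 0.06),
       poseAngles = rbind(c(-5, -5, -5), c(5, 5, 5)))
}

#' Export a synthetic dataset to disk
#'
#' Writes one ascii PLY cloud, one landmark JSON and one region-box JSON per
#' face, plus a manifest CSV (face id, split, seed, parameters as JSON).
#'
#' @param dataset result of \code{\link{generateDataset}}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
exportFaceDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  faces <- c(dataset$train, dataset$val, dataset$test)
  ids <- c(man$face_id[man$split == "train"], man$face_id[man$split == "val"],
           man$face_id[man$split == "test"])
  paramJson <- character(length(faces))
  for (i in seq_along(faces)) {
    f <- faces[[i]]
    writePointCloud(f@cloud, file.path(dir, paste0(ids[i], ".ply")))
    writeLandmarks(f@landmarks, file.path(dir, paste0(ids[i], "_landmarks.json")))
    jsonlite::write_json(as.data.frame(boxMatrix(f@boxes)),
                         file.path(dir, paste0(ids[i], "_boxes.json")),
                         digits = NA)
    paramJson[i] <- as.character(jsonlite::toJSON(
      f@params[setdiff(names(f@params), "surfaceArea")], auto_unbox = TRUE,
      digits = NA))
  }
  man2 <- man[match(ids, man$face_id), ]
  man2$params <- paramJson
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man2, manPath, row.names = FALSE)
  invisible(manPath)
}
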