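# Volumetric network layers and the two architectures: the detection network
# (conv/pool/batch-norm/sigmoid cycles -> fully connected -> 36 box values)
# and the per-region prediction network (same cycles, then a stage of
# pre-activation volumetric residual blocks, then a fully connected head ->
# 3N coordinates). Feature maps are (V, C, B) arrays with V = D^3 voxels.
# Convolution and pooling run through BLAS-backed compiled kernels; batch
# norm, activations and the dense head are vectorized R.

.newConv <- function(cin, cout, D, zero = FALSE) {
  sd <- sqrt(2 / (27 * cin))
  W <- if (zero) matrix(0, 27 * cin, cout)
       else matrix(stats::rnorm(27 * cin * cout, sd = sd), 27 * cin, cout)
  list(type = "conv", D = D, cin = cin, cout = cout, W = W, b = numeric(cout))
}

.newBN <- function(C) list(type = "bn", C = C, gamma = rep(1, C),
                           beta = numeric(C), runMean = numeric(C),
                           runVar = rep(1, C), momentum = 0.1, eps = 1e-5)

.newAct <- function(fun) list(type = "act", fun = fun)

.newPool <- function(D) list(type = "pool", D = D)

.newFC <- function(nin, nout) {
  sd <- sqrt(2 / nin)
  list(type = "fc", W = matrix(stats::rnorm(nin * nout, sd = sd), nin, nout),
       b = numeric(nout))
}

# Pre-activation residual block: y = x + conv2(relu(bn2(conv1(relu(bn1(x)))))).
# conv2 starts at zero, so a freshly built block is an exact identity.
.newResBlock <- function(C, D) {
  list(type = "resblock", C = C, D = D,
       bn1 = .newBN(C), conv1 = .newConv(C, C, D),
       bn2 = .newBN(C), conv2 = .newConv(C, C, D, zero = TRUE))
}

.bnForward <- function(layer, X, train) {
  d <- dim(X)
  V <- d[1]; C <- d[2]; B <- d[3]
  if (train) {
    m <- numeric(C); v <- numeric(C)
    for (c in seq_len(C)) {
      xc <- X[, c, ]
      m[c] <- mean(xc)
      v[c] <- mean((xc - m[c])^2)
    }
    layer$runMean <- (1 - layer$momentum) * layer$runMean + layer$momentum * m
    layer$runVar <- (1 - layer$momentum) * layer$runVar + layer$momentum * v
  } else {
    m <- layer$runMean
    v <- layer$runVar
  }
  inv <- 1 / sqrt(v + layer$eps)
  Y <- X
  xhat <- X
  for (c in seq_len(C)) {
    xh <- (X[, c, ] - m[c]) * inv[c]
    xhat[, c, ] <- xh
    Y[, c, ] <- xh * layer$gamma[c] + layer$beta[c]
  }
  list(Y = Y, cache = list(xhat = xhat, inv = inv), layer = layer)
}

.bnBackward <- function(layer, cache, dY) {
  d <- dim(dY)
  V <- d[1]; C <- d[2]; B <- d[3]
  n <- V * B
  dX <- dY
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dy <- dY[, c, ]
    xh <- cache$xhat[, c, ]
    dgamma[c] <- sum(dy * xh)
    dbeta[c] <- sum(dy)
    dxhat <- dy * layer$gamma[c]
    dX[, c, ] <- (cache$inv[c] / n) *
      (n * dxhat - sum(dxhat) - xh * sum(dxhat * xh))
  }
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

.layerForward <- function(layer, X, train) {
  switch(layer$type,
    conv = {
      Y <- conv3d_fwd_cpp(X, layer$W, layer$b, layer$D)
      list(Y = Y, cache = if (train) list(X = X), layer = layer)
    },
    pool = {
      r <- maxpool3d_fwd_cpp(X, layer$D)
      list(Y = r$Y, cache = list(idx = r$idx), layer = layer)
    },
    bn = .bnForward(layer, X, train),
    act = {
      if (layer$fun == "sigmoid") {
        Y <- 1 / (1 + exp(-X))
        list(Y = Y, cache = list(Y = Y), layer = layer)
      } else {
        Y <- pmax(X, 0)
        list(Y = Y, cache = list(mask = X > 0), layer = layer)
      }
    },
    flatten = {
      d <- dim(X)
      Y <- t(matrix(X, d[1] * d[2], d[3]))
      list(Y = Y, cache = list(dims = d), layer = layer)
    },
    fc = {
      Y <- X %*% layer$W + rep(layer$b, each = nrow(X))
      list(Y = Y, cache = list(X = X), layer = layer)
    },
    resblock = {
      r1 <- .bnForward(layer$bn1, X, train); layer$bn1 <- r1$layer
      a1 <- pmax(r1$Y, 0)
      c1 <- conv3d_fwd_cpp(a1, layer$conv1$W, layer$conv1$b, layer$D)
      r2 <- .bnForward(layer$bn2, c1, train); layer$bn2 <- r2$layer
      a2 <- pmax(r2$Y, 0)
      c2 <- conv3d_fwd_cpp(a2, layer$conv2$W, layer$conv2$b, layer$D)
      list(Y = X + c2,
           cache = if (train) list(bn1 = r1$cache, m1 = r1$Y > 0, a1 = a1,
                                   bn2 = r2$cache, m2 = r2$Y > 0, a2 = a2),
           layer = layer)
    },
    stop("unknown layer type ", layer$type))
}

.layerBackward <- function(layer, cache, dY, needDX = TRUE) {
  switch(layer$type,
    conv = {
      r <- conv3d_bwd_cpp(cache$X, layer$W, dY, layer$D, needDX)
      list(dX = r$dX, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    pool = list(dX = maxpool3d_bwd_cpp(cache$idx, dY, layer$D), grads = NULL),
    bn = .bnBackward(layer, cache, dY),
    act = {
      if (layer$fun == "sigmoid")
        list(dX = dY * cache$Y * (1 - cache$Y), grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    },
    flatten = list(dX = array(t(dY), dim = cache$dims), grads = NULL),
    fc = list(dX = dY %*% t(layer$W),
              grads = list(W = crossprod(cache$X, dY), b = colSums(dY))),
    resblock = {
      r2 <- conv3d_bwd_cpp(cache$a2, layer$conv2$W, dY, layer$D, TRUE)
      da2 <- r2$dX
      dh2 <- da2 * cache$m2
      b2 <- .bnBackward(layer$bn2, cache$bn2, dh2)
      r1 <- conv3d_bwd_cpp(cache$a1, layer$conv1$W, b2$dX, layer$D, TRUE)
      da1 <- r1$dX
      dh1 <- da1 * cache$m1
      b1 <- .bnBackward(layer$bn1, cache$bn1, dh1)
      list(dX = dY + b1$dX,
           grads = list(bn1 = b1$grads,
                        conv1 = list(W = r1$dW, b = as.numeric(r1$db)),
                        bn2 = b2$grads,
                        conv2 = list(W = r2$dW, b = as.numeric(r2$db))))
    },
    stop("unknown layer type ", layer$type))
}

#' Forward pass through a volumetric network
#'
#' @param net a \linkS4class{VolNet}.
#' @param X input batch: numeric array (M^3, 1, B) of occupancy values, or a
#'   single \linkS4class{VoxelGrid}.
#' @param train logical; TRUE uses batch statistics in batch-norm layers and
#'   updates their running statistics, FALSE (evaluation mode) uses the
#'   stored running statistics and is fully deterministic.
#' @return list with \code{out} (B x outDim raw output matrix), \code{caches}
#'   (per-layer activations for backprop) and \code{net} (with updated
#'   batch-norm running statistics when \code{train = TRUE}).
#' @export
netForward <- function(net, X, train = FALSE) {
  if (is(X, "VoxelGrid")) {
    M <- gridSide(X)
    X <- array(X@occupancy, dim = c(M^3, 1, 1))
  }
  caches <- vector("list", length(net@layers))
  for (i in seq_along(net@layers)) {
    r <- .layerForward(net@layers[[i]], X, train)
    X <- r$Y
    caches[[i]] <- r$cache
    net@layers[[i]] <- r$layer
  }
  list(out = X, caches = caches, net = net)
}

#' Backward pass through a volumetric network
#'
#' @param net a \linkS4class{VolNet}.
#' @param caches per-layer caches from \code{\link{netForward}} with
#'   \code{train = TRUE}.
#' @param dOut gradient of the loss with respect to the raw network output
#'   (B x outDim).
#' @return list of per-layer parameter gradients, parallel to
#'   \code{net@layers}.
#' @export
netBackward <- function(net, caches, dOut) {
  grads <- vector("list", length(net@layers))
  dY <- dOut
  for (i in rev(seq_along(net@layers))) {
    r <- .layerBackward(net@layers[[i]], caches[[i]], dY, needDX = i > 1)
    grads[i] <- list(r$grads)
    dY <- r$dX
  }
  grads
}

.validateNetConfig <- function(M, nBlocks, channels) {
  if (nBlocks < 2) stop("need at least 2 conv/pool blocks")
  if (length(channels) != nBlocks) stop("channels must have one entry per block")
  if (M %% (2^nBlocks) != 0 || M / 2^nBlocks < 1)
    stop("grid side ", M, " cannot survive ", nBlocks,
         " rounds of 2x pooling (spatial size would collapse below 1)")
}

#' Build the region-detection network
#'
#' Maps a 1-channel M^3 occupancy tensor to 36 raw values (six boxes of six
#' values). Each block is 3D convolution (3^3 kernel, stride 1, pad 1) ->
#' 2^3 max pooling -> batch norm -> sigmoid; blocks are followed by a
#' flatten, sigmoid-activated hidden dense layers, and a linear 36-unit
#' output. Raw outputs are decoded by \code{\link{decodeBoxes}} (tanh for
#' centers, softplus for half-extents) so invalid boxes are unrepresentable.
#'
#' @param config list with \code{M} (grid side), \code{nBlocks},
#'   \code{channels} (length nBlocks), \code{fcWidths} (hidden dense widths,
#'   may be empty).
#' @param seed optional RNG seed for weight initialization.
#' @return a \linkS4class{VolNet} of kind "detection".
#' @export
buildDetectionNet <- function(config = list(M = 32, nBlocks = 3,
                                            channels = c(8, 16, 32),
                                            fcWidths = 64),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- config$M; nBlocks <- config$nBlocks; channels <- config$channels
  .validateNetConfig(M, nBlocks, channels)
  layers <- list()
  D <- M; cin <- 1
  for (i in seq_len(nBlocks)) {
    layers <- c(layers, list(.newConv(cin, channels[i], D), .newPool(D),
                             .newBN(channels[i]), .newAct("sigmoid")))
    D <- D / 2
    cin <- channels[i]
  }
  layers <- c(layers, list(list(type = "flatten")))
  nin <- D^3 * cin
  for (w in config$fcWidths) {
    layers <- c(layers, list(.newFC(nin, w), .newAct("sigmoid")))
    nin <- w
  }
  layers <- c(layers, list(.newFC(nin, 36)))
  config$outDim <- 36L
  new("VolNet", layers = layers, config = config, kind = "detection")
}

#' Build a per-region landmark prediction network
#'
#' Same conv/pool/batch-norm/sigmoid cycles as the detection network,
#' followed by a stage of \code{nResBlocks} pre-activation two-convolution
#' volumetric residual blocks (the 18-layer residual layout transposed to
#' 3D, randomly initialized), a flatten, hidden dense layers, and a linear
#' 3N-unit output, where N is the region's landmark count.
#'
#' @param config list with \code{M}, \code{nBlocks}, \code{channels},
#'   \code{fcWidths}, \code{nResBlocks} (default 8), and \code{N} (landmark
#'   count) or \code{organ} (from which N is looked up).
#' @param seed optional RNG seed for weight initialization.
#' @return a \linkS4class{VolNet} of kind "prediction".
#' @export
buildPredictionNet <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config$N)) config$N <- organSpec(config$organ)$n_landmarks
  if (is.null(config$nResBlocks)) config$nResBlocks <- 8L
  M <- config$M; nBlocks <- config$nBlocks; channels <- config$channels
  .validateNetConfig(M, nBlocks, channels)
  layers <- list()
  D <- M; cin <- 1
  for (i in seq_len(nBlocks)) {
    layers <- c(layers, list(.newConv(cin, channels[i], D), .newPool(D),
                             .newBN(channels[i]), .newAct("sigmoid")))
    D <- D / 2
    cin <- channels[i]
  }
  for (i in seq_len(config$nResBlocks))
    layers <- c(layers, list(.newResBlock(cin, D)))
  layers <- c(layers, list(list(type = "flatten")))
  nin <- D^3 * cin
  for (w in config$fcWidths) {
    layers <- c(layers, list(.newFC(nin, w), .newAct("sigmoid")))
    nin <- w
  }
  layers <- c(layers, list(.newFC(nin, 3L * config$N)))
  config$outDim <- 3L * config$N
  new("VolNet", layers = layers, config = config, kind = "prediction")
}

#' Decode raw detection outputs into valid boxes
#'
#' Centers pass through tanh (onto (-1, 1)); half-extents through
#' softplus plus a floor of 1e-3 (strictly positive). Columns are organ-major:
#' organ k occupies columns 6(k-1)+1 .. 6k as (x, y, z, xl, yl, zl).
#'
#' @param raw numeric B x 36 matrix of raw network outputs.
#' @return B x 36 matrix of decoded box values.
#' @export
decodeBoxes <- function(raw) {
  if (is.null(dim(raw))) raw <- matrix(raw, 1)
  dec <- raw
  ctr <- .boxCenterCols
  dec[, ctr] <- tanh(raw[, ctr])
  dec[, -ctr] <- .softplus(raw[, -ctr]) + 1e-3
  dec
}

.boxCenterCols <- as.vector(outer(1:3, (0:5) * 6, "+"))

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Chain rule through decodeBoxes: elementwise d(decoded)/d(raw).
.decodeBoxesGrad <- function(raw, dec) {
  g <- raw
  ctr <- .boxCenterCols
  g[, ctr] <- 1 - dec[, ctr]^2
  g[, -ctr] <- 1 / (1 + exp(-raw[, -ctr]))
  g
}

# Decoded B x 36 row -> OrganBoxSet.
.rowToBoxSet <- function(v) {
  b <- matrix(v, 6, 6, byrow = TRUE,
              dimnames = list(organNames(), c("x", "y", "z", "xl", "yl", "zl")))
  new("OrganBoxSet", boxes = b)
}

#' Flatten an OrganBoxSet into the 36-vector network target
#'
#' @param boxes an \linkS4class{OrganBoxSet}.
#' @return numeric length-36 vector, organ-major.
#' @export
flattenBoxes <- function(boxes) as.numeric(t(boxMatrix(boxes)))
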