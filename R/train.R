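# Adam optimization over the layer parameter trees, and the two training
# loops (detection and per-region prediction). Both loops are fully
# deterministic for a fixed seed on one device: the seed drives minibatch
# shuffling only, weight initialization is seeded at build time.

.layerParamNames <- function(layer)
  switch(layer$type,
         conv = c("W", "b"), fc = c("W", "b"), bn = c("gamma", "beta"),
         NULL)

.adamInitLayer <- function(layer) {
  if (layer$type == "resblock")
    return(list(bn1 = .adamInitLayer(layer$bn1),
                conv1 = .adamInitLayer(layer$conv1),
                bn2 = .adamInitLayer(layer$bn2),
                conv2 = .adamInitLayer(layer$conv2)))
  nms <- .layerParamNames(layer)
  if (is.null(nms)) return(NULL)
  st <- list()
  for (nm in nms) st[[nm]] <- list(m = layer[[nm]] * 0, v = layer[[nm]] * 0)
  st
}

.adamStepLayer <- function(layer, grad, state, lr, beta1, beta2, eps, corr) {
  if (is.null(grad)) return(list(layer = layer, state = state))
  if (layer$type == "resblock") {
    for (part in c("bn1", "conv1", "bn2", "conv2")) {
      r <- .adamStepLayer(layer[[part]], grad[[part]], state[[part]],
                          lr, beta1, beta2, eps, corr)
      layer[[part]] <- r$layer
      state[[part]] <- r$state
    }
    return(list(layer = layer, state = state))
  }
  for (nm in .layerParamNames(layer)) {
    g <- grad[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    layer[[nm]] <- layer[[nm]] - lr * (st$m / corr$m) / (sqrt(st$v / corr$v) + eps)
    state[[nm]] <- st
  }
  list(layer = layer, state = state)
}

.adamInit <- function(net) list(t = 0L, layers = lapply(net@layers, .adamInitLayer))

.adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr <- list(m = 1 - beta1^state$t, v = 1 - beta2^state$t)
  for (i in seq_along(net@layers)) {
    r <- .adamStepLayer(net@layers[[i]], grads[[i]], state$layers[[i]],
                        lr, beta1, beta2, eps, corr)
    net@layers[[i]] <- r$layer
    state$layers[i] <- list(r$state)
  }
  list(net = net, state = state)
}

.stackGrids <- function(grids) {
  V <- gridSide(grids[[1]])^3
  X <- array(0, dim = c(V, 1, length(grids)))
  for (i in seq_along(grids)) X[, 1, i] <- as.numeric(grids[[i]]@occupancy)
  X
}

.checkpoint <- function(net, dir, every, epoch, seed, history) {
  if (is.null(dir) || every <= 0 || epoch %% every != 0) return(invisible())
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveNetCheckpoint(net, file.path(dir, sprintf("epoch_%04d.rds", epoch)),
                    seed = seed, epoch = epoch, history = history)
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single archive holding the model weights, its config,
#' the training seed and the epoch reached.
#'
#' @param net a \linkS4class{VolNet}.
#' @param path file path.
#' @param seed,epoch,history training metadata stored alongside the weights.
#' @return \code{saveNetCheckpoint}: the path, invisibly;
#'   \code{loadNetCheckpoint}: a list with \code{net}, \code{config},
#'   \code{seed}, \code{epoch}, \code{history}.
#' @export
saveNetCheckpoint <- function(net, path, seed = NA, epoch = NA, history = NULL) {
  saveRDS(list(net = net, config = net@config, seed = seed, epoch = epoch,
               history = history), path)
  invisible(path)
}

#' @rdname saveNetCheckpoint
#' @export
loadNetCheckpoint <- function(path) readRDS(path)

#' Train the region-detection network
#'
#' Minimizes the detection box loss with Adam over minibatches. The per-epoch
#' mean training loss is recorded; training aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param net a detection \linkS4class{VolNet}.
#' @param grids list of \linkS4class{VoxelGrid} (one per face).
#' @param boxes list of \linkS4class{OrganBoxSet} targets (normalized frame).
#' @param epochs number of epochs.
#' @param lr Adam learning rate (0 leaves the weights untouched).
#' @param batchSize minibatch size.
#' @param lambda1,lambda2 center / size loss weights (sum to 1).
#' @param seed RNG seed for minibatch shuffling.
#' @param sizeTerm size-error form, see \code{\link{detectionLoss}}.
#' @param valGrids,valBoxes optional validation data; when given, the
#'   returned network is the checkpoint with the lowest validation loss
#'   (convergence-aware model selection) and \code{valHistory} /
#'   \code{bestEpoch} are reported.
#' @param patience with validation data: stop after this many epochs without
#'   validation improvement (\code{Inf} trains to the full epoch count).
#' @param checkpointDir,checkpointEvery optional checkpoint directory and
#'   epoch cadence (0 disables).
#' @param verbose print the loss every few epochs.
#' @return list with \code{net} (trained) and \code{history} (numeric vector
#'   of per-epoch mean losses); with validation data also \code{valHistory}
#'   and \code{bestEpoch}.
#' @export
trainDetector <- function(net, grids, boxes, epochs, lr = 1e-3,
                          batchSize = 10, lambda1 = 0.5,
                          lambda2 = 1 - lambda1, seed = 1,
                          sizeTerm = "squared_diff",
                          valGrids = NULL, valBoxes = NULL, patience = Inf,
                          checkpointDir = NULL, checkpointEvery = 0,
                          verbose = FALSE) {
  n <- length(grids)
  if (n == 0) stop("empty dataset")
  if (length(boxes) != n) stop("grids and boxes must have the same length")
  .checkLambdas(lambda1, lambda2)
  X <- .stackGrids(grids)
  Tmat <- do.call(rbind, lapply(boxes, flattenBoxes))
  useVal <- length(valGrids) > 0
  if (useVal) {
    XV <- .stackGrids(valGrids)
    TV <- do.call(rbind, lapply(valBoxes, flattenBoxes))
  }
  set.seed(seed)
  state <- .adamInit(net)
  history <- numeric(epochs)
  valHistory <- if (useVal) numeric(epochs) else NULL
  best <- list(loss = Inf, net = net, epoch = 0L)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = batchSize)) {
      b <- idx[start:min(start + batchSize - 1, n)]
      fw <- netForward(net, X[, , b, drop = FALSE], train = TRUE)
      net <- fw$net
      dec <- decodeBoxes(fw$out)
      lb <- .detectionLossBatch(dec, Tmat[b, , drop = FALSE], lambda1,
                                lambda2, sizeTerm)
      if (!is.finite(lb$loss))
        stop("detection training diverged (non-finite loss) at epoch ", ep)
      dRaw <- lb$grad * .decodeBoxesGrad(fw$out, dec)
      grads <- netBackward(net, fw$caches, dRaw)
      upd <- .adamStep(net, grads, state, lr)
      net <- upd$net
      state <- upd$state
      tot <- tot + lb$loss * length(b)
    }
    history[ep] <- tot / n
    if (useVal) {
      vdec <- decodeBoxes(netForward(net, XV, train = FALSE)$out)
      valHistory[ep] <- .detectionLossBatch(vdec, TV, lambda1, lambda2,
                                            sizeTerm)$loss
      if (valHistory[ep] < best$loss)
        best <- list(loss = valHistory[ep], net = net, epoch = ep)
    }
    if (verbose && (ep == 1 || ep %% 10 == 0))
      message(sprintf("detect epoch %d loss %.6f", ep, history[ep]))
    .checkpoint(net, checkpointDir, checkpointEvery, ep, seed, history[seq_len(ep)])
    if (useVal && ep - best$epoch >= patience) {
      history <- history[seq_len(ep)]
      valHistory <- valHistory[seq_len(ep)]
      break
    }
  }
  if (useVal)
    list(net = best$net, history = history, valHistory = valHistory,
         bestEpoch = best$epoch)
  else list(net = net, history = history)
}

#' Train one region's landmark prediction network
#'
#' Minimizes the combined mean/max squared-distance loss with Adam. Each
#' region has its own independent parameter set; training one region never
#' touches another's network.
#'
#' @param net a prediction \linkS4class{VolNet} for this region.
#' @param grids list of region \linkS4class{VoxelGrid} (cropped and
#'   re-voxelized).
#' @param targets list of N x 3 landmark coordinate matrices in the region
#'   frame, rows in registry order.
#' @inheritParams trainDetector
#' @param lambda1,lambda2 mean / max loss weights (sum to 1).
#' @param valTargets validation targets matching \code{valGrids}.
#' @return list with \code{net} and \code{history}; with validation data also
#'   \code{valHistory} and \code{bestEpoch}.
#' @export
trainPredictor <- function(net, grids, targets, epochs, lr = 1e-3,
                           batchSize = 10, lambda1 = 0.5,
                           lambda2 = 1 - lambda1, seed = 1,
                           valGrids = NULL, valTargets = NULL, patience = Inf,
                           checkpointDir = NULL, checkpointEvery = 0,
                           verbose = FALSE) {
  n <- length(grids)
  if (n == 0) stop("empty dataset")
  if (length(targets) != n) stop("grids and targets must have the same length")
  .checkLambdas(lambda1, lambda2)
  N <- net@config$N
  X <- .stackGrids(grids)
  useVal <- length(valGrids) > 0
  if (useVal) XV <- .stackGrids(valGrids)
  set.seed(seed)
  state <- .adamInit(net)
  history <- numeric(epochs)
  valHistory <- if (useVal) numeric(epochs) else NULL
  best <- list(loss = Inf, net = net, epoch = 0L)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = batchSize)) {
      b <- idx[start:min(start + batchSize - 1, n)]
      fw <- netForward(net, X[, , b, drop = FALSE], train = TRUE)
      net <- fw$net
      raw <- fw$out
      dRaw <- raw * 0
      bl <- 0
      for (s in seq_along(b)) {
        pm <- matrix(raw[s, ], N, 3, byrow = TRUE)
        tm <- targets[[b[s]]]
        bl <- bl + lossCombined(pm, tm, lambda1, lambda2)
        dRaw[s, ] <- as.vector(t(.combinedLossGrad(pm, tm, lambda1, lambda2))) /
          length(b)
      }
      bl <- bl / length(b)
      if (!is.finite(bl))
        stop("prediction training diverged (non-finite loss) at epoch ", ep)
      grads <- netBackward(net, fw$caches, dRaw)
      upd <- .adamStep(net, grads, state, lr)
      net <- upd$net
      state <- upd$state
      tot <- tot + bl * length(b)
    }
    history[ep] <- tot / n
    if (useVal) {
      vraw <- netForward(net, XV, train = FALSE)$out
      vl <- 0
      for (s in seq_len(nrow(vraw)))
        vl <- vl + lossCombined(matrix(vraw[s, ], N, 3, byrow = TRUE),
                                valTargets[[s]], lambda1, lambda2)
      valHistory[ep] <- vl / nrow(vraw)
      if (valHistory[ep] < best$loss)
        best <- list(loss = valHistory[ep], net = net, epoch = ep)
    }
    if (verbose && (ep == 1 || ep %% 10 == 0))
      message(sprintf("predict epoch %d loss %.6f", ep, history[ep]))
    .checkpoint(net, checkpointDir, checkpointEvery, ep, seed, history[seq_len(ep)])
    if (useVal && ep - best$epoch >= patience) {
      history <- history[seq_len(ep)]
      valHistory <- valHistory[seq_len(ep)]
      break
    }
  }
  if (useVal)
    list(net = best$net, history = history, valHistory = valHistory,
         bestEpoch = best$epoch)
  else list(net = net, history = history)
}
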