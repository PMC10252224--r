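# End-to-end orchestration: dataset preparation for both training stages,
# the coarse-to-fine inference path (normalize -> voxelize -> detect boxes ->
# crop regions -> regress landmarks -> restore mm), the box-center baseline,
# and the cached multi-stage pipeline runner.

#' Prepare detection training data from synthetic faces
#'
#' @param faces list of \linkS4class{SyntheticFace}.
#' @param M face-level grid side.
#' @return list with \code{grids} (list of \linkS4class{VoxelGrid}) and
#'   \code{boxes} (list of \linkS4class{OrganBoxSet}).
#' @export
prepareDetectionData <- function(faces, M) {
  grids <- lapply(faces, function(f) voxelize(normalizeCloud(f@cloud), M))
  boxes <- lapply(faces, function(f) f@boxes)
  list(grids = grids, boxes = boxes)
}

#' Prepare one region's prediction training data
#'
#' Crops each face's region using its ground-truth box, re-voxelizes the
#' crop, and expresses the region's landmarks in the crop's own normalized
#' frame (the network target frame).
#'
#' @param faces list of \linkS4class{SyntheticFace}.
#' @param organ region name.
#' @param MOrgan region grid side.
#' @param margin crop margin multiplier.
#' @param boxes optional list of \linkS4class{OrganBoxSet}, parallel to
#'   \code{faces}, to crop with (e.g. detected boxes); default uses each
#'   face's ground-truth boxes.
#' @return list with \code{grids} and \code{targets} (N x 3 matrices in the
#'   region frame, rows in registry order).
#' @export
preparePredictionData <- function(faces, organ, MOrgan, margin = 1.1,
                                  boxes = NULL) {
  spec <- organSpec(organ)
  grids <- vector("list", length(faces))
  targets <- vector("list", length(faces))
  for (i in seq_along(faces)) {
    f <- faces[[i]]
    nc <- normalizeCloud(f@cloud)
    bset <- if (is.null(boxes)) f@boxes else boxes[[i]]
    crop <- cropOrgan(nc, boxMatrix(bset)[organ, ], margin = margin,
                      MOrgan = MOrgan)
    lmm <- landmarkCoords(f)[spec$landmark_names, , drop = FALSE]
    grids[[i]] <- crop$grid
    targets[[i]] <- toNormalized(lmm, crop$transform)
  }
  list(grids = grids, targets = targets)
}

#' Predict all 32 landmarks of a face in millimetres
#'
#' The full coarse-to-fine path: normalize the cloud, voxelize it, detect
#' the six region boxes, crop and re-voxelize each region, regress the
#' region's landmarks in its own frame, and map them back to the original
#' mm frame through the composed transforms.
#'
#' @param detector trained detection \linkS4class{VolNet}.
#' @param predictors named list of six trained prediction
#'   \linkS4class{VolNet}s, names = \code{organNames()}.
#' @param cloud a \linkS4class{FaceCloud} (mm).
#' @param margin crop margin multiplier; if a region crop comes up empty the
#'   margin is enlarged once (x1.5) before failing with the region named.
#' @return a \linkS4class{LandmarkSet} (mm) with the 32 registry landmarks.
#' @export
predictLandmarksMm <- function(detector, predictors, cloud, margin = 1.1) {
  missing <- setdiff(organNames(), names(predictors))
  if (length(missing) > 0)
    stop("missing predictor(s) for: ", paste(missing, collapse = ", "))
  nc <- normalizeCloud(cloud)
  g <- voxelize(nc, detector@config$M)
  raw <- netForward(detector, g, train = FALSE)$out
  boxes <- .rowToBoxSet(decodeBoxes(raw)[1, ])
  reg <- landmarkRegistry()
  out <- matrix(NA_real_, 32, 3, dimnames = list(reg$name, NULL))
  for (org in organNames()) {
    pnet <- predictors[[org]]
    crop <- tryCatch(
      cropOrgan(nc, boxMatrix(boxes)[org, ], margin = margin,
                MOrgan = pnet@config$M),
      facemark3d_empty_crop = function(e)
        tryCatch(cropOrgan(nc, boxMatrix(boxes)[org, ], margin = 1.5 * margin,
                           MOrgan = pnet@config$M),
                 facemark3d_empty_crop = function(e2)
                   stop("empty organ crop for region '", org, "': ",
                        conditionMessage(e2))))
    praw <- netForward(pnet, crop$grid, train = FALSE)$out
    pm <- matrix(praw[1, ], pnet@config$N, 3, byrow = TRUE)
    out[organSpec(org)$landmark_names, ] <- toMm(pm, crop$transform)
  }
  landmarkSet(out, unit = "mm")
}

#' Box-center baseline landmarks
#'
#' The naive baseline: predict the center of each region's ground-truth box
#' for every landmark of that region. Any useful landmark model must beat
#' this.
#'
#' @param face a \linkS4class{SyntheticFace}.
#' @return a \linkS4class{LandmarkSet} (mm).
#' @export
baselineLandmarks <- function(face) {
  reg <- landmarkRegistry()
  out <- matrix(NA_real_, 32, 3, dimnames = list(reg$name, NULL))
  bm <- boxMatrix(face@boxes)
  for (org in organNames()) {
    ctrMm <- toMm(bm[org, 1:3], face@transform)
    nm <- organSpec(org)$landmark_names
    out[nm, ] <- matrix(ctrMm, length(nm), 3, byrow = TRUE)
  }
  landmarkSet(out, unit = "mm")
}

#' Evaluate trained networks on a set of faces
#'
#' Runs the full inference path on each face, compares against the known
#' landmarks, and additionally reports the mean detection box IoU against
#' the ground-truth boxes.
#'
#' @param detector,predictors trained networks as in
#'   \code{\link{predictLandmarksMm}}.
#' @param faces list of \linkS4class{SyntheticFace}.
#' @param margin crop margin multiplier.
#' @return list with \code{errors} (error table), \code{summary}
#'   (\code{\link{summarizeErrors}} result), \code{meanIoU}, \code{iouByOrgan},
#'   and \code{predictions} (list of \linkS4class{LandmarkSet}).
#' @export
evaluateFaces <- function(detector, predictors, faces, margin = 1.1) {
  preds <- vector("list", length(faces))
  ious <- matrix(0, length(faces), 6, dimnames = list(NULL, organNames()))
  for (i in seq_along(faces)) {
    f <- faces[[i]]
    nc <- normalizeCloud(f@cloud)
    g <- voxelize(nc, detector@config$M)
    raw <- netForward(detector, g, train = FALSE)$out
    pb <- .rowToBoxSet(decodeBoxes(raw)[1, ])
    tb <- boxMatrix(f@boxes)
    for (org in organNames())
      ious[i, org] <- boxIoU(boxMatrix(pb)[org, ], tb[org, ])
    preds[[i]] <- predictLandmarksMm(detector, predictors, f@cloud,
                                     margin = margin)
  }
  tab <- errorTable(preds, lapply(faces, function(f) f@landmarks))
  list(errors = tab, summary = summarizeErrors(tab), meanIoU = mean(ious),
       iouByOrgan = colMeans(ious), predictions = preds)
}

#' Pipeline run configuration
#'
#' Assembles and validates the configuration for \code{\link{runPipeline}}.
#' Defaults follow the full-scale study settings (grid side M = 200, 600
#' detection epochs, 500 prediction epochs, batches of up to 10); scaled-down
#' runs override them.
#'
#' @param outDir output directory; every run writes its resolved config there.
#' @param nFaces number of synthetic faces.
#' @param split named train/test/val fractions.
#' @param M face-level grid side.
#' @param MOrgan region grid side; NULL means "same as M".
#' @param K points per face.
#' @param noiseSd surface noise sd, mm.
#' @param paramsRanges per-face parameter ranges
#'   (default \code{\link{defaultParamRanges}}).
#' @param epochsDetect,epochsPredict training epochs per stage.
#' @param lambdaDetect,lambdaPredict weight lambda1 of each stage's loss
#'   (lambda2 = 1 - lambda1).
#' @param batchSize minibatch size.
#' @param lrDetect,lrPredict Adam learning rates.
#' @param margin crop margin multiplier.
#' @param detChannels,detFcWidths,predChannels,predFcWidths,nResBlocks
#'   network architecture settings.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) used when the validation split is nonempty; \code{Inf}
#'   keeps training for the full epoch count and only selects the
#'   best-validation checkpoint.
#' @param checkpointEvery checkpoint cadence in epochs (0 disables).
#' @param seed master seed; all stage seeds derive from it.
#' @return validated config list of class "facemarkConfig".
#' @export
runConfig <- function(outDir, nFaces = 500,
                      split = c(train = 0.7, test = 0.2, val = 0.1),
                      M = 200, MOrgan = NULL, K = 20000, noiseSd = 0.3,
                      paramsRanges = defaultParamRanges(),
                      epochsDetect = 600, epochsPredict = 500,
                      lambdaDetect = 0.5, lambdaPredict = 0.5,
                      batchSize = 10, lrDetect = 1e-3, lrPredict = 1e-3,
                      margin = 1.1, detChannels = c(8, 16, 32),
                      detFcWidths = 64, predChannels = c(8, 16, 32),
                      predFcWidths = 64, nResBlocks = 8, patience = Inf,
                      checkpointEvery = 0, seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$MOrgan)) cfg$MOrgan <- M
  stopifnot(nFaces >= 10, M >= 4, cfg$MOrgan >= 4, K >= 1000,
            epochsDetect >= 1, epochsPredict >= 1, batchSize >= 1,
            margin >= 1, noiseSd >= 0,
            lambdaDetect >= 0, lambdaDetect <= 1,
            lambdaPredict >= 0, lambdaPredict <= 1)
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "facemarkConfig"
  cfg
}

.configMd5 <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

.stageFresh <- function(dir, key, outputs) {
  keyFile <- file.path(dir, "stage_key")
  file.exists(keyFile) && identical(readLines(keyFile, warn = FALSE), key) &&
    all(file.exists(file.path(dir, outputs)))
}

.stageDone <- function(dir, key) writeLines(key, file.path(dir, "stage_key"))

#' Run the full pipeline
#'
#' Executes simulate -> train-detect -> train-predict -> infer -> evaluate
#' in order, writing artifacts under \code{config$outDir}. Completed stages
#' are skipped when their content key (an md5 of the stage's resolved
#' configuration plus its upstream keys) matches the stored one; changing
#' any relevant setting, including the seed, re-executes the affected
#' stages. A failing stage halts the run with its name.
#'
#' @param config a \code{\link{runConfig}} list.
#' @param stages subset of stages to run (prerequisites must already exist).
#' @param verbose print progress messages.
#' @return list with the evaluation \code{summary}, \code{symmetry} report,
#'   \code{meanIoU}, \code{history} (training loss histories) and
#'   \code{artifacts} (paths), invisibly.
#' @export
runPipeline <- function(config, stages = c("simulate", "train-detect",
                                           "train-predict", "infer",
                                           "evaluate"),
                        verbose = FALSE) {
  stopifnot(inherits(config, "facemarkConfig"))
  od <- config$outDir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config[setdiff(names(config), "outDir")],
                       file.path(od, "config.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  say <- function(...) if (verbose) message(...)
  dirs <- file.path(od, c(simulate = "01_simulate", detect = "02_detect",
                          predict = "03_predict", infer = "04_infer",
                          evaluate = "05_evaluate"))
  names(dirs) <- c("simulate", "detect", "predict", "infer", "evaluate")
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)

  # --- simulate ---------------------------------------------------------
  simKey <- .configMd5(list(stage = "simulate", nFaces = config$nFaces,
                            split = config$split, K = config$K,
                            noiseSd = config$noiseSd,
                            ranges = config$paramsRanges, seed = config$seed))
  simOut <- "dataset.rds"
  if ("simulate" %in% stages && .stageFresh(dirs["simulate"], simKey, simOut))
    say("stage simulate: cached")
  if ("simulate" %in% stages &&
      !.stageFresh(dirs["simulate"], simKey, simOut)) {
    say("stage simulate: generating ", config$nFaces, " faces")
    ds <- tryCatch(
      generateDataset(config$nFaces, paramsRanges = config$paramsRanges,
                      split = config$split, seed = config$seed,
                      baseParams = faceParams(noiseSd = config$noiseSd,
                                              K = config$K)),
      error = function(e) stop("stage 'simulate' failed: ", conditionMessage(e)))
    saveRDS(ds, file.path(dirs["simulate"], simOut))
    utils::write.csv(ds$manifest, file.path(dirs["simulate"], "manifest.csv"),
                     row.names = FALSE)
    .stageDone(dirs["simulate"], simKey)
  }
  if (!file.exists(file.path(dirs["simulate"], simOut)))
    stop("no simulated dataset under ", od, "; run the simulate stage first")
  ds <- readRDS(file.path(dirs["simulate"], simOut))

  # --- train-detect -----------------------------------------------------
  detCfg <- list(M = config$M, nBlocks = length(config$detChannels),
                 channels = config$detChannels, fcWidths = config$detFcWidths)
  detKey <- .configMd5(list(stage = "detect", up = simKey, cfg = detCfg,
                            epochs = config$epochsDetect,
                            lambda = config$lambdaDetect,
                            batch = config$batchSize, lr = config$lrDetect,
                            seed = config$seed))
  if ("train-detect" %in% stages &&
      .stageFresh(dirs["detect"], detKey, "detector.rds"))
    say("stage train-detect: cached")
  if ("train-detect" %in% stages &&
      !.stageFresh(dirs["detect"], detKey, "detector.rds")) {
    say("stage train-detect: ", config$epochsDetect, " epochs")
    res <- tryCatch({
      dd <- prepareDetectionData(ds$train, config$M)
      dv <- if (length(ds$val) > 0) prepareDetectionData(ds$val, config$M)
      net <- buildDetectionNet(detCfg, seed = config$seed + 101L)
      trainDetector(net, dd$grids, dd$boxes, epochs = config$epochsDetect,
                    lr = config$lrDetect, batchSize = config$batchSize,
                    lambda1 = config$lambdaDetect, seed = config$seed + 11L,
                    valGrids = dv$grids, valBoxes = dv$boxes,
                    patience = config$patience,
                    checkpointDir = if (config$checkpointEvery > 0)
                      file.path(dirs["detect"], "checkpoints") else NULL,
                    checkpointEvery = config$checkpointEvery,
                    verbose = verbose)
    }, error = function(e) stop("stage 'train-detect' failed: ",
                                conditionMessage(e)))
    saveNetCheckpoint(res$net, file.path(dirs["detect"], "detector.rds"),
                      seed = config$seed, epoch = config$epochsDetect,
                      history = res$history)
    utils::write.csv(data.frame(epoch = seq_along(res$history),
                                loss = res$history),
                     file.path(dirs["detect"], "detect_log.csv"),
                     row.names = FALSE)
    .stageDone(dirs["detect"], detKey)
  }

  # --- train-predict ----------------------------------------------------
  predCfgBase <- list(M = config$MOrgan, nBlocks = length(config$predChannels),
                      channels = config$predChannels,
                      fcWidths = config$predFcWidths,
                      nResBlocks = config$nResBlocks)
  predKey <- .configMd5(list(stage = "predict", up = simKey, cfg = predCfgBase,
                             epochs = config$epochsPredict,
                             lambda = config$lambdaPredict,
                             batch = config$batchSize, lr = config$lrPredict,
                             margin = config$margin, seed = config$seed))
  predOut <- paste0("predictor_", organNames(), ".rds")
  if ("train-predict" %in% stages &&
      .stageFresh(dirs["predict"], predKey, predOut))
    say("stage train-predict: cached")
  if ("train-predict" %in% stages &&
      !.stageFresh(dirs["predict"], predKey, predOut)) {
    for (oi in seq_along(organNames())) {
      org <- organNames()[oi]
      say("stage train-predict: region ", org)
      res <- tryCatch({
        pd <- preparePredictionData(ds$train, org, config$MOrgan,
                                    margin = config$margin)
        pv <- if (length(ds$val) > 0)
          preparePredictionData(ds$val, org, config$MOrgan,
                                margin = config$margin)
        cfg <- c(predCfgBase, list(organ = org))
        net <- buildPredictionNet(cfg, seed = config$seed + 200L + oi)
        trainPredictor(net, pd$grids, pd$targets,
                       epochs = config$epochsPredict, lr = config$lrPredict,
                       batchSize = config$batchSize,
                       lambda1 = config$lambdaPredict,
                       seed = config$seed + 20L + oi,
                       valGrids = pv$grids, valTargets = pv$targets,
                       patience = config$patience,
                       checkpointDir = if (config$checkpointEvery > 0)
                         file.path(dirs["predict"], paste0("checkpoints_", org))
                       else NULL,
                       checkpointEvery = config$checkpointEvery,
                       verbose = verbose)
      }, error = function(e) stop("stage 'train-predict' (", org,
                                  ") failed: ", conditionMessage(e)))
      saveNetCheckpoint(res$net,
                        file.path(dirs["predict"],
                                  paste0("predictor_", org, ".rds")),
                        seed = config$seed, epoch = config$epochsPredict,
                        history = res$history)
      utils::write.csv(data.frame(epoch = seq_along(res$history),
                                  loss = res$history),
                       file.path(dirs["predict"],
                                 paste0("predict_log_", org, ".csv")),
                       row.names = FALSE)
    }
    .stageDone(dirs["predict"], predKey)
  }

  # --- infer + evaluate -------------------------------------------------
  if (!any(stages %in% c("infer", "evaluate")))
    return(invisible(list(artifacts = list(outDir = od, dirs = as.list(dirs)))))
  needed <- c(file.path(dirs["detect"], "detector.rds"),
              file.path(dirs["predict"], predOut))
  if (!all(file.exists(needed)))
    stop("trained checkpoints are missing under ", od,
         "; run the train-detect and train-predict stages first")
  detector <- loadNetCheckpoint(file.path(dirs["detect"], "detector.rds"))$net
  predictors <- lapply(stats::setNames(organNames(), organNames()),
    function(org) loadNetCheckpoint(
      file.path(dirs["predict"], paste0("predictor_", org, ".rds")))$net)
  infKey <- .configMd5(list(stage = "infer", up = c(detKey, predKey),
                            margin = config$margin))
  if ("infer" %in% stages && .stageFresh(dirs["infer"], infKey, "eval.rds"))
    say("stage infer: cached")
  if ("infer" %in% stages && !.stageFresh(dirs["infer"], infKey, "eval.rds")) {
    say("stage infer: ", length(ds$test), " test faces")
    ev <- tryCatch(
      evaluateFaces(detector, predictors, ds$test, margin = config$margin),
      error = function(e) stop("stage 'infer' failed: ", conditionMessage(e)))
    saveRDS(ev, file.path(dirs["infer"], "eval.rds"))
    .stageDone(dirs["infer"], infKey)
  }
  if (!file.exists(file.path(dirs["infer"], "eval.rds")))
    stop("no inference results under ", od, "; run the infer stage first")
  ev <- readRDS(file.path(dirs["infer"], "eval.rds"))

  if ("evaluate" %in% stages) {
    utils::write.csv(ev$errors, file.path(dirs["evaluate"], "errors.csv"),
                     row.names = FALSE)
    utils::write.csv(ev$summary$perOrgan,
                     file.path(dirs["evaluate"], "per_organ.csv"),
                     row.names = FALSE)
    sym <- symmetryReport(ev$errors)
    utils::write.csv(sym, file.path(dirs["evaluate"], "symmetry.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(overall = ev$summary$overall,
                              coverage = ev$summary$coverage,
                              meanIoU = ev$meanIoU,
                              iouByOrgan = as.list(ev$iouByOrgan)),
                         file.path(dirs["evaluate"], "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(formatSummary(ev$summary),
               file.path(dirs["evaluate"], "summary.txt"))
  }
  hist <- list(
    detect = tryCatch(utils::read.csv(file.path(dirs["detect"],
                                                "detect_log.csv")),
                      error = function(e) NULL))
  invisible(list(summary = ev$summary,
                 symmetry = symmetryReport(ev$errors),
                 meanIoU = ev$meanIoU, iouByOrgan = ev$iouByOrgan,
                 errors = ev$errors, history = hist,
                 artifacts = list(outDir = od, dirs = as.list(dirs))))
}
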