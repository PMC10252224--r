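# Millimetre-scale evaluation: the scaled Euclidean error metric, the error
# table, summary statistics (per-landmark mean +/- sd, overall mean +/- sd,
# threshold coverage, per-region quartiles) and the left-right symmetry
# report.

#' Landmark error in millimetres from normalized-frame coordinates
#'
#' L = S * sqrt((x - x_hat)^2 + (y - y_hat)^2 + (z - z_hat)^2): the Euclidean
#' distance in the shared normalized frame, restored to mm by the recorded
#' scaling multiplier S. Equals the plain mm-frame distance when both points
#' are mapped back through the same transform.
#'
#' @param pred,true 3-vectors or N x 3 matrices in the same normalized frame.
#' @param S positive scaling multiplier (mm per normalized unit).
#' @return nonnegative error(s) in mm.
#' @export
landmarkErrorMm <- function(pred, true, S) {
  if (length(S) != 1L || !is.finite(S) || S <= 0)
    stop("S must be a single positive number")
  if (is.null(dim(pred))) return(S * sqrt(sum((pred - true)^2)))
  S * sqrt(rowSums((pred - true)^2))
}

#' Build an error table from predicted and true landmark sets
#'
#' One row per evaluated face x landmark, with the mm error and the
#' landmark's registry metadata. Both sets must be in mm; landmarks are
#' matched by name and only names present in both are evaluated.
#'
#' @param predSets list of predicted \linkS4class{LandmarkSet} (mm).
#' @param trueSets list of ground-truth \linkS4class{LandmarkSet} (mm),
#'   parallel to \code{predSets}.
#' @param faceIds optional character vector of face identifiers.
#' @return data.frame with columns \code{face_id}, \code{landmark},
#'   \code{organ}, \code{laterality}, \code{error_mm}.
#' @export
errorTable <- function(predSets, trueSets, faceIds = NULL) {
  stopifnot(length(predSets) == length(trueSets))
  if (is.null(faceIds)) faceIds <- sprintf("face_%03d", seq_along(predSets))
  reg <- landmarkRegistry()
  rows <- lapply(seq_along(predSets), function(i) {
    p <- landmarkCoords(predSets[[i]])
    t <- landmarkCoords(trueSets[[i]])
    nm <- intersect(rownames(p), rownames(t))
    err <- sqrt(rowSums((p[nm, , drop = FALSE] - t[nm, , drop = FALSE])^2))
    data.frame(face_id = faceIds[i], landmark = nm,
               organ = reg$organ[match(nm, reg$name)],
               laterality = reg$laterality[match(nm, reg$name)],
               error_mm = unname(err), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize an error table
#'
#' Reports (a) per-landmark mean and sd of the error across faces, (b) the
#' overall mean and sd across all rows, (c) the fraction of landmarks whose
#' per-landmark mean error falls within each threshold (the primary coverage
#' mode) together with the fraction of individual rows within each threshold,
#' and (d) per-region Tukey box-plot statistics (median, quartiles,
#' 1.5 IQR whiskers). "+/-" values are sample standard deviations (n - 1).
#'
#' @param errors data.frame from \code{\link{errorTable}}.
#' @param thresholds mm thresholds for coverage, default 2.5 and 3.0.
#' @return list with \code{perLandmark} (data.frame), \code{overall}
#'   (mean, sd, n), \code{coverage} (data.frame: threshold, fraction of
#'   landmark means within, fraction of rows within), and \code{perOrgan}
#'   (data.frame of quartile statistics).
#' @export
summarizeErrors <- function(errors, thresholds = c(2.5, 3.0)) {
  if (is.null(errors) || nrow(errors) == 0) stop("empty error table")
  agg <- stats::aggregate(error_mm ~ landmark + organ + laterality,
                          data = errors, FUN = mean)
  names(agg)[names(agg) == "error_mm"] <- "mean_mm"
  sds <- stats::aggregate(error_mm ~ landmark, data = errors,
                          FUN = function(x) if (length(x) > 1) stats::sd(x) else 0)
  agg$sd_mm <- sds$error_mm[match(agg$landmark, sds$landmark)]
  reg <- landmarkRegistry()
  agg <- agg[order(match(agg$landmark, reg$name)), ]
  rownames(agg) <- NULL
  overall <- list(mean = mean(errors$error_mm),
                  sd = if (nrow(errors) > 1) stats::sd(errors$error_mm) else 0,
                  n = nrow(errors))
  coverage <- data.frame(
    threshold_mm = thresholds,
    frac_landmark_means_within = vapply(thresholds,
      function(th) mean(agg$mean_mm <= th), numeric(1)),
    frac_rows_within = vapply(thresholds,
      function(th) mean(errors$error_mm <= th), numeric(1)))
  perOrgan <- do.call(rbind, lapply(split(errors$error_mm, errors$organ),
    function(x) {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      data.frame(q1 = q[1], median = q[2], q3 = q[3],
                 whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
                 whisker_hi = max(x[x <= q[3] + 1.5 * iqr]),
                 mean = mean(x), n = length(x))
    }))
  perOrgan <- data.frame(organ = rownames(perOrgan), perOrgan,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(perLandmark = agg, overall = overall, coverage = coverage,
       perOrgan = perOrgan)
}

#' Left-right symmetry report
#'
#' For each of the 10 symmetric landmark pairs present in the table, the
#' absolute difference between the left and right per-landmark mean errors.
#' Anatomically symmetric points should show similar errors; large gaps
#' indicate laterally biased predictions.
#'
#' @param errors data.frame from \code{\link{errorTable}}.
#' @return data.frame with columns \code{abbreviation}, \code{left},
#'   \code{right}, \code{mean_left_mm}, \code{mean_right_mm},
#'   \code{abs_diff_mm}; one row per pair with both members present.
#' @export
symmetryReport <- function(errors) {
  pairs <- symmetricPairs()
  means <- tapply(errors$error_mm, errors$landmark, mean)
  keep <- pairs$left %in% names(means) & pairs$right %in% names(means)
  pairs <- pairs[keep, ]
  data.frame(abbreviation = pairs$abbreviation, left = pairs$left,
             right = pairs$right,
             mean_left_mm = unname(means[pairs$left]),
             mean_right_mm = unname(means[pairs$right]),
             abs_diff_mm = unname(abs(means[pairs$left] - means[pairs$right])),
             stringsAsFactors = FALSE)
}

#' Render a summary as human-readable text
#'
#' @param summary result of \code{\link{summarizeErrors}}.
#' @return character vector of report lines.
#' @export
formatSummary <- function(summary) {
  c(sprintf("Overall error: %.2f +/- %.2f mm over %d face x landmark pairs",
            summary$overall$mean, summary$overall$sd, summary$overall$n),
    sprintf("Landmarks with mean error <= %.1f mm: %.1f%%",
            summary$coverage$threshold_mm,
            100 * summary$coverage$frac_landmark_means_within),
    "Per-landmark mean +/- sd (mm):",
    sprintf("  %-26s %6.2f +/- %5.2f", summary$perLandmark$landmark,
            summary$perLandmark$mean_mm, summary$perLandmark$sd_mm))
}
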