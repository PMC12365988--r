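# Evaluation statistics for angle prediction: RMSE, MAE, R^2, the
# trial-averaged manual reference, the low/high angle-interval
# decomposition, and the error-distribution summaries.
#
# Error sign convention: error = predicted - actual, so positive errors
# are over-predictions. The skewness estimator is the bias-uncorrected
# Fisher-Pearson g1 = m3 / m2^(3/2) on the errors; the error standard
# deviation uses the sample (n - 1) denominator.

.makeReport <- function(actual, predicted) {
  n <- length(actual)
  if (n == 0L)
    return(new("MetricsReport", n = 0L, rmseDeg = NA_real_,
               maeDeg = NA_real_, r2 = NA_real_, meanActualDeg = NA_real_,
               errorSd = NA_real_, errorSkewness = NA_real_,
               intervals = list()))
  e <- predicted - actual
  rmse <- sqrt(mean(e^2))
  mae <- mean(abs(e))
  ybar <- mean(actual)
  sstot <- sum((actual - ybar)^2)
  r2 <- if (n >= 2L && sstot > 0) 1 - sum(e^2) / sstot else NA_real_
  sdE <- if (n >= 2L) stats::sd(e) else NA_real_
  m2 <- mean((e - mean(e))^2)
  skew <- if (n >= 2L && m2 > 0) mean((e - mean(e))^3) / m2^1.5 else NA_real_
  new("MetricsReport", n = as.integer(n), rmseDeg = rmse, maeDeg = mae,
      r2 = r2, meanActualDeg = ybar, errorSd = sdE, errorSkewness = skew,
      intervals = list())
}

#' Average repeated manual trials into the reference angle
#'
#' The reference ("ground truth") angle of each plant is the arithmetic
#' mean of its two protractor readings, which damps single-reading noise.
#'
#' @param records data.frame with columns \code{trial1_deg},
#'   \code{trial2_deg}.
#' @return the data.frame with \code{mean_measured_deg} added.
#' @export
averageTrials <- function(records) {
  if (!all(c("trial1_deg", "trial2_deg") %in% names(records)))
    diskTiltError("MISSING_TRIAL", "need trial1_deg and trial2_deg columns")
  if (anyNA(records$trial1_deg) || anyNA(records$trial2_deg))
    diskTiltError("MISSING_TRIAL", "missing trial value")
  records$mean_measured_deg <- (records$trial1_deg + records$trial2_deg) / 2
  records
}

#' Compute the angle-prediction evaluation statistics
#'
#' RMSE = sqrt(mean((y - yhat)^2)), MAE = mean(|y - yhat|),
#' R^2 = 1 - SSres/SStot with SStot about the mean reference angle, plus
#' the error SD and skewness. Constant reference angles make R^2
#' undefined; it is returned as \code{NA} with the other fields intact.
#'
#' @param records data.frame with \code{mean_measured_deg} and
#'   \code{predicted_deg} (trial columns are averaged first if the mean
#'   column is absent).
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(records) {
  if (!"mean_measured_deg" %in% names(records))
    records <- averageTrials(records)
  if (!"predicted_deg" %in% names(records))
    diskTiltError("MISSING_PREDICTED", "need a predicted_deg column")
  if (nrow(records) < 2L)
    diskTiltError("TOO_FEW_RECORDS", "need n >= 2 records")
  .makeReport(records$mean_measured_deg, records$predicted_deg)
}

#' Per-interval error decomposition
#'
#' Splits the records into closed angle intervals by their reference
#' angle (lo <= y <= hi) and computes one sub-report per interval;
#' records outside all intervals go to an \code{"other"} bucket. The
#' default intervals are the low-angle [70, 80] and high-angle [100, 110]
#' bands where field predictions degrade.
#'
#' @param records as in [computeMetrics()].
#' @param intervals list of numeric c(lo, hi); must not overlap.
#' @return named list of [MetricsReport-class] (one per interval, plus
#'   \code{other} when nonempty); empty intervals yield a report with
#'   \code{n = 0}.
#' @export
intervalBreakdown <- function(records,
                              intervals = list(c(70, 80), c(100, 110))) {
  if (!"mean_measured_deg" %in% names(records))
    records <- averageTrials(records)
  iv <- lapply(intervals, as.numeric)
  if (length(iv) > 1L) {
    srt <- iv[order(vapply(iv, `[[`, numeric(1L), 1L))]
    for (i in seq_len(length(srt) - 1L))
      if (srt[[i]][2L] >= srt[[i + 1L]][1L])
        diskTiltError("OVERLAPPING_INTERVALS", "intervals must not overlap")
  }
  y <- records$mean_measured_deg
  out <- list()
  used <- rep(FALSE, nrow(records))
  for (r in iv) {
    member <- y >= r[1L] & y <= r[2L]
    used <- used | member
    out[[sprintf("[%g, %g]", r[1L], r[2L])]] <-
      .makeReport(records$mean_measured_deg[member],
                  records$predicted_deg[member])
  }
  if (any(!used))
    out[["other"]] <- .makeReport(records$mean_measured_deg[!used],
                                  records$predicted_deg[!used])
  out
}

#' Read an angle-record CSV
#'
#' Expects a header with \code{plant_id, trial1_deg, trial2_deg}
#' (optionally \code{predicted_deg}); the trial average is added.
#'
#' @param path CSV path.
#' @return data.frame of angle records.
#' @export
readAngleCsv <- function(path) {
  if (!file.exists(path))
    diskTiltError("MISSING_FILE", sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "trial1_deg", "trial2_deg")
  if (!all(need %in% names(df)))
    diskTiltError("MALFORMED_HEADER", paste(
      "header must contain", paste(need, collapse = ", ")))
  if (nrow(df) == 0L)
    diskTiltError("EMPTY_DATA", "no data rows")
  numCols <- intersect(c("trial1_deg", "trial2_deg", "predicted_deg"),
                       names(df))
  for (cn in numCols) {
    if (!is.numeric(df[[cn]]))
      diskTiltError("NON_NUMERIC", sprintf("column %s is not numeric", cn))
  }
  averageTrials(df)
}

#' Write a metrics report as JSON (and optionally CSV)
#'
#' @param report a [MetricsReport-class] or a named list of them (as from
#'   [intervalBreakdown()]).
#' @param jsonPath output JSON path.
#' @param csvPath optional flat CSV path.
#' @return \code{jsonPath}, invisibly.
#' @export
writeMetricsReport <- function(report, jsonPath, csvPath = NULL) {
  flat <- function(r) list(n = r@n, rmse_deg = r@rmseDeg, mae_deg = r@maeDeg,
                           r2 = r@r2, mean_actual_deg = r@meanActualDeg,
                           error_sd = r@errorSd,
                           error_skewness = r@errorSkewness)
  obj <- if (is(report, "MetricsReport")) flat(report) else lapply(report, flat)
  jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csvPath)) {
    rows <- if (is(report, "MetricsReport")) list(overall = flat(report))
      else lapply(report, flat)
    df <- do.call(rbind, lapply(names(rows), function(nm)
      data.frame(scope = nm, as.data.frame(rows[[nm]]))))
    utils::write.csv(df, csvPath, row.names = FALSE)
  }
  invisible(jsonPath)
}

#' Reference protractor trials and model predictions for ten plants
#'
#' A ten-plant sample of repeated manual protractor readings with the
#' per-plant reference (mean of the two trials) and the pipeline's
#' predicted angle, in degrees. Useful as a worked example for
#' [averageTrials()], [computeMetrics()] and [intervalBreakdown()]. Also
#' shipped as \code{inst/extdata/sunflower_trials.csv}.
#'
#' @return data.frame with plant_id, trial1_deg, trial2_deg,
#'   predicted_deg.
#' @export
sunflowerTrials <- function() {
  data.frame(
    plant_id = 1:10,
    trial1_deg = c(100, 88, 92, 76, 93, 77, 79, 91, 79, 96),
    trial2_deg = c(106, 92, 91, 75, 100, 71, 73, 99, 87, 105),
    predicted_deg = c(102.7, 91.2, 95.2, 72.7, 101.5, 74.6, 77.4, 100.3,
                      77, 101))
}
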