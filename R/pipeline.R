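#' Run the full screening pipeline on one input
#'
#' Ties the stages together: chart digitization (skipped when the input is
#' already an RR series), smoothing, R-peak detection, RR extraction,
#' optional device calibration, windowing, covariate extraction and
#' classification. Raw uncalibrated RR data feed the classifier directly
#' when no calibration model is given; by design the recurrence covariates
#' do not change under the affine calibration anyway.
#'
#' @param input one of: an `ecg_chart`, a `raster_image`, a path to a chart
#'   PNG/JPEG, a path to an RR CSV (extension `.csv`), or an `rr_series`.
#' @param model a fitted `af_logit` classifier (or path to its JSON).
#' @param calibration optional `rr_calibration` (or path to its JSON).
#' @param window_len,m analysis window length (beats) and embedding
#'   dimension.
#' @param features covariate set, see [feature_vector()].
#' @param output_dir if non-`NULL`, intermediate artifacts (signal CSV, RR
#'   CSV, per-window feature/probability CSV, report JSON) are written
#'   there.
#' @param ... digitizer options passed to [digitize_chart()].
#' @return A list of class `af_report`: `windows` (data frame of features,
#'   probability and call per window), `overall` (majority-vote call),
#'   `rr` (the RR series used), `n_windows`.
#' @export
run_pipeline <- function(input, model, calibration = NULL,
                         window_len = 102, m = 3,
                         features = default_features(),
                         output_dir = NULL, ...) {
  if (is.character(model)) model <- read_classifier_json(model)
  if (!inherits(model, "af_logit"))
    stop("a trained classifier model is required (train one with ",
         "fit_af_classifier or pass its JSON path)")
  if (is.character(calibration)) calibration <- read_calibration_json(calibration)

  sig <- NULL
  if (inherits(input, "rr_series")) {
    rr <- input
  } else if (is.character(input) && grepl("\\.csv$", input, ignore.case = TRUE)) {
    rr <- read_rr_csv(input)
  } else {
    sig <- digitize_chart(input, ...)
    sig <- smooth_signal(sig)
    rr <- compute_rr(detect_r_peaks(sig))
  }
  if (!is.null(calibration)) rr <- apply_calibration(rr, calibration)

  windows <- window_rr(rr, window_len = window_len)
  if (!length(windows))
    stop("input yields no complete ", window_len, "-beat window (",
         length(rr), " intervals)")
  feats <- feature_matrix(windows, m = m, features = features)
  probs <- predict(model, feats, type = "prob")
  calls <- factor(ifelse(probs > model$tau, "AF", "NS"),
                  levels = c("NS", "AF"))
  win_df <- data.frame(window = seq_along(windows), feats,
                       prob_af = probs, call = calls)
  overall <- names(which.max(table(calls)))
  report <- structure(list(windows = win_df, overall = overall, rr = rr,
                           n_windows = length(windows)),
                      class = "af_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sig)) {
      t <- (seq_along(sig$samples) - 1) / sig$sampling_rate
      utils::write.csv(data.frame(time_s = t, amplitude_mv = sig$samples),
                       file.path(output_dir, "signal.csv"), row.names = FALSE)
    }
    write_rr_csv(rr, file.path(output_dir, "rr.csv"))
    utils::write.csv(win_df, file.path(output_dir, "windows.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(overall = overall,
                              n_windows = length(windows),
                              calls = as.character(calls),
                              prob_af = probs),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.af_report <- function(x, ...) {
  cat(sprintf("Screening report: %d window(s), overall call %s\n",
              x$n_windows, x$overall))
  tab <- table(x$windows$call)
  cat(sprintf("  windows: %d NS, %d AF; mean P(AF) = %.3f\n",
              tab[["NS"]], tab[["AF"]], mean(x$windows$prob_af)))
  invisible(x)
}
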