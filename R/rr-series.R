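#' RR-interval series
#'
#' The central data structure of the package: a numeric vector of inter-beat
#' (RR) intervals in seconds, optionally labelled with the rhythm it came
#' from. All downstream analysis (calibration, symbolic recurrence features,
#' classification) consumes `rr_series` objects, which behave like plain
#' numeric vectors.
#'
#' @param values numeric vector of RR intervals, seconds. Must be finite,
#'   strictly positive and of length >= 1.
#' @param label rhythm label: `"NS"` (normal sinus), `"AF"` (atrial
#'   fibrillation) or `"unknown"`.
#' @return An object of class `rr_series`.
#' @examples
#' rr <- rr_series(c(0.55, 0.65, 0.60, 0.70, 0.65, 0.50))
#' mean(rr)
#' @export
rr_series <- function(values, label = c("unknown", "NS", "AF")) {
  label <- match.arg(label)
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("an RR series needs at least one interval")
  if (!all(is.finite(values)))
    stop("RR intervals must be finite")
  if (any(values <= 0))
    stop("RR intervals must be strictly positive")
  structure(values, label = label, class = c("rr_series", "numeric"))
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d intervals, label %s\n", length(x), rr_label(x)))
  cat(sprintf("  mean %.3f s, sd %.3f s, range [%.3f, %.3f] s\n",
              mean(x), stats::sd(x), min(x), max(x)))
  invisible(x)
}

#' @rdname rr_series
#' @param x an `rr_series` object.
#' @export
rr_label <- function(x) {
  lab <- attr(x, "label")
  if (is.null(lab)) "unknown" else lab
}

#' @export
`[.rr_series` <- function(x, i, ...) {
  rr_series(unclass(x)[i], label = rr_label(x))
}

#' Uniformly sampled waveform
#'
#' A one-dimensional signal (single ECG lead, in millivolts unless stated
#' otherwise) sampled at a fixed rate. Produced by the chart digitizer and by
#' the synthetic waveform generator.
#'
#' @param samples numeric vector of amplitudes.
#' @param sampling_rate sampling frequency, Hz (> 0).
#' @return An object of class `ecg_signal`: a list with elements `samples`
#'   and `sampling_rate`.
#' @export
ecg_signal <- function(samples, sampling_rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (length(samples) && !all(is.finite(samples)))
    stop("signal samples must be finite")
  structure(list(samples = samples, sampling_rate = sampling_rate),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("ECG signal: %d samples at %g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' @export
plot.ecg_signal <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$sampling_rate
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "amplitude (mV)", ...)
  invisible(x)
}

#' Read / write RR series as CSV
#'
#' The on-disk interchange format is one interval per line, in seconds, with
#' an optional `rr_s` header.
#'
#' @param path file path.
#' @param label label to attach on read (files carry no label).
#' @return `read_rr_csv` returns an `rr_series`; `write_rr_csv` returns
#'   `path` invisibly.
#' @export
read_rr_csv <- function(path, label = c("unknown", "NS", "AF")) {
  label <- match.arg(label)
  first <- readLines(path, n = 1L)
  skip <- if (suppressWarnings(is.na(as.numeric(first)))) 1L else 0L
  vals <- utils::read.csv(path, header = FALSE, skip = skip)[[1L]]
  rr_series(vals, label = label)
}

#' @rdname read_rr_csv
#' @param rr an `rr_series`.
#' @export
write_rr_csv <- function(rr, path) {
  utils::write.table(data.frame(rr_s = as.numeric(rr)), path,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
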