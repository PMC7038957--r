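#' Smooth a digitized waveform
#'
#' Causal rational-transfer-function filtering
#' `y[n] = (1/a[1]) * (sum b[i] x[n-i] - sum a[j] y[n-j])` with zero initial
#' conditions, the classic direct-form digital filter. The default is the
#' fourth-order moving average `b = (0.2, 0.2, 0.2, 0.2, 0.2)`, `a = 1`,
#' which has unit DC gain and a flat two-sample group delay — a delay that
#' cancels exactly when differencing R-peak positions into RR intervals, so
#' no compensation is applied.
#'
#' @param signal an `ecg_signal`.
#' @param b numerator (feed-forward) coefficients.
#' @param a denominator (feedback) coefficients; `a[1]` must be non-zero.
#' @return The filtered `ecg_signal`, same length as the input.
#' @export
smooth_signal <- function(signal, b = rep(0.2, 5), a = 1) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (length(a) < 1 || a[1] == 0) stop("a[1] must be non-zero")
  b <- b / a[1]; a <- a / a[1]
  y <- as.numeric(signal::filter(signal::Arma(b = b, a = a), signal$samples))
  ecg_signal(y, signal$sampling_rate)
}

# topographic prominence of peak i among candidates, MATLAB-style:
# descend on each side until a strictly higher sample (or the signal edge);
# the peak's base is the higher of the two side minima.
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) { lmin <- min(lmin, x[i]); i <- i - 1L }
    rmin <- h
    i <- p + 1L
    while (i <= n && x[i] <= h) { rmin <- min(rmin, x[i]); i <- i + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect R peaks
#'
#' Finds local maxima, keeps those whose topographic prominence reaches a
#' robust fraction of the signal's dynamic range (99th percentile minus
#' median — insensitive to baseline offset and to a few outliers), and
#' enforces a refractory spacing between peaks; when two candidates are too
#' close the higher one wins. A flat signal yields no peaks.
#'
#' @param signal an `ecg_signal` of length >= 3.
#' @param min_distance minimum peak spacing, seconds. The 0.25 s default is
#'   the physiologic refractory bound (~240 bpm).
#' @param min_prominence required prominence as a fraction of the robust
#'   range.
#' @return An object of class `peak_list`: list with `indices` (1-based
#'   sample positions, strictly increasing) and `sampling_rate`.
#' @export
detect_r_peaks <- function(signal, min_distance = 0.25,
                           min_prominence = 0.4) {
  stopifnot(inherits(signal, "ecg_signal"))
  x <- signal$samples
  if (length(x) < 3) stop("signal too short for peak detection")
  scale <- stats::quantile(x, 0.99, names = FALSE) - stats::median(x)
  empty <- structure(list(indices = integer(0),
                          sampling_rate = signal$sampling_rate),
                     class = "peak_list")
  if (scale <= 0) return(empty)
  # plateau-aware local maxima: collapse equal-value runs, a run is a peak
  # when both neighbouring runs are lower; the candidate is the run centre
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  k <- length(v)
  if (k < 3) return(empty)
  is_max <- c(FALSE, v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k], FALSE)
  cand <- as.integer(floor((starts[is_max] + ends[is_max]) / 2))
  if (!length(cand)) return(empty)
  prom <- peak_prominences(x, cand)
  cand <- cand[prom >= min_prominence * scale]
  if (!length(cand)) return(empty)
  # refractory spacing: greedy by height, higher peak wins a conflict
  min_gap <- min_distance * signal$sampling_rate
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  structure(list(indices = sort(kept), sampling_rate = signal$sampling_rate),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("peak list: %d peaks at %g Hz\n",
              length(x$indices), x$sampling_rate))
  invisible(x)
}

#' RR intervals from detected peaks
#'
#' @param peaks a `peak_list` with at least two peaks.
#' @return An `rr_series` of `length(indices) - 1` intervals in seconds.
#' @export
compute_rr <- function(peaks) {
  stopifnot(inherits(peaks, "peak_list"))
  if (length(peaks$indices) < 2)
    stop("need at least two peaks to form RR intervals")
  rr_series(diff(peaks$indices) / peaks$sampling_rate)
}

#' Split an RR series into fixed-length windows
#'
#' Consecutive (by default non-overlapping) analysis windows; a trailing
#' remainder shorter than `window_len` is dropped. The 102-beat default
#' matches the window length on which the symbolic recurrence contrast
#' between rhythms is typically displayed; discrimination improves with
#' window size.
#'
#' @param rr an `rr_series`.
#' @param window_len beats per window.
#' @param step stride between window starts, beats.
#' @return A list of `rr_series` windows (empty, with a warning, when the
#'   series is shorter than one window).
#' @export
window_rr <- function(rr, window_len = 102, step = window_len) {
  stopifnot(inherits(rr, "rr_series"), window_len >= 1, step >= 1)
  n <- length(rr)
  if (n < window_len) {
    warning("series shorter than one window; returning empty list")
    return(list())
  }
  starts <- seq(1L, n - window_len + 1L, by = step)
  lapply(starts, function(s) rr[s:(s + window_len - 1L)])
}
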