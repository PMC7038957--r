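#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic normal-sinus RR series
#'
#' Emulates a normal sinus rhythm tachogram: RR intervals fluctuate mildly
#' around a stable mean, with a slow periodic modulation (the respiratory
#' sinus arrhythmia seen in healthy subjects) plus Gaussian beat-to-beat
#' noise. The ordinal-pattern sequence of such a series repeats
#' quasi-periodically, the signature that symbolic recurrence analysis keys
#' on.
#'
#' The model is
#' \deqn{RR_t = \bar{RR} + A \sin(2\pi t / P) + \epsilon_t,\qquad
#'       \epsilon_t \sim N(0, (cv\,\bar{RR})^2),}
#' with values clipped from below at 0.2 s to stay physiologic.
#'
#' @param n number of intervals (>= 1).
#' @param mean_rr mean RR interval, seconds (default 0.8 s, 75 bpm).
#' @param cv coefficient of variation of the noise, in `[0, 0.15]` (the
#'   normal-sinus regime; AF variability is far larger).
#' @param mod_amp amplitude of the periodic modulation, seconds.
#' @param mod_period modulation period, beats (respiratory frequency is a few
#'   beats per cycle at rest).
#' @param seed integer seed for reproducibility; `NULL` leaves the RNG alone.
#' @return An `rr_series` labelled `"NS"`.
#' @export
generate_rr_ns <- function(n, mean_rr = 0.8, cv = 0.03, mod_amp = 0.05,
                           mod_period = 6, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  if (mean_rr <= 0) stop("mean_rr must be positive")
  if (cv < 0 || cv > 0.15)
    stop("cv must lie in [0, 0.15] for the normal-sinus regime")
  n <- as.integer(n)
  with_seed(seed, {
    t <- seq_len(n)
    vals <- mean_rr + mod_amp * sin(2 * pi * t / mod_period) +
      stats::rnorm(n, 0, cv * mean_rr)
    rr_series(pmax(vals, 0.2), label = "NS")
  })
}

#' Synthetic atrial-fibrillation RR series
#'
#' Emulates the irregularly irregular tachogram of atrial fibrillation:
#' intervals are drawn i.i.d. from a gamma distribution with the requested
#' mean and coefficient of variation, so a long series has essentially no
#' serial structure (lag-1 autocorrelation near zero) and its ordinal
#' symbols appear at random.
#'
#' @param n number of intervals.
#' @param mean_rr mean RR interval, seconds.
#' @param cv coefficient of variation, must be >= 0.15 (the AF regime).
#' @param seed integer seed; `NULL` leaves the RNG alone.
#' @return An `rr_series` labelled `"AF"`, values clipped to `[0.2, 2.0]` s.
#' @export
generate_rr_af <- function(n, mean_rr = 0.7, cv = 0.25, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  if (mean_rr <= 0) stop("mean_rr must be positive")
  if (cv < 0.15)
    stop("cv must be >= 0.15 for the atrial-fibrillation regime")
  n <- as.integer(n)
  with_seed(seed, {
    shape <- 1 / cv^2
    vals <- stats::rgamma(n, shape = shape, scale = mean_rr / shape)
    rr_series(pmin(pmax(vals, 0.2), 2.0), label = "AF")
  })
}

#' Default PQRST wave parameters
#'
#' Each heartbeat is modelled as a sum of five Gaussian bumps. Centers are
#' offsets from the R peak in seconds, widths are Gaussian standard
#' deviations in seconds, amplitudes in millivolts. The R amplitude is the
#' largest positive one by construction, so the within-beat maximum falls at
#' the R center.
#'
#' @return A data frame with columns `wave`, `amp_mv`, `center_s`, `width_s`.
#' @export
ecg_wave_defaults <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amp_mv = c(0.10, -0.06, 1.00, -0.08, 0.25),
    center_s = c(-0.20, -0.045, 0.00, 0.045, 0.30),
    width_s = c(0.040, 0.012, 0.016, 0.014, 0.060),
    stringsAsFactors = FALSE
  )
}

#' Synthesize a single-lead ECG waveform from an RR series
#'
#' Places one PQRST complex per beat (Gaussian-bump morphology, see
#' [ecg_wave_defaults()]) at R-peak times accumulated from the RR series,
#' samples the sum uniformly and optionally adds white measurement noise.
#' The true R-peak sample indices are attached so that peak-detection and
#' digitization stages can be scored against ground truth.
#'
#' An RR series of `n` intervals yields `n + 1` beats, so that detecting all
#' R peaks recovers exactly the generating intervals.
#'
#' @param rr an `rr_series`.
#' @param sampling_rate Hz.
#' @param waves wave-parameter data frame as from [ecg_wave_defaults()].
#' @param noise_sd additive Gaussian noise, mV.
#' @param lead_in,tail quiet padding before the first and after the last
#'   beat, seconds.
#' @param seed seed for the noise.
#' @return An `ecg_signal` with attribute `r_peaks`: the 1-based sample
#'   indices of the true R-wave centers.
#' @export
synthesize_ecg <- function(rr, sampling_rate = 300,
                           waves = ecg_wave_defaults(), noise_sd = 0,
                           lead_in = 0.4, tail = 0.4, seed = NULL) {
  stopifnot(inherits(rr, "rr_series"), sampling_rate > 0)
  if (any(waves$width_s <= 0)) stop("wave widths must be positive")
  r_amp <- waves$amp_mv[waves$wave == "R"]
  if (length(r_amp) != 1L || any(waves$amp_mv[waves$amp_mv > 0] > r_amp))
    stop("R amplitude must be the largest positive wave amplitude")
  r_times <- lead_in + c(0, cumsum(as.numeric(rr)))
  duration <- r_times[length(r_times)] + tail
  t <- seq(0, duration, by = 1 / sampling_rate)
  x <- numeric(length(t))
  for (k in seq_along(r_times)) {
    for (j in seq_len(nrow(waves))) {
      c_j <- r_times[k] + waves$center_s[j]
      w_j <- waves$width_s[j]
      # only evaluate near the bump; 5 sd covers it to ~1e-6
      idx <- which(t >= c_j - 5 * w_j & t <= c_j + 5 * w_j)
      x[idx] <- x[idx] + waves$amp_mv[j] * exp(-((t[idx] - c_j)^2) / (2 * w_j^2))
    }
  }
  if (noise_sd > 0)
    x <- with_seed(seed, x + stats::rnorm(length(x), 0, noise_sd))
  sig <- ecg_signal(x, sampling_rate)
  attr(sig, "r_peaks") <- as.integer(round(r_times * sampling_rate)) + 1L
  attr(sig, "r_times") <- r_times
  sig
}

#' Synthetic device-calibration RR pairs
#'
#' Draws paired RR measurements (low-cost device, gold standard) with the
#' statistical structure reported for simultaneous Lead-I acquisitions on
#' normal-sinus subjects: the gold-standard reading is an affine function of
#' the low-cost reading plus Gaussian residual noise,
#' `rr_gold = a + b * rr_lowcost + e`.
#'
#' The defaults reproduce the published study conditions in closed form:
#' slope and intercept are the reported device-pair coefficients, the
#' residual sd equals the square root of the reported post-calibration mean
#' squared error, the low-cost sd follows from the reported coefficient of
#' determination, and the mean from the reported pre-calibration mean
#' squared error (see the methods vignette for the algebra).
#'
#' @param n number of pairs (study size 400 = 20 patients x 20 samples).
#' @param mean_x,sd_x mean and sd of the low-cost RR readings, seconds.
#' @param intercept,slope true affine map from low-cost to gold standard.
#' @param noise_sd residual sd of the gold-standard reading, seconds.
#' @param seed seed.
#' @return A data frame with columns `rr_lowcost`, `rr_gold`.
#' @export
generate_calibration_pairs <- function(n = 400, mean_x = 0.763,
                                       sd_x = 0.0561,
                                       intercept = -0.011794,
                                       slope = 1.0679,
                                       noise_sd = 0.018841, seed = NULL) {
  stopifnot(n >= 2)
  with_seed(seed, {
    x <- stats::rnorm(n, mean_x, sd_x)
    y <- intercept + slope * x + stats::rnorm(n, 0, noise_sd)
    data.frame(rr_lowcost = x, rr_gold = y)
  })
}
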