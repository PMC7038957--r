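#' Fit a device calibration for RR intervals
#'
#' Low-cost single-lead recorders measure RR intervals with a small
#' systematic deviation from hospital-grade equipment. This fits the affine
#' correction `rr_gold = a + b * rr_lowcost` by ordinary least squares on
#' simultaneously acquired pairs; the fitted map is then applied to each new
#' patient's low-cost readings. OLS guarantees that, on the training pairs,
#' the mean squared disagreement after calibration is no larger than
#' before.
#'
#' @param pairs a data frame (or 2-column matrix) with low-cost RR in the
#'   first column and gold-standard RR in the second, seconds; at least two
#'   pairs with non-constant low-cost values.
#' @return An object of class `rr_calibration`: list with `intercept` (a,
#'   seconds), `slope` (b), `r_squared`, `n`.
#' @export
fit_calibration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2) stop("pairs must have two columns (low-cost, gold)")
  x <- as.numeric(pairs[[1]]); y <- as.numeric(pairs[[2]])
  if (length(x) < 2) stop("need at least two pairs")
  if (stats::var(x) == 0) stop("low-cost values are constant; cannot fit")
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = min(max(r2, 0), 1),
                 n = length(x)),
            class = "rr_calibration")
}

#' @export
print.rr_calibration <- function(x, ...) {
  cat(sprintf("RR calibration: gold = %.6f + %.4f * lowcost  (R^2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.rr_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Apply a fitted calibration to an RR series
#'
#' Maps every interval through `a + b * rr`, preserving the rhythm label.
#' Should the affine map produce a non-positive interval (possible with a
#' negative intercept on a very short interval), the value is clipped to a
#' small positive epsilon with a warning rather than failing a batch run.
#'
#' @param rr an `rr_series`.
#' @param model an `rr_calibration`.
#' @param eps clipping floor, seconds.
#' @return The calibrated `rr_series`.
#' @export
apply_calibration <- function(rr, model, eps = 1e-3) {
  stopifnot(inherits(rr, "rr_series"), inherits(model, "rr_calibration"))
  out <- model$intercept + model$slope * as.numeric(rr)
  if (any(out <= 0)) {
    warning(sprintf("%d calibrated interval(s) were non-positive; clipped to %g s",
                    sum(out <= 0), eps))
    out[out <= 0] <- eps
  }
  rr_series(out, label = rr_label(rr))
}

#' Mean squared error between two equal-length sequences
#'
#' `mse(x, y) = mean((x - y)^2)`: the agreement metric used to validate the
#' calibration (lower after calibration than before, on training pairs).
#'
#' @param x,y numeric sequences of equal length >= 1.
#' @return A single number.
#' @export
mse <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1) stop("need at least one observation")
  mean((as.numeric(x) - as.numeric(y))^2)
}

#' Serialize / load a calibration model as JSON
#'
#' @param model an `rr_calibration`.
#' @param path file path.
#' @return `write_calibration_json` returns `path` invisibly;
#'   `read_calibration_json` returns an `rr_calibration`.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "rr_calibration"))
  jsonlite::write_json(list(a = model$intercept, b = model$slope,
                            r_squared = model$r_squared, n = model$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = obj$a, slope = obj$b,
                 r_squared = obj$r_squared, n = obj$n),
            class = "rr_calibration")
}
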