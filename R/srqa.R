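#' Ordinal-pattern alphabet
#'
#' The symmetric group of permutations of the offsets `0..m-1`, in canonical
#' lexicographic order. Each permutation is one ordinal symbol: the order in
#' which the entries of an m-history must be read to see them ascending.
#'
#' @param m embedding dimension (2..7; the alphabet has `m!` symbols).
#' @return An integer matrix with `m!` rows, one permutation per row.
#' @export
symbol_alphabet <- function(m) {
  stopifnot(m >= 1, m <= 7)
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  unname(perms(0:(m - 1L)))
}

# lexicographic rank (1-based) of a 0-based permutation tuple
perm_rank <- function(p) {
  m <- length(p)
  r <- 0
  for (i in seq_len(m - 1L)) {
    r <- r + sum(p[(i + 1L):m] < p[i]) * factorial(m - i)
  }
  as.integer(r + 1L)
}

#' Delay embedding of a time series
#'
#' Builds the `T - m + 1` overlapping m-histories
#' `(x_t, x_{t+1}, ..., x_{t+m-1})` (delay 1), the state-space
#' reconstruction on which the symbolization operates.
#'
#' @param x numeric vector (or `rr_series`) of length >= m.
#' @param m embedding dimension.
#' @return A matrix with one m-history per row.
#' @export
embed_series <- function(x, m = 3) {
  x <- as.numeric(x)
  if (length(x) < m) stop("series shorter than the embedding dimension")
  n <- length(x) - m + 1L
  out <- matrix(0, n, m)
  for (j in seq_len(m)) out[, j] <- x[j:(j + n - 1L)]
  out
}

#' Ordinal symbol of one m-history
#'
#' The symbol is the permutation of time offsets `0..m-1` that lists the
#' history's values in ascending order; ties are broken by ascending offset
#' (stable sort), the standard ordinal-pattern convention. For example
#' `(0.55, 0.65, 0.60)` maps to `(0, 2, 1)`: the smallest value sits at
#' offset 0, the next at offset 2, the largest at offset 1.
#'
#' @param history numeric vector of length m.
#' @return Integer vector: the permutation (0-based offsets).
#' @export
symbolize <- function(history) {
  as.integer(order(history) - 1L)
}

#' Symbolize a whole series
#'
#' Embeds the series and maps every m-history to its ordinal symbol,
#' identified by its 1-based rank in the lexicographic alphabet of
#' [symbol_alphabet()].
#'
#' @param x numeric vector or `rr_series`.
#' @param m embedding dimension.
#' @return An object of class `symbol_sequence`: list with `ids` (symbol
#'   ranks, length `T - m + 1`), `m`, and `alphabet`.
#' @export
symbolize_series <- function(x, m = 3) {
  H <- embed_series(x, m)
  ids <- apply(H, 1, function(h) perm_rank(symbolize(h)))
  structure(list(ids = as.integer(ids), m = m,
                 alphabet = symbol_alphabet(m)),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("symbol sequence: %d symbols, m = %d (alphabet %d)\n",
              length(x$ids), x$m, nrow(x$alphabet)))
  invisible(x)
}

#' Symbolic recurrence plot
#'
#' The N x N matrix whose entry `(t, s)` is the symbol id `k` when the
#' m-histories at times t and s carry the same ordinal symbol `pi_k`, and 0
#' otherwise. It is symmetric with a fully recurrent main diagonal; colored
#' by symbol it gives the characteristic structured (normal sinus) versus
#' unstructured (atrial fibrillation) dot patterns.
#'
#' @param symbols a `symbol_sequence`.
#' @return An integer matrix of class `srp_matrix` with attribute `m`.
#' @export
build_srp <- function(symbols) {
  stopifnot(inherits(symbols, "symbol_sequence"))
  ids <- symbols$ids
  if (!length(ids)) stop("empty symbol sequence")
  eq <- outer(ids, ids, "==")
  srp <- matrix(0L, length(ids), length(ids))
  srp[eq] <- ids[row(srp)[eq]]
  structure(srp, m = symbols$m, class = c("srp_matrix", "matrix", "array"))
}

#' Plot a symbolic recurrence plot
#'
#' Colored-dot rendering: one color per symbol, white where non-recurrent.
#'
#' @param srp an `srp_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot_srp <- function(srp, ...) {
  m <- attr(srp, "m")
  k <- factorial(m)
  cols <- c("white", grDevices::hcl.colors(k, "Dark 3"))
  graphics::image(seq_len(nrow(srp)), seq_len(ncol(srp)), unclass(srp),
                  col = cols, zlim = c(0, k), xlab = "t", ylab = "s",
                  useRaster = TRUE, ...)
  invisible(srp)
}

#' Per-symbol recurrence rates
#'
#' For each symbol k the fraction of ordered off-diagonal pairs `(t, s)`
#' that are recurrent with that symbol: `c_k (c_k - 1) / (N (N - 1))` where
#' `c_k` counts occurrences of k. The line of identity (self-recurrence) is
#' excluded, so the rates sum to the global off-diagonal recurrence rate.
#'
#' @param symbols a `symbol_sequence` of length N >= 2.
#' @return Named numeric vector of length `m!` (names are the permutation
#'   tuples).
#' @export
recurrence_rates <- function(symbols) {
  stopifnot(inherits(symbols, "symbol_sequence"))
  n <- length(symbols$ids)
  if (n < 2) stop("need at least two symbols")
  k <- nrow(symbols$alphabet)
  counts <- tabulate(symbols$ids, nbins = k)
  rates <- counts * (counts - 1) / (n * (n - 1))
  names(rates) <- apply(symbols$alphabet, 1,
                        function(p) paste0("(", paste(p, collapse = ","), ")"))
  rates
}

# run lengths of TRUE in a logical vector
true_runs <- function(v) {
  if (!length(v)) return(integer(0))
  r <- rle(v)
  r$lengths[r$values]
}

#' Diagonal line measures of a symbolic recurrence plot
#'
#' Scans the upper triangle (main diagonal excluded) for maximal runs of
#' recurrent entries along diagonals. Determinism `det` is the fraction of
#' recurrent points lying on runs of length >= `l_min`; `l_max` is the
#' longest run, `l_mean` the mean length among qualifying runs. All zero
#' when the triangle holds no recurrent points.
#'
#' @param srp an `srp_matrix` with N >= 2.
#' @param l_min minimum qualifying line length.
#' @return List with `det`, `l_max`, `l_mean`.
#' @export
diagonal_measures <- function(srp, l_min = 2) {
  n <- nrow(srp)
  stopifnot(n >= 2)
  total <- 0; on_lines <- 0; l_max <- 0
  lens <- integer(0)
  for (d in seq_len(n - 1L)) {
    v <- srp[cbind(seq_len(n - d), seq_len(n - d) + d)] > 0
    total <- total + sum(v)
    runs <- true_runs(v)
    q <- runs[runs >= l_min]
    on_lines <- on_lines + sum(q)
    lens <- c(lens, q)
    if (length(runs)) l_max <- max(l_max, runs)
  }
  if (total == 0) return(list(det = 0, l_max = 0, l_mean = 0))
  list(det = on_lines / total, l_max = l_max,
       l_mean = if (length(lens)) mean(lens) else 0)
}

#' Vertical line measures of a symbolic recurrence plot
#'
#' Scans every column (main diagonal entries excluded) for maximal runs of
#' recurrent entries. Laminarity `lam` is the fraction of off-diagonal
#' recurrent points lying on vertical runs of length >= `v_min`; trapping
#' time `tt` is the mean qualifying run length.
#'
#' @param srp an `srp_matrix` with N >= 2.
#' @param v_min minimum qualifying run length.
#' @return List with `lam`, `tt`.
#' @export
vertical_measures <- function(srp, v_min = 2) {
  n <- nrow(srp)
  stopifnot(n >= 2)
  M <- unclass(srp) > 0
  diag(M) <- FALSE
  total <- sum(M)
  if (total == 0) return(list(lam = 0, tt = 0))
  on_lines <- 0
  lens <- integer(0)
  for (s in seq_len(n)) {
    runs <- true_runs(M[, s])
    q <- runs[runs >= v_min]
    on_lines <- on_lines + sum(q)
    lens <- c(lens, q)
  }
  list(lam = on_lines / total, tt = if (length(lens)) mean(lens) else 0)
}

#' Shannon entropy of the per-symbol recurrence-rate distribution
#'
#' Normalizes the per-symbol recurrence rates to a probability distribution
#' and returns its Shannon entropy (natural log), in `[0, log(m!)]`. Zero
#' for a constant-symbol series, and defined as zero when there are no
#' recurrences at all.
#'
#' @param symbols a `symbol_sequence`.
#' @return A single number.
#' @export
symbol_entropy <- function(symbols) {
  rates <- recurrence_rates(symbols)
  s <- sum(rates)
  if (s == 0) return(0)
  p <- rates[rates > 0] / s
  -sum(p * log(p))
}

#' RR-distribution covariates
#'
#' The location/dispersion summaries of the RR distribution used alongside
#' the recurrence measures: mean, median, Pearson coefficient of variation
#' (sample sd over mean) and a robust median-based coefficient of variation
#' (median absolute deviation from the median, over the median).
#'
#' @param rr an `rr_series` (length >= 2, positive mean and median).
#' @return List with `rr_mean`, `rr_median`, `rr_cv`, `rr_cv_med`.
#' @export
distribution_stats <- function(rr) {
  x <- as.numeric(rr)
  if (length(x) < 2) stop("need at least two intervals")
  mu <- mean(x); med <- stats::median(x)
  if (mu == 0 || med == 0) stop("zero mean or median RR")
  list(rr_mean = mu, rr_median = med,
       rr_cv = stats::sd(x) / mu,
       rr_cv_med = stats::median(abs(x - med)) / med)
}

#' Default covariate set
#' @return Character vector of the nine default feature names.
#' @export
default_features <- function() {
  c("det", "lam", "l_max", "l_mean", "symbol_entropy",
    "rr_mean", "rr_median", "rr_cv", "rr_cv_med")
}

#' Covariate vector of one RR window
#'
#' Computes the full symbolic-recurrence + distribution covariate set for a
#' single analysis window: the window is symbolized (ordinal patterns of
#' dimension `m`), its symbolic recurrence plot built, and the diagonal,
#' vertical and entropy measures extracted; the RR-distribution summaries
#' are appended. The default nine covariates (in fixed order) are
#' `det, lam, l_max, l_mean, symbol_entropy, rr_mean, rr_median, rr_cv,
#' rr_cv_med`. The recurrence-based components depend only on the ordinal
#' structure, so they are invariant under any strictly increasing transform
#' of the intervals.
#'
#' @param rr an `rr_series` window (length >= m + 1).
#' @param m embedding dimension.
#' @param l_min,v_min minimum diagonal / vertical line lengths.
#' @param features which covariates to return, a subset of
#'   [default_features()].
#' @return Named numeric vector.
#' @export
feature_vector <- function(rr, m = 3, l_min = 2, v_min = 2,
                           features = default_features()) {
  if (length(rr) < m + 1) stop("window too short for feature extraction")
  bad <- setdiff(features, default_features())
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  sym <- symbolize_series(rr, m)
  srp <- build_srp(sym)
  dm <- diagonal_measures(srp, l_min)
  vm <- vertical_measures(srp, v_min)
  ds <- distribution_stats(rr)
  all <- c(det = dm$det, lam = vm$lam, l_max = dm$l_max, l_mean = dm$l_mean,
           symbol_entropy = symbol_entropy(sym),
           rr_mean = ds$rr_mean, rr_median = ds$rr_median,
           rr_cv = ds$rr_cv, rr_cv_med = ds$rr_cv_med)
  all[features]
}

#' Covariate matrix for a list of RR windows
#'
#' @param windows list of `rr_series` (as from [window_rr()]).
#' @param ... passed to [feature_vector()].
#' @return A numeric matrix, one row per window.
#' @export
feature_matrix <- function(windows, ...) {
  do.call(rbind, lapply(windows, feature_vector, ...))
}
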