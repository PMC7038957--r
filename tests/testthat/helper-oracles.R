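# Independent brute-force oracles and shared fixtures for the test suite.

# Diagonal-line statistics by explicit run enumeration over the upper
# triangle of a recurrence matrix (independent of the package's rle-based
# implementation).
oracle_diagonal <- function(srp, l_min = 2) {
  n <- nrow(srp)
  total <- 0; on_lines <- 0; l_max <- 0; lens <- c()
  for (d in 1:(n - 1)) {
    run <- 0
    for (i in 1:(n - d)) {
      rec <- srp[i, i + d] > 0
      if (rec) { total <- total + 1; run <- run + 1 }
      if (!rec || i == n - d) {
        if (run >= l_min) { on_lines <- on_lines + run; lens <- c(lens, run) }
        if (run > l_max) l_max <- run
        run <- 0
      }
    }
  }
  if (total == 0) return(list(det = 0, l_max = 0, l_mean = 0))
  list(det = on_lines / total, l_max = l_max,
       l_mean = if (length(lens)) mean(lens) else 0)
}

# Vertical-line statistics by explicit column scans, main diagonal excluded.
oracle_vertical <- function(srp, v_min = 2) {
  n <- nrow(srp)
  M <- unclass(srp) > 0
  diag(M) <- FALSE
  total <- sum(M)
  if (total == 0) return(list(lam = 0, tt = 0))
  on_lines <- 0; lens <- c()
  for (s in 1:n) {
    run <- 0
    for (t in 1:n) {
      if (M[t, s]) run <- run + 1
      if (!M[t, s] || t == n) {
        if (run >= v_min) { on_lines <- on_lines + run; lens <- c(lens, run) }
        run <- 0
      }
    }
  }
  list(lam = on_lines / total, tt = if (length(lens)) mean(lens) else 0)
}

# Exhaustive scan for the ROC operating point closest to (0, 1), using the
# same candidate set and classification rule as the spec of the curve.
oracle_threshold <- function(probs, y) {
  cand <- sort(unique(c(0, 1, probs)))
  best_d <- Inf; best_t <- NA
  for (tau in cand) {
    pred <- probs > tau
    fpr <- sum(pred & y == 0) / sum(y == 0)
    se <- sum(pred & y == 1) / sum(y == 1)
    d <- sqrt(fpr^2 + (1 - se)^2)
    if (d < best_d - 1e-12 || (abs(d - best_d) <= 1e-12 && tau > best_t)) {
      best_d <- d; best_t <- tau
    }
  }
  best_t
}

# symbol_sequence built directly from ids (for unit tests of the matrix
# measures, bypassing the symbolization stage)
make_symbols <- function(ids, m = 3) {
  structure(list(ids = as.integer(ids), m = m,
                 alphabet = symbol_alphabet(m)),
            class = "symbol_sequence")
}

# Covariate benchmark: 100 NS + 100 AF synthetic 102-beat windows with
# deterministic per-window seeds derived from a base seed.
benchmark_features <- function(n_each = 100, window = 102, base_seed = 1,
                               transform = identity) {
  feats <- function(gen, off) {
    t(vapply(seq_len(n_each), function(i) {
      rr <- gen(window, seed = base_seed * 1000 + off + i)
      feature_vector(rr_series(transform(as.numeric(rr))))
    }, numeric(9)))
  }
  list(x = rbind(feats(generate_rr_ns, 0), feats(generate_rr_af, 500)),
       y = rep(c(0L, 1L), each = n_each))
}
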