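test_that("ordinal symbolization matches the hand-worked six-beat example", {
  # (0.55, 0.65, 0.60): smallest at offset 0, then offset 2, then offset 1
  expect_equal(symbolize(c(0.55, 0.65, 0.60)), c(0L, 2L, 1L))
  expect_equal(symbolize(c(0.65, 0.60, 0.70)), c(1L, 0L, 2L))
  # ties resolve by time order (stable sort)
  expect_equal(symbolize(c(1, 1, 1)), c(0L, 1L, 2L))

  x <- c(0.55, 0.65, 0.60, 0.70, 0.65, 0.50)
  sym <- symbolize_series(x, m = 3)
  expect_equal(sym$alphabet[sym$ids, ],
               rbind(c(0L, 2L, 1L), c(1L, 0L, 2L),
                     c(0L, 2L, 1L), c(2L, 1L, 0L)))
})

test_that("the m = 3 alphabet is the six-permutation symmetric group", {
  ab <- symbol_alphabet(3)
  expect_equal(nrow(ab), 6)
  expect_equal(nrow(unique(ab)), 6)
  expect_true(all(apply(ab, 1, function(p) setequal(p, 0:2))))
  # lexicographic canonical order
  expect_equal(ab[1, ], c(0L, 1L, 2L))
  expect_equal(ab[6, ], c(2L, 1L, 0L))
  expect_equal(nrow(symbol_alphabet(4)), 24)
})

test_that("delay embedding produces T - m + 1 overlapping histories", {
  x <- c(0.55, 0.65, 0.60, 0.70, 0.65, 0.50)
  H <- embed_series(x, 3)
  expect_equal(dim(H), c(4, 3))
  expect_equal(H[1, ], x[1:3])
  expect_equal(nrow(embed_series(rnorm(102), 3)), 100)
  expect_error(embed_series(c(1, 2), 3), "shorter")
})

test_that("the symbolic recurrence plot marks equal-symbol pairs", {
  sym <- make_symbols(c(1, 2, 1))
  srp <- build_srp(sym)
  nz <- which(unclass(srp) > 0, arr.ind = TRUE)
  expect_setequal(paste(nz[, 1], nz[, 2]),
                  c("1 1", "2 2", "3 3", "1 3", "3 1"))
  expect_true(all(diag(srp) > 0))
  expect_identical(unclass(srp), t(unclass(srp)))
  # a monotone series has a single symbol: fully recurrent plot
  full <- build_srp(symbolize_series(1:6, 3))
  expect_true(all(unclass(full) > 0))
})

test_that("per-symbol recurrence rates count off-diagonal pairs", {
  const <- recurrence_rates(symbolize_series(1:7, 3))
  expect_equal(sort(const, decreasing = TRUE)[[1]], 1)
  expect_equal(sum(const > 0), 1L)

  distinct <- recurrence_rates(make_symbols(c(1, 2, 3, 4)))
  expect_true(all(distinct == 0))

  ab <- recurrence_rates(make_symbols(c(1, 1, 2, 2)))
  expect_equal(unname(ab[1]), 2 / 12)
  expect_equal(unname(ab[2]), 2 / 12)

  # rates sum to the global off-diagonal recurrence rate
  set.seed(2)
  sym <- make_symbols(sample(1:6, 30, replace = TRUE))
  srp <- build_srp(sym)
  global <- (sum(unclass(srp) > 0) - 30) / (30 * 29)
  expect_equal(sum(recurrence_rates(sym)), global)
})

test_that("line measures equal brute-force enumeration on random plots", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    sym <- make_symbols(sample(1:sample(2:6, 1), n, replace = TRUE))
    srp <- build_srp(sym)
    dm <- diagonal_measures(srp)
    od <- oracle_diagonal(srp)
    expect_equal(dm$det, od$det)
    expect_equal(dm$l_max, od$l_max)
    expect_equal(dm$l_mean, od$l_mean)
    vm <- vertical_measures(srp)
    ov <- oracle_vertical(srp)
    expect_equal(vm$lam, ov$lam)
    expect_equal(vm$tt, ov$tt)
  }
})

test_that("line measures behave on degenerate plots", {
  # constant symbol, N = 5: everything recurrent. The far-corner diagonal
  # holds a single point, below l_min = 2, so DET is 9/10 (brute-force
  # enumeration agrees), and the column runs split by the excluded line of
  # identity put LAM at 18/20.
  srp <- build_srp(make_symbols(rep(2, 5)))
  dm <- diagonal_measures(srp)
  expect_equal(dm$det, oracle_diagonal(srp)$det)
  expect_equal(dm$det, 0.9)
  expect_equal(dm$l_max, 4)
  expect_equal(vertical_measures(srp)$lam, 0.9)
  # with l_min = 1 every recurrent point is on a line
  expect_equal(diagonal_measures(srp, l_min = 1)$det, 1)
  expect_equal(vertical_measures(srp, v_min = 1)$lam, 1)
  # no repeated symbols: no recurrences at all
  none <- diagonal_measures(build_srp(make_symbols(1:5)))
  expect_equal(none$det, 0)
  expect_equal(none$l_max, 0)
  # alternating symbols: recurrences exist but no vertical run reaches 2
  alt <- build_srp(make_symbols(rep(c(1, 2), 5)))
  expect_equal(vertical_measures(alt)$lam, 0)
  expect_gt(diagonal_measures(alt)$det, 0)
})

test_that("distribution covariates match hand arithmetic", {
  rr <- rr_series(c(0.55, 0.65, 0.60, 0.70, 0.65, 0.50))
  ds <- distribution_stats(rr)
  expect_equal(ds$rr_mean, 0.6083333, tolerance = 1e-6)
  expect_equal(ds$rr_median, 0.625)
  expect_equal(ds$rr_cv, sd(rr) / mean(rr))
  const <- distribution_stats(rr_series(rep(0.8, 5)))
  expect_equal(const$rr_cv, 0)
  expect_equal(const$rr_cv_med, 0)
  # both CVs are scale-invariant
  ds3 <- distribution_stats(rr_series(3 * as.numeric(rr)))
  expect_equal(ds3$rr_cv, ds$rr_cv)
  expect_equal(ds3$rr_cv_med, ds$rr_cv_med)
})

test_that("symbolic measures are invariant under strictly increasing maps", {
  transforms <- list(function(x) 0.3 + 2 * x, exp, function(x) x^3)
  set.seed(13)
  for (i in 1:100) {
    x <- rr_series(runif(sample(10:40, 1), 0.4, 1.2))
    base <- symbolize_series(x, 3)
    srqa_names <- c("det", "lam", "l_max", "l_mean", "symbol_entropy")
    f0 <- feature_vector(x)[srqa_names]
    for (g in transforms) {
      gx <- rr_series(g(as.numeric(x)))
      expect_identical(symbolize_series(gx, 3)$ids, base$ids)
      expect_identical(feature_vector(gx)[srqa_names], f0)
    }
  }
})

test_that("symbol entropy stays within its theoretical bounds", {
  expect_equal(symbol_entropy(symbolize_series(1:10, 3)), 0)
  set.seed(3)
  for (i in 1:20) {
    h <- symbol_entropy(make_symbols(sample(1:6, 50, replace = TRUE)))
    expect_gte(h, 0)
    expect_lte(h, log(factorial(3)) + 1e-12)
  }
})

test_that("the covariate vector has the documented nine components", {
  rr <- generate_rr_ns(102, seed = 1)
  fv <- feature_vector(rr)
  expect_named(fv, c("det", "lam", "l_max", "l_mean", "symbol_entropy",
                     "rr_mean", "rr_median", "rr_cv", "rr_cv_med"))
  expect_true(all(fv[c("det", "lam")] >= 0 & fv[c("det", "lam")] <= 1))
  expect_lte(fv[["l_max"]], 99)

  # normal sinus windows are more deterministic than AF windows
  fa <- feature_vector(generate_rr_af(102, seed = 1))
  expect_gt(fv[["det"]], fa[["det"]])
  expect_gt(fv[["lam"]], fa[["lam"]])

  # an increasing affine recalibration leaves every symbolic component alone
  cal <- rr_series(-0.011794 + 1.0679 * as.numeric(rr))
  srqa_names <- c("det", "lam", "l_max", "l_mean", "symbol_entropy")
  expect_identical(feature_vector(cal)[srqa_names], fv[srqa_names])

  expect_error(feature_vector(rr_series(c(0.8, 0.9)), m = 3), "short")
  expect_error(feature_vector(rr, features = "nope"), "unknown")
})
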