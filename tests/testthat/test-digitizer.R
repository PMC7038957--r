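white_image <- function(h, w, dpi = 600) raster_image(array(1, c(h, w, 3)), dpi)

test_that("rasterize round-trips PNG pixels and rejects bad input", {
  px <- array(runif(20 * 30 * 3), c(20, 30, 3))
  f <- tempfile(fileext = ".png")
  png::writePNG(px, f)
  img <- rasterize(f, dpi = 300)
  expect_equal(dim(img$pixels), c(20, 30, 3))
  expect_equal(img$dpi, 300)
  # 8-bit quantization on write is the only loss
  expect_lt(max(abs(img$pixels - px)), 1 / 255)
  expect_error(rasterize(tempfile(fileext = ".png")), "not found")
  expect_error(rasterize({f2 <- tempfile(fileext = ".pdf"); file.create(f2); f2}),
               "PDF")
})

test_that("crop returns the requested sub-image and validates bounds", {
  img <- white_image(600, 600)
  expect_identical(crop(img, c(0, 0, 600, 600))$pixels, img$pixels)
  expect_equal(dim(crop(img, c(0, 0, 10, 10))$pixels), c(10, 10, 3))
  expect_error(crop(img, c(-1, 0, 10, 10)), "bounds")
  expect_error(crop(img, c(0, 0, 601, 10)), "bounds")
})

test_that("grid removal whitens the colour box and keeps the trace", {
  # pure grid-coloured image -> all white
  img <- white_image(10, 10)
  img$pixels[, , 1] <- 200 / 255; img$pixels[, , 2] <- 120 / 255
  img$pixels[, , 3] <- 120 / 255
  out <- remove_grid(img, c(150, 50, 50), c(255, 200, 200))
  expect_true(all(out$pixels == 1))

  # black trace on a pink grid: only the trace survives
  sig <- ecg_signal(rep(0, 50), 50)
  ch <- render_chart(sig, dpi = 100, speck_noise_rate = 0)
  clean <- remove_grid(ch$strips[[1]])
  dark <- clean$pixels[, , 1] < 0.5
  m <- binarize(clean)
  expect_identical(m$mask, dark)
  # trace band only: 2 rows, all columns
  expect_equal(sum(dark), 2L * dim(clean$pixels)[2])

  # an empty box (lower > upper) changes nothing
  same <- remove_grid(ch$strips[[1]], c(255, 255, 255), c(0, 0, 0))
  expect_identical(same$pixels, ch$strips[[1]]$pixels)
})

test_that("binarize thresholds the darkest channel strictly", {
  img <- white_image(4, 4)
  expect_false(any(binarize(img)$mask))
  img$pixels[2, , ] <- 0                      # black line
  expect_equal(which(apply(binarize(img)$mask, 1, all)), 2L)
  # pixel exactly at the threshold is excluded
  img2 <- white_image(1, 1)
  img2$pixels[1, 1, ] <- 128 / 255
  expect_false(binarize(img2, darkness_threshold = 128)$mask[1, 1])
  expect_true(binarize(img2, darkness_threshold = 129)$mask[1, 1])
})

test_that("despeckle removes small 8-connected components, strict area rule", {
  m <- matrix(FALSE, 100, 200)
  m[1:10, 1:10] <- TRUE                       # 100-px blob
  m[30:69, 50:99] <- TRUE                     # 2000-px blob
  out <- despeckle(binary_image(m, 600), min_area = 1260)
  expect_false(any(out$mask[1:10, 1:10]))
  expect_true(all(out$mask[30:69, 50:99]))

  # empty mask passes through
  e <- despeckle(binary_image(matrix(FALSE, 5, 5), 600))
  expect_false(any(e$mask))

  # a blob of exactly min_area pixels is retained (35 x 36 = 1260)
  m2 <- matrix(FALSE, 50, 50)
  m2[1:35, 1:36] <- TRUE
  out2 <- despeckle(binary_image(m2, 600), min_area = 1260)
  expect_identical(out2$mask, m2)

  # diagonal chains count as one component (8-connectivity)
  m3 <- matrix(FALSE, 10, 10)
  for (i in 1:6) m3[i, i] <- TRUE
  out3 <- despeckle(binary_image(m3, 600), min_area = 6)
  expect_identical(out3$mask, m3)

  # default area rescales with resolution squared
  m4 <- matrix(FALSE, 60, 60)
  m4[1:18, 1:18] <- TRUE                      # 324 px > 1260/4 = 315
  expect_true(any(despeckle(binary_image(m4, 300))$mask))
  m4[1:18, 1:18] <- FALSE; m4[1:17, 1:18] <- TRUE   # 306 px < 315
  expect_false(any(despeckle(binary_image(m4, 300))$mask))
})

test_that("thinning erodes thick strokes, preserves connectivity, never adds", {
  thick <- matrix(FALSE, 20, 40)
  thick[8:12, 5:35] <- TRUE                   # 5-px-thick horizontal line
  b <- binary_image(thick, 600)
  expect_identical(shrink(b, 0)$mask, thick)
  out <- shrink(b, 2)
  expect_lt(sum(out$mask), sum(thick))
  expect_true(all(thick[out$mask]))           # subset of original
  # still a single 8-connected component spanning the same columns
  lab <- ecgsrqa:::label_components8(out$mask)
  expect_equal(length(lab$sizes), 1L)
  # thinning may nibble the bar ends but must keep the core span
  cols <- unique(which(out$mask, arr.ind = TRUE)[, 2])
  expect_true(all(cols %in% 5:35))
  expect_true(all(9:31 %in% cols))

  # isolated pixels survive thinning
  lone <- matrix(FALSE, 5, 5); lone[3, 3] <- TRUE
  expect_identical(shrink(binary_image(lone, 600), 3)$mask, lone)
})

test_that("vertical scan emits per-column spans in 0-based coordinates", {
  # the worked record: trace pixels in rows 27-28 of column 12 (0-based)
  m <- matrix(FALSE, 60, 30)
  m[28:29, 13] <- TRUE
  sp <- vertical_scan(binary_image(m, 600))
  expect_equal(nrow(sp), 1L)
  expect_equal(unlist(sp[1, ]), c(column = 12, top = 27, bottom = 28))

  # a single-pixel column has top == bottom; blank columns emit nothing
  m2 <- matrix(FALSE, 10, 5)
  m2[4, 1] <- TRUE; m2[5:6, 3] <- TRUE
  sp2 <- vertical_scan(binary_image(m2, 600))
  expect_equal(sp2$column, c(0, 2))
  expect_equal(sp2$top[1], sp2$bottom[1])

  # disjoint runs: the run nearest the previous column's trace is kept
  m3 <- matrix(FALSE, 30, 3)
  m3[10:11, 1] <- TRUE
  m3[c(10, 25), 2] <- TRUE; m3[11, 2] <- TRUE   # runs at 10-11 and 25
  m3[10:11, 3] <- TRUE
  sp3 <- vertical_scan(binary_image(m3, 600))
  expect_equal(sp3$bottom[sp3$column == 1], 10)  # 0-based rows 9-10 run
})

test_that("span collapse follows the modal-thickness / reference rule", {
  # constant-thickness flat line at rows 27-28: mu = 1, y = 28 everywhere
  m <- matrix(FALSE, 60, 20)
  m[28:29, ] <- TRUE
  tr <- spans_to_trace(vertical_scan(binary_image(m, 600)))
  expect_equal(tr$mu, 1)
  expect_equal(tr$y, rep(28, 20))

  # thick column after a flat stretch at lambda = 40: span 10-40 -> y = 10
  m2 <- matrix(FALSE, 60, 6)
  m2[40:41, 1:5] <- TRUE                      # rows 39-40 (0-based), y = 40
  m2[11:41, 6] <- TRUE                        # span 10-40 (0-based)
  tr2 <- spans_to_trace(vertical_scan(binary_image(m2, 600)))
  expect_equal(tr2$y[1:5], rep(40, 5))
  expect_equal(tr2$y[6], 10)

  # single-column input: y = bottom_row, no history needed
  m3 <- matrix(FALSE, 20, 1); m3[5:9, 1] <- TRUE
  tr3 <- spans_to_trace(vertical_scan(binary_image(m3, 600)))
  expect_equal(tr3$y, 8)
})

test_that("gap interpolation fills interior linearly and edges by extension", {
  tv <- function(y) structure(list(y = y, mu = 1, n_cols = length(y)),
                              class = "trace_vector")
  expect_equal(interpolate_gaps(tv(c(10, NA, 20)))$y, c(10, 15, 20))
  expect_equal(interpolate_gaps(tv(c(10, 14, 20)))$y, c(10, 14, 20))
  expect_equal(interpolate_gaps(tv(c(NA, 10, 20)))$y, c(10, 10, 20))
  expect_error(interpolate_gaps(tv(c(NA, 10, NA))), "two")
})

test_that("unit conversion is baseline-centred and affine in pixel rows", {
  tv <- function(y) structure(list(y = y, mu = 1, n_cols = length(y)),
                              class = "trace_vector")
  # flat trace -> all-zero signal
  s <- trace_to_signal(tv(rep(40, 500)), dpi = 600, target_rate = 100)
  expect_true(all(s$samples == 0))
  # a deflection of dpi*gain/25.4 pixels above baseline reads 1 mV
  px_mv <- 600 * 10 / 25.4
  y <- rep(100, 1001); y[501] <- 100 - px_mv
  s2 <- trace_to_signal(tv(y), dpi = 600, target_rate = NULL)
  expect_equal(max(s2$samples), 1, tolerance = 1e-12)
  # shifting the whole trace shifts nothing (median baseline follows)
  s3 <- trace_to_signal(tv(y + 17), dpi = 600, target_rate = NULL)
  expect_equal(s2$samples, s3$samples)
  expect_error(trace_to_signal(tv(c(1, NA)), 600), "gaps")
})

test_that("render -> digitize round trip preserves waveform and beats", {
  rr <- generate_rr_ns(6, seed = 21)
  sig <- synthesize_ecg(rr, sampling_rate = 300)
  chart <- render_chart(sig, dpi = 600)
  rec <- digitize_chart(chart, target_rate = NULL)   # one sample per column
  src <- approx((seq_along(sig$samples) - 1) / 300, sig$samples,
                xout = (seq_along(rec$samples) - 1) / rec$sampling_rate,
                rule = 2)$y
  expect_gt(cor(rec$samples, src), 0.99)
  det <- detect_r_peaks(rec)
  expect_length(det$indices, length(chart$r_peak_columns))
  expect_true(all(abs((det$indices - 1) - chart$r_peak_columns) <= 1))

  # deterministic: same chart in, same signal out
  rec2 <- digitize_chart(chart, target_rate = NULL)
  expect_identical(rec$samples, rec2$samples)
})

test_that("multi-strip charts digitize to one continuous signal", {
  rr <- generate_rr_ns(4, seed = 2)
  sig <- synthesize_ecg(rr, sampling_rate = 200)
  whole <- render_chart(sig, dpi = 200)
  split <- render_chart(sig, dpi = 200, max_width_px = 300)
  expect_gt(length(split$strips), 1L)
  a <- digitize_chart(whole, target_rate = 200)
  b <- digitize_chart(split, target_rate = 200)
  expect_gt(cor(a$samples, b$samples), 0.999)
})
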