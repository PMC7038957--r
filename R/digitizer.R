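#' Raster and binary image containers
#'
#' `raster_image` wraps an RGB pixel array (rows x cols x 3, values in
#' `[0, 1]`) plus its resolution; `binary_image` wraps a logical trace mask
#' of the same shape. Pixel coordinates reported by the digitizer are
#' 0-based with rows growing downward, the usual image-processing
#' convention.
#'
#' @param pixels numeric array rows x cols x 3 in `[0, 1]` (grayscale
#'   matrices are promoted to RGB).
#' @param dpi resolution, dots per inch.
#' @return An object of class `raster_image` / `binary_image`.
#' @export
raster_image <- function(pixels, dpi) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (length(dim(pixels)) != 3) stop("pixels must be rows x cols x channels")
  if (dim(pixels)[3] == 4) pixels <- pixels[, , 1:3, drop = FALSE]
  if (dim(pixels)[3] == 2) pixels <- array(rep(pixels[, , 1], 3),
                                           c(dim(pixels)[1:2], 3))
  stopifnot(dim(pixels)[1] > 0, dim(pixels)[2] > 0, dpi > 0)
  structure(list(pixels = pixels, dpi = dpi), class = "raster_image")
}

#' @rdname raster_image
#' @param mask logical matrix, `TRUE` = trace pixel.
#' @export
binary_image <- function(mask, dpi) {
  stopifnot(is.matrix(mask), is.logical(mask), dpi > 0)
  structure(list(mask = mask, dpi = dpi), class = "binary_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("raster image: %d x %d px at %g dpi\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$dpi))
  invisible(x)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("binary mask: %d x %d px, %d trace pixels\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Load an ECG chart image
#'
#' Reads a PNG or JPEG chart into a `raster_image`. Raster inputs are passed
#' through at native resolution with the stated dpi annotated. PDF input is
#' not rasterized by this package; export or convert the page to PNG at the
#' desired dpi first.
#'
#' @param path image file.
#' @param dpi resolution to annotate (raster files rarely carry a reliable
#'   one); print-quality chart scans are typically 600 dpi.
#' @return A `raster_image`.
#' @export
rasterize <- function(path, dpi = 600) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdf")
    stop("PDF input is not rasterized by this package; ",
         "convert the page to PNG at ", dpi, " dpi and retry")
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG input requires the EBImage package")
    img <- EBImage::readImage(path)
    d <- EBImage::imageData(img)
    px <- if (length(dim(d)) == 2) t(d) else aperm(d, c(2, 1, 3))
  } else {
    stop("unsupported image format: .", ext, " (use PNG or JPEG)")
  }
  raster_image(px, dpi)
}

#' Crop a chart image
#'
#' Charts usually contain headers, metadata and several strips; digitization
#' operates on a pruned rectangle containing one trace.
#'
#' @param image a `raster_image`.
#' @param region `c(left, top, width, height)` in 0-based pixel coordinates.
#' @return The cropped `raster_image`.
#' @export
crop <- function(image, region) {
  stopifnot(inherits(image, "raster_image"), length(region) == 4)
  left <- region[1]; top <- region[2]; w <- region[3]; h <- region[4]
  d <- dim(image$pixels)
  if (left < 0 || top < 0 || w <= 0 || h <= 0 ||
      left + w > d[2] || top + h > d[1])
    stop("crop region out of image bounds")
  raster_image(image$pixels[(top + 1):(top + h), (left + 1):(left + w), ,
                            drop = FALSE], image$dpi)
}

#' Remove the chart grid by colour thresholding
#'
#' Every pixel whose RGB value falls inside the given box (the grid and
#' background hues) is replaced by white; the darker trace pixels fall
#' outside the box and survive. The default box clears any pixel with a red
#' channel above ~40% — white paper and the red/pink grid family — while
#' keeping a dark trace.
#'
#' @param image a `raster_image`.
#' @param lower,upper RGB bounds of the colour box, 0-255 scale (inclusive).
#' @return A `raster_image` with the grid whitened.
#' @export
remove_grid <- function(image, lower = c(100, 0, 0),
                        upper = c(255, 255, 255)) {
  stopifnot(inherits(image, "raster_image"))
  px <- image$pixels
  lo <- lower / 255; hi <- upper / 255
  inside <- px[, , 1] >= lo[1] & px[, , 1] <= hi[1] &
    px[, , 2] >= lo[2] & px[, , 2] <= hi[2] &
    px[, , 3] >= lo[3] & px[, , 3] <= hi[3]
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[inside] <- 1
    px[, , ch] <- plane
  }
  raster_image(px, image$dpi)
}

#' Binarize a grid-free chart image
#'
#' A pixel belongs to the trace mask when its darkest channel is below the
#' threshold (strictly), i.e. `min(R, G, B) < darkness_threshold` on the
#' 0-255 scale.
#'
#' @param image a `raster_image` (grid already removed or absent).
#' @param darkness_threshold 0-255.
#' @return A `binary_image`.
#' @export
binarize <- function(image, darkness_threshold = 128) {
  stopifnot(inherits(image, "raster_image"))
  m <- pmin(image$pixels[, , 1], image$pixels[, , 2], image$pixels[, , 3])
  if (!is.matrix(m)) m <- matrix(m, dim(image$pixels)[1], dim(image$pixels)[2])
  binary_image(m * 255 < darkness_threshold, image$dpi)
}

# 8-connected component labelling via row-run merging. Returns a list with
# per-pixel component ids (same shape as mask) built from horizontal runs
# joined across adjacent rows (column ranges overlapping within +/- 1).
label_components8 <- function(mask) {
  runs <- list(); ri <- 0L
  row_runs <- vector("list", nrow(mask))
  for (r in seq_len(nrow(mask))) {
    cols <- which(mask[r, ])
    if (!length(cols)) { row_runs[[r]] <- integer(0); next }
    breaks <- c(0L, which(diff(cols) > 1L), length(cols))
    ids <- integer(length(breaks) - 1L)
    for (k in seq_len(length(breaks) - 1L)) {
      ri <- ri + 1L
      runs[[ri]] <- c(r, cols[breaks[k] + 1L], cols[breaks[k + 1L]])
      ids[k] <- ri
    }
    row_runs[[r]] <- ids
  }
  if (ri == 0L)
    return(list(labels = matrix(0L, nrow(mask), ncol(mask)), sizes = integer(0)))
  runmat <- do.call(rbind, runs)  # row, start, end
  edges <- list(); ei <- 0L
  for (r in seq_len(nrow(mask) - 1L)) {
    a <- row_runs[[r]]; b <- row_runs[[r + 1L]]
    if (!length(a) || !length(b)) next
    for (i in a) for (j in b) {
      if (runmat[j, 2] <= runmat[i, 3] + 1L && runmat[j, 3] >= runmat[i, 2] - 1L) {
        ei <- ei + 1L; edges[[ei]] <- c(i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = ri, directed = FALSE)
  if (ei > 0L)
    g <- igraph::add_edges(g, as.integer(t(do.call(rbind, edges))))
  comp <- igraph::components(g)$membership
  labels <- matrix(0L, nrow(mask), ncol(mask))
  sizes <- integer(max(comp))
  for (i in seq_len(ri)) {
    cid <- comp[i]
    labels[runmat[i, 1], runmat[i, 2]:runmat[i, 3]] <- cid
    sizes[cid] <- sizes[cid] + runmat[i, 3] - runmat[i, 2] + 1L
  }
  list(labels = labels, sizes = sizes)
}

#' Remove small speckle components (area opening)
#'
#' Deletes 8-connected components whose pixel area is strictly below
#' `min_area`, leaving the long trace component intact. The default area is
#' stated for 600 dpi scans and rescales with the square of the resolution.
#'
#' @param mask a `binary_image`.
#' @param min_area minimum component area in pixels; default
#'   `1260 * (dpi / 600)^2`.
#' @return The cleaned `binary_image`.
#' @export
despeckle <- function(mask, min_area = NULL) {
  stopifnot(inherits(mask, "binary_image"))
  if (is.null(min_area)) min_area <- 1260 * (mask$dpi / 600)^2
  lab <- label_components8(mask$mask)
  if (!length(lab$sizes)) return(mask)
  keep <- which(lab$sizes >= min_area)
  kept <- matrix(lab$labels %in% keep, nrow(mask$mask), ncol(mask$mask))
  binary_image(kept & mask$mask, mask$dpi)
}

# matrix shift helper: move content by (dr, dc), fill with FALSE
shift_mat <- function(M, dr, dc) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(FALSE, n, m)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(m, m + dc)
  out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

#' Morphological thinning (shrink)
#'
#' Applies Zhang-Suen thinning passes to the trace mask so that thick or
#' doubled strokes collapse toward a one-pixel curve while connectivity is
#' preserved; isolated pixels are untouched and no pixels are ever added.
#'
#' @param mask a `binary_image`.
#' @param iterations number of full thinning iterations (0 = identity).
#' @return The thinned `binary_image`.
#' @export
shrink <- function(mask, iterations = 2) {
  stopifnot(inherits(mask, "binary_image"), iterations >= 0)
  M <- mask$mask
  for (it in seq_len(iterations)) {
    for (sub in 1:2) {
      P2 <- shift_mat(M, 1, 0);  P3 <- shift_mat(M, 1, -1)
      P4 <- shift_mat(M, 0, -1); P5 <- shift_mat(M, -1, -1)
      P6 <- shift_mat(M, -1, 0); P7 <- shift_mat(M, -1, 1)
      P8 <- shift_mat(M, 0, 1);  P9 <- shift_mat(M, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (sub == 1) {
        cond <- M & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- M & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      M[cond] <- FALSE
    }
  }
  binary_image(M, mask$dpi)
}

#' Column-wise scan of the trace mask
#'
#' Walks the mask left to right and records, for every column containing
#' trace pixels, the vertical extent `(top, bottom)` of the trace there —
#' the per-column pair the digitization algorithm stores as a complex-number
#' vector (real part = column, imaginary parts = the two row limits). When a
#' column contains several disjoint runs (residual grid, specks), the run
#' nearest the previous column's trace is kept.
#'
#' @param mask a `binary_image`.
#' @return An object of class `column_spans`: a data frame with 0-based
#'   columns `column`, `top`, `bottom`, plus the image dimensions as
#'   attributes.
#' @export
vertical_scan <- function(mask) {
  stopifnot(inherits(mask, "binary_image"))
  M <- mask$mask
  out_col <- integer(0); out_top <- integer(0); out_bot <- integer(0)
  prev_y <- NA_real_
  for (c in seq_len(ncol(M))) {
    rows <- which(M[, c])
    if (!length(rows)) next
    breaks <- c(0L, which(diff(rows) > 1L), length(rows))
    nruns <- length(breaks) - 1L
    tops <- rows[breaks[-length(breaks)] + 1L]
    bots <- rows[breaks[-1L]]
    if (nruns == 1L) {
      k <- 1L
    } else if (is.na(prev_y)) {
      k <- which.max(bots - tops)            # largest run, tie -> topmost
    } else {
      k <- which.min(abs((tops + bots) / 2 - prev_y))
    }
    out_col <- c(out_col, c - 1L)
    out_top <- c(out_top, tops[k] - 1L)
    out_bot <- c(out_bot, bots[k] - 1L)
    prev_y <- (tops[k] + bots[k]) / 2
  }
  structure(data.frame(column = out_col, top = out_top, bottom = out_bot),
            n_rows = nrow(M), n_cols = ncol(M),
            class = c("column_spans", "data.frame"))
}

# statistical mode; ties broken toward the smallest value
stat_mode <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Collapse column spans to a one-dimensional trace
#'
#' Reduces each column's `(top, bottom)` span to a single row coordinate.
#' The modal span thickness mu over the whole trace separates "thin" columns
#' (ordinary trace, thickness <= mu) from "thick" ones (steep strokes such
#' as QRS flanks). Thin columns take the lower row (`bottom`) and update the
#' running reference lambda; thick columns take whichever of `top`/`bottom`
#' lies farther from lambda, which follows the moving flank of a steep
#' stroke. Columns without a span are marked `NA` (gaps) for later
#' interpolation.
#'
#' @param spans a `column_spans` object.
#' @param n_cols trace length in columns; defaults to the source image
#'   width.
#' @return An object of class `trace_vector`: list with `y` (per-column row,
#'   `NA` = gap), `mu` (modal thickness) and `n_cols`.
#' @export
spans_to_trace <- function(spans, n_cols = NULL) {
  stopifnot(inherits(spans, "column_spans"))
  if (nrow(spans) == 0) stop("empty column spans: no trace found")
  if (is.null(n_cols)) n_cols <- attr(spans, "n_cols")
  if (is.null(n_cols)) n_cols <- max(spans$column) + 1L
  mu <- stat_mode(spans$bottom - spans$top)
  y <- rep(NA_real_, n_cols)
  lambda <- NA_real_
  for (i in seq_len(nrow(spans))) {
    top <- spans$top[i]; bot <- spans$bottom[i]
    if (is.na(lambda)) {                    # first column: no history
      yi <- bot; lambda <- bot
    } else if (bot - top <= mu) {
      yi <- bot; lambda <- yi
    } else {
      yi <- if (abs(top - lambda) > abs(bot - lambda)) top else bot
    }
    y[spans$column[i] + 1L] <- yi
  }
  structure(list(y = y, mu = mu, n_cols = n_cols), class = "trace_vector")
}

#' Fill trace gaps by linear interpolation
#'
#' Interior gaps are estimated linearly between the nearest recovered
#' columns; leading/trailing gaps take the nearest recovered value.
#'
#' @param trace a `trace_vector`.
#' @return A gap-free `trace_vector`.
#' @export
interpolate_gaps <- function(trace) {
  stopifnot(inherits(trace, "trace_vector"))
  known <- which(!is.na(trace$y))
  if (length(known) < 2) stop("need at least two recovered columns")
  y <- stats::approx(known, trace$y[known], xout = seq_along(trace$y),
                     rule = 2)$y
  structure(list(y = y, mu = trace$mu, n_cols = trace$n_cols),
            class = "trace_vector")
}

#' Convert a trace vector to a calibrated waveform
#'
#' Maps pixel rows to millivolts and columns to seconds using the chart
#' geometry, then resamples to a uniform rate by linear interpolation. The
#' amplitude baseline is the median trace row (a robust zero reference; any
#' constant offset is immaterial to RR intervals and to the ordinal
#' features downstream).
#'
#' @param trace a gap-free `trace_vector`.
#' @param dpi chart resolution.
#' @param paper_speed,gain chart scaling, mm/s and mm/mV.
#' @param target_rate output sampling rate, Hz; twice the recorder bandwidth
#'   is enough, 300 Hz by default (single-lead portable recorders). `NULL`
#'   keeps one sample per pixel column.
#' @return An `ecg_signal` in mV.
#' @export
trace_to_signal <- function(trace, dpi, paper_speed = 25, gain = 10,
                            target_rate = 300) {
  stopifnot(inherits(trace, "trace_vector"))
  if (anyNA(trace$y)) stop("trace has gaps; run interpolate_gaps() first")
  geom <- chart_geometry(dpi, paper_speed, gain)
  baseline <- stats::median(trace$y)
  mv <- (baseline - trace$y) / geom$px_per_mv
  t <- (seq_along(trace$y) - 1) / geom$px_per_s
  if (is.null(target_rate)) return(ecg_signal(mv, geom$px_per_s))
  if (target_rate <= 0) stop("target_rate must be positive")
  xout <- seq(0, t[length(t)], by = 1 / target_rate)
  ecg_signal(stats::approx(t, mv, xout = xout)$y, target_rate)
}

#' Digitize an ECG chart into a waveform
#'
#' Runs the full digitization chain — grid removal, binarization, area
#' opening, thinning, column scan, span collapse, gap interpolation and
#' unit conversion — on a rendered chart, a raster image or an image file.
#' Multi-strip charts are scanned strip by strip and concatenated before
#' unit conversion.
#'
#' @param x an `ecg_chart`, `raster_image`, or path to a PNG/JPEG file.
#' @param dpi resolution (ignored for `ecg_chart` input, which knows its
#'   own).
#' @param paper_speed,gain chart scaling.
#' @param grid_lower,grid_upper RGB colour box of the grid (see
#'   [remove_grid()]).
#' @param darkness_threshold binarization threshold, 0-255.
#' @param min_area despeckle area, pixels (`NULL` = dpi-scaled default).
#' @param shrink_iterations thinning passes.
#' @param target_rate output sampling rate, Hz.
#' @return An `ecg_signal`.
#' @export
digitize_chart <- function(x, dpi = 600, paper_speed = 25, gain = 10,
                           grid_lower = c(100, 0, 0),
                           grid_upper = c(255, 255, 255),
                           darkness_threshold = 128, min_area = NULL,
                           shrink_iterations = 2, target_rate = 300) {
  if (is.character(x)) x <- rasterize(x, dpi)
  if (inherits(x, "raster_image")) {
    strips <- list(x)
    offsets <- 0L
    total_w <- dim(x$pixels)[2]
  } else if (inherits(x, "ecg_chart")) {
    strips <- x$strips
    offsets <- x$strip_offsets
    total_w <- x$width
    dpi <- x$dpi; paper_speed <- x$paper_speed; gain <- x$gain
  } else stop("unsupported input type")
  y_all <- rep(NA_real_, total_w)
  mu <- NA_real_
  for (s in seq_along(strips)) {
    m <- binarize(remove_grid(strips[[s]], grid_lower, grid_upper),
                  darkness_threshold)
    m <- despeckle(m, min_area)
    m <- shrink(m, shrink_iterations)
    spans <- vertical_scan(m)
    if (nrow(spans) == 0) next
    tr <- spans_to_trace(spans)
    w <- length(tr$y)
    y_all[offsets[s] + seq_len(w)] <- tr$y
    mu <- tr$mu
  }
  if (all(is.na(y_all))) stop("no trace recovered from chart")
  trace <- structure(list(y = y_all, mu = mu, n_cols = total_w),
                     class = "trace_vector")
  trace <- interpolate_gaps(trace)
  trace_to_signal(trace, dpi, paper_speed, gain, target_rate)
}
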