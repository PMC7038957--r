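#' Chart geometry conversions
#'
#' Standard ECG paper conventions link pixels to physical units: at
#' `paper_speed` mm/s and `gain` mm/mV, one second spans
#' `dpi * paper_speed / 25.4` pixels and one millivolt spans
#' `dpi * gain / 25.4` pixels.
#'
#' @param dpi raster resolution, dots per inch.
#' @param paper_speed chart speed, mm/s (clinical default 25).
#' @param gain vertical scale, mm/mV (clinical default 10).
#' @return A list with `px_per_s`, `px_per_mv`, `px_per_mm`.
#' @export
chart_geometry <- function(dpi, paper_speed = 25, gain = 10) {
  stopifnot(dpi > 0, paper_speed > 0, gain > 0)
  list(px_per_s = dpi * paper_speed / 25.4,
       px_per_mv = dpi * gain / 25.4,
       px_per_mm = dpi / 25.4)
}

#' Render a waveform as a gridded ECG chart image
#'
#' Draws the signal as a dark polyline trace (about 2 px thick) over the
#' familiar pink millimetre grid of ECG paper, emulating the chart a
#' low-cost recorder prints. This is the forward model the digitizer
#' inverts, so the two together form a testable round trip. Signals too wide
#' for `max_width_px` are split into consecutive strips, each digitized
#' separately.
#'
#' @param signal an `ecg_signal` (mV). If it carries true R-peak times (as
#'   produced by [synthesize_ecg()]), their column positions are attached to
#'   the result for ground-truth scoring.
#' @param dpi raster resolution (print-quality default 600).
#' @param paper_speed,gain chart scaling, mm/s and mm/mV.
#' @param grid draw the background grid?
#' @param grid_color fine-grid RGB, 0-255; the bold 5 mm grid uses a darker
#'   shade of the same hue.
#' @param trace_color trace RGB, 0-255.
#' @param fine_grid_mm,bold_grid_mm grid pitches, mm.
#' @param speck_noise_rate fraction of pixels flipped to trace colour
#'   (salt-and-pepper scanner specks).
#' @param margin_mm white margin above/below the trace extremes.
#' @param max_width_px maximum strip width before the chart wraps.
#' @param seed seed for the speck noise.
#' @return An object of class `ecg_chart`: a list with `strips` (list of
#'   `raster_image`), `dpi`, `paper_speed`, `gain`, `strip_offsets` (0-based
#'   first column of each strip), `baseline_row`, `width`, and optionally
#'   `r_peak_columns` (0-based global columns of the true R peaks).
#' @export
render_chart <- function(signal, dpi = 600, paper_speed = 25, gain = 10,
                         grid = TRUE, grid_color = c(250, 175, 175),
                         trace_color = c(0, 0, 0),
                         fine_grid_mm = 1, bold_grid_mm = 5,
                         speck_noise_rate = 0, margin_mm = 4,
                         max_width_px = Inf, seed = NULL) {
  stopifnot(inherits(signal, "ecg_signal"), length(signal$samples) > 0)
  if (all(grid_color == trace_color))
    stop("grid_color must differ from trace_color")
  geom <- chart_geometry(dpi, paper_speed, gain)
  x <- signal$samples
  t_samp <- (seq_along(x) - 1) / signal$sampling_rate
  width <- floor(t_samp[length(t_samp)] * geom$px_per_s) + 1L
  cols <- 0:(width - 1L)
  y_mv <- stats::approx(t_samp, x, xout = cols / geom$px_per_s, rule = 2)$y

  margin_px <- max(2L, round(margin_mm * geom$px_per_mm))
  top_mv <- max(y_mv)
  baseline_row <- margin_px + round(top_mv * geom$px_per_mv)   # 0-based
  rows_trace <- baseline_row - round(y_mv * geom$px_per_mv)    # 0-based
  height <- max(rows_trace) + margin_px + 2L

  fine_px <- fine_grid_mm * geom$px_per_mm
  bold_px <- bold_grid_mm * geom$px_per_mm
  fine_rgb <- grid_color / 255
  bold_rgb <- pmax(grid_color - 60, 0) / 255
  trace_rgb <- trace_color / 255

  n_strips <- if (is.finite(max_width_px)) ceiling(width / max_width_px) else 1L
  strip_w <- ceiling(width / n_strips)
  offsets <- (seq_len(n_strips) - 1L) * strip_w

  specks <- NULL
  if (speck_noise_rate > 0) {
    n_spk <- round(speck_noise_rate * height * width)
    specks <- with_seed(seed, cbind(sample.int(height, n_spk, replace = TRUE),
                                    sample.int(width, n_spk, replace = TRUE)))
  }

  strips <- vector("list", n_strips)
  for (s in seq_len(n_strips)) {
    c0 <- offsets[s]
    c1 <- min(c0 + strip_w, width) - 1L
    w_s <- c1 - c0 + 1L
    img <- array(1, dim = c(height, w_s, 3))
    if (grid) {
      gl <- function(pitch) unique(round(seq(0, by = pitch,
                                             length.out = floor(width / pitch) + 1L)))
      for (pass in 1:2) {
        pitch <- if (pass == 1) fine_px else bold_px
        rgb <- if (pass == 1) fine_rgb else bold_rgb
        vcols <- gl(pitch); vcols <- vcols[vcols >= c0 & vcols <= c1] - c0 + 1L
        hrows <- gl(pitch); hrows <- hrows[hrows < height] + 1L
        for (ch in 1:3) {
          img[, vcols, ch] <- rgb[ch]
          img[hrows, , ch] <- rgb[ch]
        }
      }
    }
    # trace: connect consecutive columns with vertical spans, ~2 px thick
    for (c in c0:c1) {
      r_prev <- rows_trace[max(c, 1L) - 1L + 1L]  # previous global column
      r_cur <- rows_trace[c + 1L]
      lo <- min(r_prev, r_cur)
      hi <- min(max(r_prev, r_cur) + 1L, height - 1L)
      rr <- (lo:hi) + 1L
      for (ch in 1:3) img[rr, c - c0 + 1L, ch] <- trace_rgb[ch]
    }
    if (!is.null(specks)) {
      sel <- specks[, 2] - 1L >= c0 & specks[, 2] - 1L <= c1
      if (any(sel)) {
        spk <- specks[sel, , drop = FALSE]
        for (ch in 1:3)
          img[cbind(spk[, 1], spk[, 2] - c0, ch)] <- trace_rgb[ch]
      }
    }
    strips[[s]] <- raster_image(img, dpi)
  }

  out <- structure(list(strips = strips, dpi = dpi,
                        paper_speed = paper_speed, gain = gain,
                        strip_offsets = offsets, baseline_row = baseline_row,
                        width = width),
                   class = "ecg_chart")
  r_times <- attr(signal, "r_times")
  if (!is.null(r_times))
    out$r_peak_columns <- round(r_times * geom$px_per_s)
  out
}

#' @export
print.ecg_chart <- function(x, ...) {
  h <- nrow(x$strips[[1]]$pixels)
  cat(sprintf("ECG chart: %d strip(s), %d x %d px total at %g dpi (%g mm/s, %g mm/mV)\n",
              length(x$strips), h, x$width, x$dpi, x$paper_speed, x$gain))
  invisible(x)
}

#' Write a rendered chart to PNG or single-page PDF
#'
#' Multi-strip charts write one file per strip (suffix `_1`, `_2`, ...) for
#' PNG, or one page per strip for PDF. When the chart carries ground-truth
#' R-peak columns a JSON sidecar `<path>.json` is written with them.
#'
#' @param chart an `ecg_chart`.
#' @param path output path (extension decides nothing; see `format`).
#' @param format `"png"` or `"pdf"`.
#' @param sidecar write the ground-truth JSON sidecar if available?
#' @return The paths written, invisibly.
#' @export
write_chart <- function(chart, path, format = c("png", "pdf"),
                        sidecar = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(chart, "ecg_chart"))
  n <- length(chart$strips)
  paths <- character(0)
  if (format == "png") {
    if (n == 1L) {
      png::writePNG(chart$strips[[1]]$pixels, path, dpi = chart$dpi)
      paths <- path
    } else {
      stem <- sub("\\.png$", "", path)
      for (s in seq_len(n)) {
        p <- sprintf("%s_%d.png", stem, s)
        png::writePNG(chart$strips[[s]]$pixels, p, dpi = chart$dpi)
        paths <- c(paths, p)
      }
    }
  } else {
    h <- nrow(chart$strips[[1]]$pixels)
    w <- ncol(chart$strips[[1]]$pixels)
    grDevices::pdf(path, width = w / chart$dpi, height = h / chart$dpi)
    for (s in seq_len(n)) {
      graphics::par(mar = c(0, 0, 0, 0))
      graphics::plot.new()
      graphics::rasterImage(chart$strips[[s]]$pixels, 0, 0, 1, 1,
                            interpolate = FALSE)
    }
    grDevices::dev.off()
    paths <- path
  }
  if (sidecar && !is.null(chart$r_peak_columns)) {
    sc <- paste0(path, ".json")
    jsonlite::write_json(list(r_peak_columns = chart$r_peak_columns,
                              dpi = chart$dpi,
                              paper_speed = chart$paper_speed,
                              gain = chart$gain),
                         sc, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, sc)
  }
  invisible(paths)
}
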