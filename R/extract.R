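# Extraction of normalized dF/F0 spike traces from x-t line-scan images:
# background subtraction, baseline estimation, 7-pixel spatial averaging,
# noise estimation and per-sample corrected acquisition times.

#' Line-scan (x-t) image
#'
#' @param pixels m x n numeric matrix of fluorescence intensities
#'   (rows = scan lines / time, columns = space), arbitrary detector units.
#' @param config the \code{\link{scan_config}} the image was acquired with;
#'   dimensions must match.
#' @param stimulus_onset time of the voltage stimulus, ms from the first
#'   line of the image.
#' @return Object of class \code{"linescan_image"}.
#' @export
linescan_image <- function(pixels, config, stimulus_onset) {
  stopifnot(is.matrix(pixels), inherits(config, "scan_config"))
  if (any(!is.finite(pixels))) stop("pixel values must be finite", call. = FALSE)
  if (nrow(pixels) != config$m || ncol(pixels) != config$n)
    stop("image dimensions do not match the scan config", call. = FALSE)
  structure(list(pixels = pixels, config = config,
                 stimulus_onset = as.numeric(stimulus_onset)),
            class = "linescan_image")
}

#' @export
print.linescan_image <- function(x, ...) {
  cat(sprintf("Line-scan image: %d lines x %d pixels (%s), stimulus at %g ms\n",
              x$config$m, x$config$n, x$config$mode, x$stimulus_onset))
  invisible(x)
}

#' Rectangular region of interest
#'
#' ROIs are axis-aligned rectangles in pixel coordinates, 1-based and
#' inclusive at both ends (standard R indexing).
#'
#' @param rows length-2 integer vector, first and last row (scan line).
#' @param cols length-2 integer vector, first and last column.
#' @return Object of class \code{"roi"}.
#' @export
roi <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 2L || length(cols) != 2L ||
      rows[1] > rows[2] || cols[1] > cols[2] || rows[1] < 1L || cols[1] < 1L)
    stop("roi must be given as increasing 1-based (rows, cols) ranges",
         call. = FALSE)
  structure(list(rows = rows, cols = cols), class = "roi")
}

check_roi_in_image <- function(r, image) {
  if (r$rows[2] > image$config$m || r$cols[2] > image$config$n)
    stop("ROI extends outside the image", call. = FALSE)
  invisible(TRUE)
}

roi_pixels <- function(image, r) {
  image$pixels[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2], drop = FALSE]
}

#' Subtract the background fluorescence level
#'
#' Estimates the background as the mean intensity over a region outside the
#' cell and subtracts it from every pixel. The estimated level is recorded
#' in the \code{"background"} attribute of the returned image.
#'
#' @param image a \code{\link{linescan_image}}.
#' @param background_roi \code{\link{roi}} placed outside the cell.
#' @return The background-subtracted \code{linescan_image}.
#' @export
subtract_background <- function(image, background_roi) {
  stopifnot(inherits(image, "linescan_image"), inherits(background_roi, "roi"))
  check_roi_in_image(background_roi, image)
  b <- mean(roi_pixels(image, background_roi))
  out <- image
  out$pixels <- image$pixels - b
  attr(out, "background") <- b
  out
}

#' Estimate the baseline fluorescence and per-pixel noise
#'
#' The baseline F0 is the mean intensity over a pre-stimulus region inside
#' the cell; the raw noise level is the SD of single pixels in the same
#' region. A warning is issued when the ROI extends past the stimulus
#' onset, where release-related fluorescence would inflate both estimates.
#'
#' @param image a (background-subtracted) \code{\link{linescan_image}}.
#' @param baseline_roi \code{\link{roi}} inside the cell, preceding the
#'   stimulus.
#' @return List with \code{F0} (detector units) and \code{sd_raw}
#'   (per-pixel SD, detector units).
#' @export
estimate_baseline <- function(image, baseline_roi) {
  stopifnot(inherits(image, "linescan_image"), inherits(baseline_roi, "roi"))
  check_roi_in_image(baseline_roi, image)
  line_ms <- 1000 / image$config$f
  last_row_time <- (baseline_roi$rows[2] - 1) * line_ms
  if (last_row_time >= image$stimulus_onset)
    warning("baseline ROI extends past the stimulus onset")
  px <- roi_pixels(image, baseline_roi)
  list(F0 = mean(px), sd_raw = stats::sd(as.vector(px)))
}

#' Normalized fluorescence trace
#'
#' Container for a (possibly non-uniformly sampled) dF/F0 time course.
#' Times are in ms relative to the stimulus onset, so the fitted latency
#' t0 is directly the stimulus-to-onset delay.
#'
#' @param times numeric vector, ms; strictly increasing.
#' @param values numeric vector of dF/F0 values, same length.
#' @param baseline_sd noise SD of the trace (dF/F0 units), estimated over
#'   the pre-stimulus samples.
#' @param center_column within-line position the trace was extracted at
#'   (\code{NA} for purely synthetic traces).
#' @param n_avg number of spatially averaged columns.
#' @param F0 baseline fluorescence in detector units (\code{NA} for
#'   synthetic traces generated directly in dF/F0 units).
#' @return Object of class \code{"fluo_trace"}.
#' @export
fluo_trace <- function(times, values, baseline_sd = NA_real_,
                       center_column = NA_integer_, n_avg = 1L,
                       F0 = NA_real_) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (!is.na(baseline_sd) && baseline_sd < 0)
    stop("baseline_sd must be >= 0", call. = FALSE)
  structure(list(times = times, values = values, baseline_sd = baseline_sd,
                 center_column = center_column, n_avg = n_avg, F0 = F0),
            class = "fluo_trace")
}

#' @export
print.fluo_trace <- function(x, ...) {
  cat(sprintf("dF/F0 trace: %d samples, %.1f..%.1f ms, noise SD %s\n",
              length(x$times), min(x$times), max(x$times),
              if (is.na(x$baseline_sd)) "unknown"
              else sprintf("%.4g", x$baseline_sd)))
  invisible(x)
}

#' Extract a spatially averaged dF/F0 trace from an x-t image
#'
#' Averages \code{2 * half_width + 1} spatial pixels (7 by default) centred
#' at \code{center_column} on every scan line, normalizes to the baseline
#' (\code{dF/F0 = (F - F0)/F0}) and attaches per-sample acquisition times.
#' With \code{correct_times = TRUE} each sample gets the corrected
#' acquisition time of the centre pixel of its line (spatial averaging
#' incurs the same sequential-sampling error as the centre pixel alone);
#' otherwise the uncorrected line times t_i are used. In the uncorrected
#' bidirectional convention, consecutive forward/backward line pairs are
#' additionally averaged and assigned the mean of their line times, as in
#' the standard rendering of bidirectional scans. Returned times are
#' relative to the stimulus onset. The trace noise SD is the SD of the
#' averaged trace over the pre-stimulus lines.
#'
#' @param image a background-subtracted \code{\link{linescan_image}}.
#' @param center_column centre pixel of the spike, 1-based.
#' @param F0 baseline fluorescence (detector units), from
#'   \code{\link{estimate_baseline}}.
#' @param timemap optional precomputed \code{\link{build_pixel_time_map}}
#'   for \code{image$config}; built on the fly when \code{NULL}.
#' @param correct_times logical; use per-pixel corrected times (default)
#'   or the uncorrected line-time convention.
#' @param half_width half-width of the spatial averaging window in pixels
#'   (default 3, i.e. 7 pixels).
#' @return A \code{\link{fluo_trace}}.
#' @export
extract_trace <- function(image, center_column, F0, timemap = NULL,
                          correct_times = TRUE, half_width = 3L) {
  stopifnot(inherits(image, "linescan_image"))
  center_column <- as.integer(center_column)
  half_width <- as.integer(half_width)
  cols <- (center_column - half_width):(center_column + half_width)
  if (cols[1] < 1L || cols[length(cols)] > image$config$n)
    stop("averaging window extends outside the image", call. = FALSE)
  if (!is.finite(F0) || F0 <= 0)
    stop("F0 must be a positive number", call. = FALSE)
  if (is.null(timemap)) timemap <- build_pixel_time_map(image$config)

  avg <- rowMeans(image$pixels[, cols, drop = FALSE])
  values <- avg / F0 - 1
  if (correct_times) {
    times <- timemap$times[, center_column]
  } else if (image$config$mode == "bidirectional") {
    # uncorrected bidirectional convention: consecutive forward/backward
    # line pairs are averaged and assigned the pair's mean line time, so
    # each sample carries both sweep directions
    m2 <- 2L * (image$config$m %/% 2L)
    odd <- seq(1L, m2, by = 2L)
    values <- (values[odd] + values[odd + 1L]) / 2
    times <- (timemap$line_times[odd] + timemap$line_times[odd + 1L]) / 2
  } else {
    times <- timemap$line_times
  }
  pre <- times < image$stimulus_onset
  baseline_sd <- if (sum(pre) >= 2L) stats::sd(values[pre]) else NA_real_
  fluo_trace(times = times - image$stimulus_onset, values = values,
             baseline_sd = baseline_sd, center_column = center_column,
             n_avg = length(cols), F0 = F0)
}

#' Read a grayscale TIFF as a line-scan image
#'
#' Reads a single-channel grayscale TIFF (8/12/16-bit) as an x-t image.
#' Intensities are rescaled from the \[0, 1\] range returned by the TIFF
#' reader back to detector units using the sample bit depth.
#'
#' @param path TIFF file path.
#' @param config the acquisition \code{\link{scan_config}}.
#' @param stimulus_onset stimulus time, ms from the first line.
#' @return A \code{\link{linescan_image}}.
#' @export
read_linescan_tiff <- function(path, config, stimulus_onset) {
  img <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop("expected a single-channel grayscale TIFF", call. = FALSE)
    img <- img[, , 1L]
  }
  bits <- attr(img, "bits.per.sample")
  scale <- if (is.null(bits)) 65535 else 2^bits - 1
  px <- matrix(as.numeric(img) * scale, nrow(img), ncol(img))
  linescan_image(px, config, stimulus_onset)
}

#' Write a line-scan image to a 16-bit grayscale TIFF
#'
#' @param image a \code{\link{linescan_image}}; intensities are clipped to
#'   \[0, 65535\] and stored as 16-bit samples.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_linescan_tiff <- function(image, path) {
  stopifnot(inherits(image, "linescan_image"))
  px <- pmin(pmax(image$pixels / 65535, 0), 1)
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}

#' Export a trace as a two-column CSV
#'
#' @param trace a \code{\link{fluo_trace}}.
#' @param path output CSV path; columns \code{time_ms}, \code{dF_F0}.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fluo_trace"))
  utils::write.csv(data.frame(time_ms = trace$times, dF_F0 = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}
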