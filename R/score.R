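# The cellulite undulation score: column-averaged vertical line-scan
# profiles, two-scale moving-average smoothing, baseline subtraction, and
# summed deviations aggregated over 12 adjacent regions of interest.

#' Scorer parameters
#'
#' Tunable parameters of the undulation score. The two smoothing windows are
#' physical lengths: the small window removes sub-millimetre sensor/texture
#' noise, the large window estimates the illumination baseline by removing
#' everything below ~20 mm; their difference isolates cellulite-scale
#' undulations (roughly the 2-20 mm band).
#'
#' @param small_window_mm small smoothing window in mm; default 1.
#' @param large_window_mm baseline smoothing window in mm; default 20. A
#'   `large_window_px` override is available for sensitivity analyses where
#'   the baseline window is fixed in pixels instead of mm.
#' @param n_rois number of adjacent regions of interest; default 12.
#' @param roi_width_mm,roi_height_mm ROI extent in mm; defaults 4 x 60.
#' @param deviation how the bandpassed residual is accumulated: `"absolute"`
#'   (default), `"signed"`, or `"squared"`. Signed deviations of a bandpassed
#'   signal sum to approximately zero, so absolute is the reading consistent
#'   with scores in the hundreds-to-thousands range on visibly cellulitic
#'   skin.
#' @param quantize_profile if `TRUE`, the column-averaged profile is
#'   re-quantized to whole grey levels before smoothing (strict 8-bit
#'   storage); default `FALSE`, keeping sub-grey-level precision from the
#'   column average.
#' @param large_window_px optional integer override for the baseline window.
#' @return an object of class `score_params`.
#' @export
score_params <- function(small_window_mm = 1, large_window_mm = 20,
                         n_rois = 12, roi_width_mm = 4, roi_height_mm = 60,
                         deviation = c("absolute", "signed", "squared"),
                         quantize_profile = FALSE, large_window_px = NULL) {
  deviation <- match.arg(deviation)
  if (small_window_mm <= 0 || large_window_mm <= 0)
    cm_stop("window lengths must be > 0.", "cm_invalid_parameter")
  if (is.null(large_window_px) && small_window_mm >= large_window_mm)
    cm_stop("`small_window_mm` must be smaller than `large_window_mm`.",
            "cm_invalid_parameter")
  if (n_rois < 1)
    cm_stop("`n_rois` must be >= 1.", "cm_invalid_parameter")
  if (roi_width_mm <= 0 || roi_height_mm <= 0)
    cm_stop("ROI dimensions must be > 0.", "cm_invalid_parameter")
  structure(list(small_window_mm = small_window_mm,
                 large_window_mm = large_window_mm,
                 n_rois = as.integer(n_rois),
                 roi_width_mm = roi_width_mm, roi_height_mm = roi_height_mm,
                 deviation = deviation,
                 quantize_profile = isTRUE(quantize_profile),
                 large_window_px = large_window_px),
            class = "score_params")
}

#' Region-of-interest specification
#'
#' A single scoring region, positioned in mm from the image's bottom-left
#' corner (physical coordinates increase upward, matching distances measured
#' up the thigh from the knee).
#'
#' @param x0_mm,y0_mm lower-left corner in mm.
#' @param width_mm,height_mm extent in mm; defaults 4 x 60.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(x0_mm, y0_mm, width_mm = 4, height_mm = 60) {
  if (width_mm <= 0 || height_mm <= 0)
    cm_stop("ROI dimensions must be > 0.", "cm_invalid_parameter")
  structure(list(x0_mm = x0_mm, y0_mm = y0_mm,
                 width_mm = width_mm, height_mm = height_mm),
            class = "roi_spec")
}

#' Extract the column-averaged vertical profile of an ROI
#'
#' Averages the ROI's pixel rows across its width into a single vertical
#' intensity array, ordered bottom-to-top. The average is kept at real
#' precision by default; set `quantize` to emulate strict 8-bit storage.
#'
#' @param image a [skin_image].
#' @param roi an [roi_spec].
#' @param quantize re-quantize the averaged profile to whole grey levels.
#' @return an object of class `line_profile`: list with `values` (numeric,
#'   length `height_mm * px_per_mm`) and `px_per_mm`.
#' @export
extract_profile <- function(image, roi, quantize = FALSE) {
  stopifnot(inherits(image, "skin_image"), inherits(roi, "roi_spec"))
  ppm <- image$px_per_mm
  c0 <- round(roi$x0_mm * ppm)
  nc <- max(1L, round(roi$width_mm * ppm))
  r_bot0 <- round(roi$y0_mm * ppm)       # rows below the ROI, from the bottom
  nr <- max(1L, round(roi$height_mm * ppm))
  cols <- (c0 + 1):(c0 + nc)
  rows_from_bottom <- (r_bot0 + 1):(r_bot0 + nr)
  if (c0 < 0 || c0 + nc > image$width_px ||
      r_bot0 < 0 || r_bot0 + nr > image$height_px)
    cm_stop(sprintf(
      "ROI [%g, %g] + %g x %g mm falls outside the %d x %d px raster.",
      roi$x0_mm, roi$y0_mm, roi$width_mm, roi$height_mm,
      image$width_px, image$height_px), "cm_out_of_bounds")
  rows <- image$height_px - rows_from_bottom + 1L  # top-indexed
  v <- rowMeans(image$pixels[rows, cols, drop = FALSE])
  v <- rev(v)                                      # order bottom -> top
  if (isTRUE(quantize)) v <- clip8(round_half_away(v))
  structure(list(values = v, px_per_mm = ppm), class = "line_profile")
}

#' Centred moving average with shrinking edges
#'
#' Simple moving mean over an odd window, shifting one sample at a time. At
#' the edges the window shrinks symmetrically (at index i it spans
#' `min(k, i-1, L-i)` samples each side, `k = (w-1)/2`), which preserves
#' constants and straight lines everywhere. The fully-valid interval, where
#' the complete window fits, is returned as the `"valid_range"` attribute
#' (1-based `[k+1, L-k]`).
#'
#' @param values numeric vector.
#' @param window_px odd integer window width, >= 1; the vector must be at
#'   least as long as the window.
#' @return numeric vector of the same length, with attribute `valid_range`.
#' @export
moving_average <- function(values, window_px) {
  if (!is.numeric(values) || any(!is.finite(values)))
    cm_stop("`values` must be finite numerics.", "cm_invalid_input")
  window_px <- as.integer(window_px)
  if (is.na(window_px) || window_px < 1 || window_px %% 2 == 0)
    cm_stop("`window_px` must be an odd integer >= 1.", "cm_invalid_input")
  L <- length(values)
  if (L < window_px)
    cm_stop(sprintf("array of length %d shorter than window %d.",
                    L, window_px), "cm_invalid_input")
  k <- (window_px - 1L) %/% 2L
  i <- seq_len(L)
  ki <- pmin(k, i - 1L, L - i)
  cs <- c(0, cumsum(values))
  out <- (cs[i + ki + 1L] - cs[i - ki]) / (2 * ki + 1)
  attr(out, "valid_range") <- c(k + 1L, L - k)
  out
}

#' Two-scale bandpass deviation of a profile
#'
#' The core of the score. The profile is smoothed with the small window
#' (removing sub-mm features, `px1`), then `px1` is smoothed again with the
#' large window to form the illumination baseline (`px2`). Their difference
#' over the interval where the large window fits entirely is the bandpassed
#' undulation signal; its summed deviations are the ROI score. A constant or
#' linearly ramping profile (uniform skin, smooth illumination gradient)
#' scores exactly 0.
#'
#' @param profile a `line_profile` from [extract_profile], or a bare numeric
#'   vector plus `px_per_mm`.
#' @param params a [score_params].
#' @param px_per_mm calibration, only needed when `profile` is a bare vector.
#' @return list with `roi_score` (non-negative under absolute/squared
#'   deviation) and `pair`, an object of class `smoothed_pair` holding `px1`,
#'   `px2` and `valid_range`.
#' @export
bandpass_deviation <- function(profile, params = score_params(),
                               px_per_mm = NULL) {
  if (inherits(profile, "line_profile")) {
    v <- profile$values
    ppm <- profile$px_per_mm
  } else {
    v <- as.numeric(profile)
    ppm <- px_per_mm
    if (is.null(ppm))
      cm_stop("`px_per_mm` required for a bare numeric profile.",
              "cm_invalid_input")
  }
  if (isTRUE(params$quantize_profile)) v <- clip8(round_half_away(v))
  w_small <- odd_window_px(params$small_window_mm, ppm)
  w_large <- if (!is.null(params$large_window_px))
    as.integer(params$large_window_px) else
      odd_window_px(params$large_window_mm, ppm)
  px1 <- moving_average(v, w_small)
  px2 <- moving_average(as.numeric(px1), w_large)
  k2 <- (w_large - 1L) %/% 2L
  valid <- c(k2 + 1L, length(v) - k2)
  if (valid[2] < valid[1])
    cm_stop("profile shorter than the baseline window.", "cm_invalid_input")
  idx <- valid[1]:valid[2]
  band <- px1[idx] - px2[idx]
  roi_score <- switch(params$deviation,
                      absolute = sum(abs(band)),
                      signed = sum(band),
                      squared = sum(band^2))
  pair <- structure(list(px1 = as.numeric(px1), px2 = as.numeric(px2),
                         valid_range = valid),
                    class = "smoothed_pair")
  list(roi_score = roi_score, pair = pair)
}

#' Score an image over the 12-ROI strip
#'
#' Applies [bandpass_deviation] to each of `n_rois` adjacent (non-overlapping,
#' side-by-side) 4 x 60 mm regions starting at `region_origin_mm`, and sums
#' the per-ROI deviation scores into the overall undulation score. Smooth
#' featureless skin scores exactly 0; visibly cellulitic skin scores in the
#' hundreds to thousands.
#'
#' @param image a [skin_image].
#' @param region_origin_mm length-2 c(x, y), the lower-left corner of the
#'   first ROI in mm from the image's bottom-left.
#' @param params a [score_params].
#' @return an object of class `undulation_score`: list with `roi_scores`
#'   (length `n_rois`), `total` (their sum), `region_origin_mm` and `params`.
#' @export
score_image <- function(image, region_origin_mm = c(0, 0),
                        params = score_params()) {
  stopifnot(inherits(image, "skin_image"), inherits(params, "score_params"))
  ppm <- image$px_per_mm
  strip_w <- params$n_rois * params$roi_width_mm
  need_w <- round((region_origin_mm[1] + strip_w) * ppm)
  if (region_origin_mm[1] < 0 || need_w > image$width_px)
    cm_stop(sprintf(
      "the %d-ROI strip needs an image at least %d px (%.0f mm) wide from x0 = %g mm; image is %d px.",
      params$n_rois, need_w, strip_w + region_origin_mm[1],
      region_origin_mm[1], image$width_px), "cm_out_of_bounds")
  roi_scores <- vapply(seq_len(params$n_rois), function(k) {
    roi <- roi_spec(region_origin_mm[1] + (k - 1) * params$roi_width_mm,
                    region_origin_mm[2],
                    params$roi_width_mm, params$roi_height_mm)
    prof <- extract_profile(image, roi, quantize = params$quantize_profile)
    bandpass_deviation(prof, params)$roi_score
  }, numeric(1))
  structure(list(roi_scores = roi_scores, total = sum(roi_scores),
                 region_origin_mm = region_origin_mm, params = params),
            class = "undulation_score")
}

#' @export
print.undulation_score <- function(x, ...) {
  cat(sprintf("<undulation_score> total = %.4g over %d ROIs\n",
              x$total, length(x$roi_scores)))
  cat("  per ROI:", paste(sprintf("%.3g", x$roi_scores), collapse = " "),
      "\n")
  invisible(x)
}

#' Digitally oblate circumference marks
#'
#' Replaces the marked horizontal bands by per-column linear interpolation
#' between the nearest unmarked rows below and above, approximating the skin
#' intensity hidden under the drawn lines so that scoring is not dominated by
#' the ink.
#'
#' @param image a [skin_image].
#' @param mark_rows_mm band centre positions in mm from the bottom (typically
#'   from the image's sidecar metadata).
#' @param thickness_mm band thickness in mm; default 2.
#' @return a [skin_image] with the bands interpolated away.
#' @export
oblate_marks <- function(image, mark_rows_mm, thickness_mm = 2) {
  stopifnot(inherits(image, "skin_image"))
  if (length(mark_rows_mm) == 0) return(image)
  marked <- rep(FALSE, image$height_px)
  for (y in mark_rows_mm) marked[mark_rows_px(image, y, thickness_mm)] <- TRUE
  px <- image$pixels
  runs <- rle(marked)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (b in which(runs$values)) {
    r0 <- starts[b]; r1 <- ends[b]
    if (r0 == 1L || r1 == image$height_px)
      cm_stop("marked band touches the image border; cannot interpolate.",
              "cm_cannot_interpolate")
    above <- px[r0 - 1L, ]   # row index grows downward
    below <- px[r1 + 1L, ]
    n <- r1 - r0 + 1L
    w <- seq_len(n) / (n + 1)
    interp <- outer(w, below - above) + rep(above, each = n)
    px[r0:r1, ] <- clip8(round_half_away(interp))
  }
  out <- image
  out$pixels <- px
  out$meta$oblated_mm <- mark_rows_mm
  out
}
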