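# Rendering of surface fields into photograph-like 8-bit images under
# near-grazing illumination from the bottom of the frame.

#' Illumination model
#'
#' Describes the study-style lighting geometry: a beam travelling upward
#' across the frame from a source mounted at platform level below the thigh,
#' tilted `elevation_deg` away from the participant's vertical axis, with a
#' finite beam divergence. The divergence is modelled as a linear tilt of the
#' light direction across the frame height spanning +/- `dispersion_deg`/2
#' around the nominal elevation.
#'
#' @param elevation_deg beam elevation relative to the vertical axis, in
#'   (0, 90); default 70.
#' @param dispersion_deg beam divergence in degrees; default 15.
#' @param ambient_fraction fraction of shading-independent light in `[0, 1)`.
#' @return an object of class `illumination_model`.
#' @export
illumination_model <- function(elevation_deg = 70, dispersion_deg = 15,
                               ambient_fraction = 0.2) {
  if (!(elevation_deg > 0 && elevation_deg < 90))
    cm_stop("`elevation_deg` must lie strictly between 0 and 90.",
            "cm_invalid_parameter")
  if (dispersion_deg < 0)
    cm_stop("`dispersion_deg` must be >= 0.", "cm_invalid_parameter")
  if (!(ambient_fraction >= 0 && ambient_fraction < 1))
    cm_stop("`ambient_fraction` must lie in [0, 1).", "cm_invalid_parameter")
  structure(list(elevation_deg = elevation_deg, azimuth = "from_below",
                 dispersion_deg = dispersion_deg,
                 ambient_fraction = ambient_fraction),
            class = "illumination_model")
}

#' Construct a skin image
#'
#' An 8-bit single-channel raster with a mm-per-pixel calibration. Pixel
#' matrix row 1 is the TOP of the image (standard raster convention); all
#' physical (mm) coordinates used by the scorer are measured from the
#' bottom-left corner, matching how positions on a thigh are measured upward
#' from the knee.
#'
#' @param pixels integer matrix with values in `[0, 255]`; row 1 = top row.
#' @param px_per_mm pixels per millimetre (> 0); default 10.
#' @param meta optional named list of provenance metadata.
#' @return an object of class `skin_image` with fields `pixels`, `px_per_mm`,
#'   `width_px`, `height_px`, `meta`.
#' @export
skin_image <- function(pixels, px_per_mm = 10, meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    cm_stop("`pixels` must be a numeric matrix.", "cm_invalid_parameter")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != floor(pixels)))
    cm_stop("`pixels` must be integers in [0, 255].", "cm_invalid_parameter")
  if (!is.numeric(px_per_mm) || px_per_mm <= 0)
    cm_stop("`px_per_mm` must be > 0.", "cm_invalid_parameter")
  structure(list(pixels = pixels, px_per_mm = px_per_mm,
                 width_px = ncol(pixels), height_px = nrow(pixels),
                 meta = meta),
            class = "skin_image")
}

#' @export
print.skin_image <- function(x, ...) {
  cat(sprintf("<skin_image> %d x %d px @ %g px/mm (%.1f x %.1f mm)\n",
              x$width_px, x$height_px, x$px_per_mm,
              x$width_px / x$px_per_mm, x$height_px / x$px_per_mm))
  cat(sprintf("  intensity: [%d, %d]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Bilinear interpolation of field heights at arbitrary mm coordinates.
# x, y are vectors; returns the ny-by-nx matrix h(y_i, x_j). Coordinates
# outside the sampled centres are clamped to the border sample.
interp_field <- function(field, x, y) {
  co <- field_coords(field)
  gs <- field$grid_spacing_mm
  h <- field$heights
  fx <- pmin(pmax((x - co$x[1]) / gs, 0), length(co$x) - 1)
  fy <- pmin(pmax((y - co$y[1]) / gs, 0), length(co$y) - 1)
  jx0 <- pmin(floor(fx), length(co$x) - 1 - (length(co$x) > 1))
  iy0 <- pmin(floor(fy), length(co$y) - 1 - (length(co$y) > 1))
  tx <- fx - jx0
  ty <- fy - iy0
  jx0 <- jx0 + 1; iy0 <- iy0 + 1
  jx1 <- pmin(jx0 + 1, length(co$x)); iy1 <- pmin(iy0 + 1, length(co$y))
  # expand over the grid of (y, x)
  H00 <- h[iy0, jx0, drop = FALSE]; H01 <- h[iy0, jx1, drop = FALSE]
  H10 <- h[iy1, jx0, drop = FALSE]; H11 <- h[iy1, jx1, drop = FALSE]
  TX <- matrix(tx, nrow = length(y), ncol = length(x), byrow = TRUE)
  TY <- matrix(ty, nrow = length(y), ncol = length(x))
  (1 - TY) * ((1 - TX) * H00 + TX * H01) + TY * ((1 - TX) * H10 + TX * H11)
}

# Finite-difference gradients of a height map sampled at spacing d (mm).
# Central differences in the interior, one-sided at the borders.
grad_fd <- function(h, d) {
  ny <- nrow(h); nx <- ncol(h)
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  if (nx >= 3)
    gx[, 2:(nx - 1)] <- (h[, 3:nx, drop = FALSE] -
                           h[, 1:(nx - 2), drop = FALSE]) / (2 * d)
  if (nx >= 2) {
    gx[, 1] <- (h[, 2] - h[, 1]) / d
    gx[, nx] <- (h[, nx] - h[, nx - 1]) / d
  }
  if (ny >= 3)
    gy[2:(ny - 1), ] <- (h[3:ny, , drop = FALSE] -
                           h[1:(ny - 2), , drop = FALSE]) / (2 * d)
  if (ny >= 2) {
    gy[1, ] <- (h[2, ] - h[1, ]) / d
    gy[ny, ] <- (h[ny, ] - h[ny - 1, ]) / d
  }
  list(gx = gx, gy = gy)
}

#' Render a surface field into a photograph-like image
#'
#' Lambertian shading under the bottom-mounted grazing beam. For each pixel,
#' intensity before quantization is
#' `base_level * (ambient + (1 - ambient) * max(0, n.l) / c)`, where `n` is
#' the unit surface normal from finite differences of the height map, `l` the
#' unit direction toward the light at that pixel (tilted linearly across the
#' frame height within the beam dispersion), and `c` the value `n.l` takes on
#' a flat surface under the same local `l`, so a flat field renders at
#' exactly `base_level` before noise. Gaussian sensor noise is added, then
#' the result is rounded half away from zero and clipped to `[0, 255]`.
#'
#' @param field a [surface_field]; its extent determines the frame unless
#'   `width_px`/`height_px` are given.
#' @param illum an [illumination_model].
#' @param px_per_mm pixels per millimetre of the output raster; default 10.
#' @param base_level flat-skin grey level in (0, 255); default 180.
#' @param noise_sd standard deviation of additive Gaussian sensor noise in
#'   grey levels (>= 0).
#' @param seed integer seed for the noise generator (required when
#'   `noise_sd > 0`).
#' @param width_px,height_px optional raster size; must be covered by the
#'   field extent.
#' @return a [skin_image]; `meta` records the renderer parameters.
#' @export
render_image <- function(field, illum = illumination_model(), px_per_mm = 10,
                         base_level = 180, noise_sd = 0, seed = NULL,
                         width_px = NULL, height_px = NULL) {
  stopifnot(inherits(field, "surface_field"),
            inherits(illum, "illumination_model"))
  if (!(base_level > 0 && base_level < 255))
    cm_stop("`base_level` must lie in (0, 255).", "cm_invalid_parameter")
  if (noise_sd < 0)
    cm_stop("`noise_sd` must be >= 0.", "cm_invalid_parameter")
  if (noise_sd > 0 && is.null(seed))
    cm_stop("`seed` is required when `noise_sd > 0`.", "cm_invalid_parameter")
  W <- width_px %||% round(field$extent_mm[["width"]] * px_per_mm)
  H <- height_px %||% round(field$extent_mm[["height"]] * px_per_mm)
  if (W / px_per_mm > field$extent_mm[["width"]] + 1e-9 ||
      H / px_per_mm > field$extent_mm[["height"]] + 1e-9)
    cm_stop(sprintf(
      "field extent %.1f x %.1f mm too small for a %d x %d px raster at %g px/mm.",
      field$extent_mm[["width"]], field$extent_mm[["height"]], W, H, px_per_mm),
      "cm_size_mismatch")
  d <- 1 / px_per_mm
  # pixel centres in mm from the bottom-left; heights stored bottom-up here
  x_mm <- (seq_len(W) - 0.5) * d
  y_mm <- (seq_len(H) - 0.5) * d
  h <- interp_field(field, x_mm, y_mm)
  g <- grad_fd(h, d)
  # light direction per row: elevation tilts linearly bottom -> top
  yfrac <- (y_mm - y_mm[1]) / max(y_mm[H] - y_mm[1], d)
  alpha <- (illum$elevation_deg +
              illum$dispersion_deg * (yfrac - 0.5)) * pi / 180
  ca <- matrix(cos(alpha), H, W)
  sa <- matrix(sin(alpha), H, W)
  # n = (-gx, -gy, 1)/N, l = (0, -cos a, sin a) pointing toward the source
  ndotl <- (g$gy * ca + sa) / sqrt(1 + g$gx^2 + g$gy^2)
  amb <- illum$ambient_fraction
  shade <- amb + (1 - amb) * pmax(0, ndotl) / sa  # sa = flat-surface n.l
  img <- base_level * shade
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
  }
  px <- clip8(round_half_away(img))
  # flip to standard raster orientation (row 1 = top)
  px <- px[H:1, , drop = FALSE]
  skin_image(px, px_per_mm,
             meta = list(descriptor = field$descriptor,
                         elevation_deg = illum$elevation_deg,
                         dispersion_deg = illum$dispersion_deg,
                         ambient_fraction = amb,
                         base_level = base_level, noise_sd = noise_sd,
                         seed = seed))
}

# Pixel rows (top-indexed) covered by a horizontal band centred at y_mm with
# the given thickness; exactly round(thickness * px_per_mm) rows.
mark_rows_px <- function(image, y_mm, thickness_mm) {
  n <- round(thickness_mm * image$px_per_mm)
  # first covered row counted from the bottom
  r_bot <- round((y_mm - thickness_mm / 2) * image$px_per_mm) + 1
  rows_from_bottom <- r_bot:(r_bot + n - 1)
  if (any(rows_from_bottom < 1) || any(rows_from_bottom > image$height_px))
    cm_stop(sprintf("mark at %g mm extends outside the raster.", y_mm),
            "cm_out_of_bounds")
  image$height_px - rows_from_bottom + 1L
}

#' Draw circumference marks on an image
#'
#' Superimposes dark horizontal bands emulating the indelible lines drawn on
#' the skin to position the circumference tape. Marked pixels become
#' `pixel * (1 - darkness)` (quantized half away from zero). Returns a new
#' image; the input is not modified.
#'
#' @param image a [skin_image].
#' @param line_rows_mm vector of band centre positions, mm above the bottom
#'   edge.
#' @param darkness absorption of the ink in `[0, 1]`; 0 leaves the image
#'   unchanged, 1 makes marked rows black.
#' @param thickness_mm band thickness in mm; default 2.
#' @return a [skin_image] with the marks applied.
#' @export
draw_marks <- function(image, line_rows_mm, darkness = 0.8,
                       thickness_mm = 2) {
  stopifnot(inherits(image, "skin_image"))
  if (!(darkness >= 0 && darkness <= 1))
    cm_stop("`darkness` must lie in [0, 1].", "cm_invalid_parameter")
  px <- image$pixels
  for (y in line_rows_mm) {
    rows <- mark_rows_px(image, y, thickness_mm)
    px[rows, ] <- round_half_away(px[rows, , drop = FALSE] * (1 - darkness))
  }
  out <- image
  out$pixels <- px
  out$meta$marks_mm <- line_rows_mm
  out$meta$mark_thickness_mm <- thickness_mm
  out
}
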