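# Ground-truth skin surfaces: height maps in mm over a regular mm-grid.
#
# Convention: `heights` is a matrix with row 1 at the BOTTOM of the surface,
# sample (i, j) centred at y = (i - 0.5) * grid_spacing_mm,
# x = (j - 0.5) * grid_spacing_mm, measured from the bottom-left corner.

#' Construct a surface field
#'
#' A `surface_field` is a height map (mm) sampled on a square mm-grid. It is
#' the ground truth that the renderer turns into a photograph-like image, and
#' against which scorer behaviour is validated.
#'
#' @param heights numeric matrix of surface elevations in mm; row 1 is the
#'   bottom edge of the surface.
#' @param grid_spacing_mm spacing between samples in mm (same along both axes).
#' @param descriptor free-text provenance string.
#' @return an object of class `surface_field` with fields `heights`,
#'   `grid_spacing_mm`, `extent_mm` (c(width, height)) and `descriptor`.
#' @export
surface_field <- function(heights, grid_spacing_mm, descriptor = "") {
  if (!is.matrix(heights) || !is.numeric(heights))
    cm_stop("`heights` must be a numeric matrix.", "cm_invalid_parameter")
  if (!all(is.finite(heights)))
    cm_stop("`heights` must be finite everywhere.", "cm_invalid_parameter")
  if (!is.numeric(grid_spacing_mm) || length(grid_spacing_mm) != 1 ||
      grid_spacing_mm <= 0)
    cm_stop("`grid_spacing_mm` must be a single positive number.",
            "cm_invalid_parameter")
  structure(
    list(
      heights = heights,
      grid_spacing_mm = grid_spacing_mm,
      extent_mm = c(width = ncol(heights) * grid_spacing_mm,
                    height = nrow(heights) * grid_spacing_mm),
      descriptor = descriptor
    ),
    class = "surface_field"
  )
}

#' @export
print.surface_field <- function(x, ...) {
  cat(sprintf("<surface_field> %.1f x %.1f mm @ %.3g mm/sample\n",
              x$extent_mm[["width"]], x$extent_mm[["height"]],
              x$grid_spacing_mm))
  cat(sprintf("  heights: [%.4g, %.4g] mm  %s\n",
              min(x$heights), max(x$heights), x$descriptor))
  invisible(x)
}

# Sample grid coordinates (mm) of a field.
field_coords <- function(field) {
  gs <- field$grid_spacing_mm
  list(x = (seq_len(ncol(field$heights)) - 0.5) * gs,
       y = (seq_len(nrow(field$heights)) - 0.5) * gs)
}

#' Sinusoidal undulation field
#'
#' Generates a plane-wave undulation
#' `h(x, y) = A sin(2 pi (x sin(theta) + y cos(theta)) / lambda + phase)`.
#' Orientation 0 deg gives horizontal ridges (height varies along the
#' vertical axis only), which is the configuration a bottom-mounted grazing
#' light reveals; 90 deg gives vertical ridges, which it cannot.
#'
#' @param amplitude_mm ridge amplitude A in mm (>= 0).
#' @param wavelength_mm ridge wavelength lambda in mm (> 0).
#' @param orientation_deg ridge orientation theta in degrees; 0 = horizontal
#'   ridges.
#' @param phase_rad phase offset in radians.
#' @param extent_mm numeric length-2, c(width, height) of the surface in mm.
#' @param grid_spacing_mm sample spacing in mm.
#' @return a [surface_field].
#' @export
make_undulation_field <- function(amplitude_mm, wavelength_mm,
                                  orientation_deg = 0, phase_rad = 0,
                                  extent_mm = c(60, 70),
                                  grid_spacing_mm = 0.1) {
  if (amplitude_mm < 0)
    cm_stop("`amplitude_mm` must be >= 0.", "cm_invalid_parameter")
  if (wavelength_mm <= 0)
    cm_stop("`wavelength_mm` must be > 0.", "cm_invalid_parameter")
  if (grid_spacing_mm <= 0)
    cm_stop("`grid_spacing_mm` must be > 0.", "cm_invalid_parameter")
  extent_mm <- rep_len(extent_mm, 2)
  nx <- max(1L, round(extent_mm[1] / grid_spacing_mm))
  ny <- max(1L, round(extent_mm[2] / grid_spacing_mm))
  x <- (seq_len(nx) - 0.5) * grid_spacing_mm
  y <- (seq_len(ny) - 0.5) * grid_spacing_mm
  th <- orientation_deg * pi / 180
  # outer over (y rows, x cols): argument x sin(theta) + y cos(theta)
  arg <- outer(y * cos(th), x * sin(th), `+`)
  h <- amplitude_mm * sin(2 * pi * arg / wavelength_mm + phase_rad)
  surface_field(h, grid_spacing_mm,
                sprintf("sinusoid A=%gmm lambda=%gmm theta=%gdeg",
                        amplitude_mm, wavelength_mm, orientation_deg))
}

#' Random dimpled field
#'
#' Superimposes Gaussian-bump depressions at uniform-random centres over a
#' flat surface, as an irregular "orange-peel" surrogate for real cellulite
#' texture. Deterministic for a fixed seed.
#'
#' @param n_dimples number of depressions (>= 0).
#' @param depth_mm_range length-2 range of depression depths in mm.
#' @param radius_mm_range length-2 range of Gaussian radii (sigma) in mm.
#' @param extent_mm c(width, height) of the surface in mm.
#' @param grid_spacing_mm sample spacing in mm.
#' @param seed integer seed (required, for reproducibility).
#' @return a [surface_field] with non-positive heights.
#' @export
make_dimple_field <- function(n_dimples, depth_mm_range = c(0.3, 0.8),
                              radius_mm_range = c(3, 8),
                              extent_mm = c(60, 70), grid_spacing_mm = 0.1,
                              seed) {
  if (missing(seed))
    cm_stop("`seed` is required for a reproducible dimple field.",
            "cm_invalid_parameter")
  if (length(depth_mm_range) != 2 || any(depth_mm_range < 0) ||
      diff(depth_mm_range) < 0)
    cm_stop("`depth_mm_range` must be a non-decreasing pair of depths >= 0.",
            "cm_invalid_parameter")
  if (length(radius_mm_range) != 2 || any(radius_mm_range <= 0) ||
      diff(radius_mm_range) < 0)
    cm_stop("`radius_mm_range` must be a non-decreasing pair of radii > 0.",
            "cm_invalid_parameter")
  if (grid_spacing_mm <= 0)
    cm_stop("`grid_spacing_mm` must be > 0.", "cm_invalid_parameter")
  extent_mm <- rep_len(extent_mm, 2)
  nx <- max(1L, round(extent_mm[1] / grid_spacing_mm))
  ny <- max(1L, round(extent_mm[2] / grid_spacing_mm))
  x <- (seq_len(nx) - 0.5) * grid_spacing_mm
  y <- (seq_len(ny) - 0.5) * grid_spacing_mm
  h <- matrix(0, nrow = ny, ncol = nx)
  if (n_dimples > 0) {
    rng <- local({
      set.seed(seed)
      list(cx = runif(n_dimples, 0, extent_mm[1]),
           cy = runif(n_dimples, 0, extent_mm[2]),
           depth = runif(n_dimples, depth_mm_range[1], depth_mm_range[2]),
           radius = runif(n_dimples, radius_mm_range[1], radius_mm_range[2]))
    })
    for (k in seq_len(n_dimples)) {
      dx2 <- (x - rng$cx[k])^2
      dy2 <- (y - rng$cy[k])^2
      h <- h - rng$depth[k] *
        exp(-outer(dy2, dx2, `+`) / (2 * rng$radius[k]^2))
    }
  }
  fld <- surface_field(h, grid_spacing_mm,
                       sprintf("dimples n=%d seed=%d", n_dimples,
                               as.integer(seed)))
  # keep the drawn dimple parameters so the superposition can be re-derived
  fld$dimples <- if (n_dimples > 0)
    data.frame(cx = rng$cx, cy = rng$cy, depth = rng$depth,
               radius = rng$radius)
  else data.frame(cx = numeric(0), cy = numeric(0), depth = numeric(0),
                  radius = numeric(0))
  fld
}

#' Flat field
#'
#' Perfectly smooth skin at a constant elevation; renders to a uniform image
#' and scores exactly zero.
#' @inheritParams make_dimple_field
#' @param level_mm constant elevation in mm.
#' @return a [surface_field].
#' @export
make_flat_field <- function(extent_mm = c(60, 70), grid_spacing_mm = 0.1,
                            level_mm = 0) {
  extent_mm <- rep_len(extent_mm, 2)
  nx <- max(1L, round(extent_mm[1] / grid_spacing_mm))
  ny <- max(1L, round(extent_mm[2] / grid_spacing_mm))
  surface_field(matrix(level_mm, ny, nx), grid_spacing_mm, "flat")
}
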