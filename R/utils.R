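# Internal helpers shared across modules.

#' @keywords internal
cm_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "cellumetry_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

#' Round half away from zero
#'
#' Fixed quantization rule used everywhere an intensity is written to 8 bits,
#' so renders are bit-reproducible across platforms (base `round()` rounds
#' half to even, which is representation-sensitive).
#' @param x numeric vector or matrix.
#' @return `x` rounded half away from zero, same shape.
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Clip to the 8-bit range after quantization (shape-preserving).
clip8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Convert a physical window length to an odd pixel count
#'
#' Windows are specified in millimetres and converted via the image
#' calibration; the centred moving average needs an odd width, so the pixel
#' count is rounded to the nearest odd integer (ties round up), never below 1.
#' @param window_mm window length in mm.
#' @param px_per_mm pixels per millimetre.
#' @return odd integer window width in pixels.
#' @export
odd_window_px <- function(window_mm, px_per_mm) {
  if (!is.numeric(window_mm) || window_mm <= 0)
    cm_stop("`window_mm` must be a positive number.", "cm_invalid_parameter")
  if (!is.numeric(px_per_mm) || px_per_mm <= 0)
    cm_stop("`px_per_mm` must be a positive number.", "cm_invalid_parameter")
  # 2*floor(x/2) + 1 is the nearest odd integer to x, rounding ties upward
  as.integer(2L * floor(window_mm * px_per_mm / 2) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
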