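# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the implementation they check.

# Direct centred moving mean with symmetric shrinking edges.
ma_direct <- function(v, w) {
  k <- (w - 1) %/% 2
  L <- length(v)
  out <- numeric(L)
  for (i in seq_len(L)) {
    ki <- min(k, i - 1, L - i)
    out[i] <- mean(v[(i - ki):(i + ki)])
  }
  out
}

# Direct two-scale bandpass score (absolute deviation).
bandpass_direct <- function(v, w_small, w_large) {
  p1 <- ma_direct(v, w_small)
  p2 <- ma_direct(p1, w_large)
  k2 <- (w_large - 1) %/% 2
  idx <- (k2 + 1):(length(v) - k2)
  sum(abs(p1[idx] - p2[idx]))
}

# Exact two-tailed signed-rank p-value by exhaustive sign enumeration.
wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  count <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    W <- sum(r[bits == 1])
    if (abs(W - mu) >= abs(W_obs - mu) - 1e-9) count <- count + 1
  }
  count / 2^n
}

# Per-pixel Lambertian shading oracle for a field whose grid coincides with
# the pixel grid (grid_spacing_mm == 1/px_per_mm). Returns the unclipped,
# unquantized intensity matrix in bottom-up row order.
shade_direct <- function(h, d, elevation_deg, dispersion_deg, ambient,
                         base_level) {
  ny <- nrow(h); nx <- ncol(h)
  out <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) {
    yfrac <- (i - 1) / (ny - 1)
    a <- (elevation_deg + dispersion_deg * (yfrac - 0.5)) * pi / 180
    for (j in seq_len(nx)) {
      gx <- if (j == 1) (h[i, 2] - h[i, 1]) / d
      else if (j == nx) (h[i, nx] - h[i, nx - 1]) / d
      else (h[i, j + 1] - h[i, j - 1]) / (2 * d)
      gy <- if (i == 1) (h[2, j] - h[1, j]) / d
      else if (i == ny) (h[ny, j] - h[ny - 1, j]) / d
      else (h[i + 1, j] - h[i - 1, j]) / (2 * d)
      ndotl <- (gy * cos(a) + sin(a)) / sqrt(1 + gx^2 + gy^2)
      out[i, j] <- base_level *
        (ambient + (1 - ambient) * max(0, ndotl) / sin(a))
    }
  }
  out
}

# Small rendered fixture shared across tests: a horizontal in-band ridge
# covering a reduced 3-ROI strip (keeps the default 60 mm ROI height).
ridge_image <- function(amplitude_mm = 0.06, wavelength_mm = 10,
                        orientation_deg = 0, n_rois = 3, noise_sd = 0,
                        seed = NULL) {
  extent <- c(n_rois * 4 + 4, 64)
  f <- make_undulation_field(amplitude_mm, wavelength_mm, orientation_deg,
                             extent_mm = extent)
  render_image(f, noise_sd = noise_sd, seed = seed)
}

small_params <- function(n_rois = 3, ...) score_params(n_rois = n_rois, ...)
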