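# The line-scan bandpass score.

test_that("profile extraction averages ROI columns at real precision", {
  img <- skin_image(matrix(128L, 120, 60), px_per_mm = 2)
  p <- extract_profile(img, roi_spec(0, 0, 4, 60))
  expect_length(p$values, 120)
  expect_true(all(p$values == 128))

  # columns cycle 100/120/140/160 across the width -> profile all 130
  px <- matrix(rep(c(100, 120, 140, 160), each = 120), 120, 60)
  img2 <- skin_image(px, px_per_mm = 2)
  p2 <- extract_profile(img2, roi_spec(0, 0, 4, 60))
  expect_true(all(p2$values == 130))

  # width of one pixel: the profile is that pixel column, bottom-up
  imgv <- skin_image(matrix(seq_len(10) * 10L, 10, 4), px_per_mm = 1)
  pv <- extract_profile(imgv, roi_spec(1, 2, 1, 6))
  expect_equal(pv$values, rev(imgv$pixels[8:3, 2]))

  expect_error(extract_profile(img, roi_spec(28, 0, 4, 60)),
               class = "cm_out_of_bounds")
  expect_error(extract_profile(img, roi_spec(0, 10, 4, 60)),
               class = "cm_out_of_bounds")
})

test_that("moving average matches hand values and keeps length", {
  v <- c(0, 0, 0, 10, 0, 0, 0)
  expect_identical(as.numeric(moving_average(v, 1)), v)
  out <- moving_average(v, 3)
  expect_equal(as.numeric(out), c(0, 0, 10 / 3, 10 / 3, 10 / 3, 0, 0))
  expect_equal(attr(out, "valid_range"), c(2L, 6L))
  expect_equal(as.numeric(moving_average(rep(4.5, 9), 5)), rep(4.5, 9))
  expect_error(moving_average(v, 4), class = "cm_invalid_input")
  expect_error(moving_average(v, 9), class = "cm_invalid_input")
})

test_that("moving average agrees with the direct-loop oracle everywhere", {
  set.seed(11)
  for (w in c(3, 11, 201)) {
    v <- rnorm(600)
    expect_equal(as.numeric(moving_average(v, w)), ma_direct(v, w),
                 tolerance = 1e-12)
  }
})

test_that("window conversion gives odd pixel counts at physical scales", {
  expect_identical(odd_window_px(1, 10), 11L)
  expect_identical(odd_window_px(20, 10), 201L)
  expect_identical(odd_window_px(0.05, 10), 1L)
  expect_identical(odd_window_px(1, 3), 3L)
  expect_error(odd_window_px(0, 10), class = "cm_invalid_parameter")
})

test_that("constant and linear-ramp profiles score exactly zero", {
  pp <- score_params()
  expect_equal(bandpass_deviation(rep(128, 600), pp, 10)$roi_score, 0)
  ramp <- seq(40, 200, length.out = 600)
  expect_equal(bandpass_deviation(ramp, pp, 10)$roi_score, 0,
               tolerance = 1e-9)
})

test_that("bandpass deviation matches a brute-force implementation", {
  set.seed(42)
  pp <- score_params()
  for (i in 1:100) {
    v <- runif(600, 60, 220)
    got <- bandpass_deviation(v, pp, 10)$roi_score
    want <- bandpass_direct(v, 11, 201)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # sinusoid case: strictly positive and oracle-equal
  x <- (1:600 - 0.5) / 10
  v <- 128 + 3 * sin(2 * pi * x / 10)
  got <- bandpass_deviation(v, pp, 10)
  expect_gt(got$roi_score, 0)
  expect_equal(got$roi_score, bandpass_direct(v, 11, 201),
               tolerance = 1e-9)
  expect_equal(got$pair$valid_range, c(101L, 500L))
})

test_that("deviation variants relate as expected", {
  x <- (1:600 - 0.5) / 10
  v <- 128 + 3 * sin(2 * pi * x / 10)   # whole periods across valid range
  s_abs <- bandpass_deviation(v, score_params(deviation = "absolute"), 10)
  s_sgn <- bandpass_deviation(v, score_params(deviation = "signed"), 10)
  s_sq <- bandpass_deviation(v, score_params(deviation = "squared"), 10)
  # signed deviations of a bandpassed signal nearly cancel
  expect_lt(abs(s_sgn$roi_score), 0.05 * s_abs$roi_score)
  expect_gt(s_sq$roi_score, 0)
})

test_that("score is offset-invariant and scale-equivariant", {
  set.seed(5)
  v <- 120 + as.numeric(stats::filter(rnorm(700), rep(1 / 30, 30),
                                      sides = 2))[31:630] * 20
  v <- v[is.finite(v)]
  pp <- score_params()
  base <- bandpass_deviation(v, pp, 10)$roi_score
  expect_equal(bandpass_deviation(v + 17.3, pp, 10)$roi_score, base,
               tolerance = 1e-9)
  expect_equal(bandpass_deviation(v * 1.7, pp, 10)$roi_score, 1.7 * base,
               tolerance = 1e-9)
  expect_equal(bandpass_deviation(v * 0, pp, 10)$roi_score, 0)
})

test_that("wavelengths outside the 2-20 mm band are strongly suppressed", {
  pp <- score_params()
  score_at <- function(lam, phase = 0) {
    x <- (1:600 - 0.5) / 10
    bandpass_deviation(128 + 2 * sin(2 * pi * x / lam + phase), pp,
                       10)$roi_score
  }
  for (ph in c(0, 1.1, 2.7)) {
    in_band <- score_at(10, ph)
    # sub-mm texture and >=20 mm illumination trends pass at most ~11% of
    # the in-band response (the 20 mm boxcar's sinc sidelobe bounds the
    # 80 mm leak at ~10%)
    expect_lt(score_at(0.4, ph), 0.11 * in_band)
    expect_lt(score_at(80, ph), 0.11 * in_band)
  }
})

test_that("roi score rises with rendered amplitude in the linear regime", {
  amps <- c(0.01, 0.02, 0.04, 0.08)
  totals <- sapply(amps, function(a)
    score_image(ridge_image(a), c(2, 2), small_params())$total)
  expect_true(all(diff(totals) > 0))
})

test_that("image scoring sums adjacent per-ROI scores", {
  img <- ridge_image(0.06, n_rois = 3)
  pp <- small_params()
  sc <- score_image(img, c(2, 2), pp)
  expect_length(sc$roi_scores, 3)
  expect_identical(sc$total, sum(sc$roi_scores))
  # horizontally uniform ridges: every ROI scores the same
  expect_equal(max(sc$roi_scores) - min(sc$roi_scores), 0, tolerance = 1e-9)
  # each ROI reproduced by a direct single-ROI call
  for (k in 1:3) {
    roi <- roi_spec(2 + (k - 1) * 4, 2, 4, 60)
    one <- bandpass_deviation(extract_profile(img, roi), pp)$roi_score
    expect_equal(sc$roi_scores[k], one, tolerance = 1e-12)
  }
  # flat image scores exactly zero
  flat <- render_image(make_flat_field(c(16, 64)))
  expect_identical(score_image(flat, c(2, 2), pp)$total, 0)
  # strip that does not fit names the required width
  expect_error(score_image(img, c(10, 2), pp), class = "cm_out_of_bounds")
  expect_error(score_image(img, c(2, 2), score_params(n_rois = 12)),
               "at least", class = "cm_out_of_bounds")
})

test_that("theta = 90 ridge images score at quantization level", {
  img <- ridge_image(0.06, orientation_deg = 90)
  expect_equal(score_image(img, c(2, 2), small_params())$total, 0)
})

test_that("oblating marks restores flat images and improves ridge scores", {
  pp <- small_params()
  flat <- render_image(make_flat_field(c(16, 64)))
  marked <- draw_marks(flat, 30, darkness = 0.7, thickness_mm = 2)
  expect_gt(score_image(marked, c(2, 2), pp)$total, 0)
  fixed <- oblate_marks(marked, 30, thickness_mm = 2)
  expect_identical(fixed$pixels, flat$pixels)
  expect_identical(score_image(fixed, c(2, 2), pp)$total, 0)
  # no marks: identity
  expect_identical(oblate_marks(flat, numeric(0))$pixels, flat$pixels)

  ridge <- ridge_image(0.06)
  clean <- score_image(ridge, c(2, 2), pp)$total
  rmark <- draw_marks(ridge, 30, darkness = 0.7, thickness_mm = 2)
  rfix <- oblate_marks(rmark, 30, thickness_mm = 2)
  s_mark <- score_image(rmark, c(2, 2), pp)$total
  s_fix <- score_image(rfix, c(2, 2), pp)$total
  expect_lt(abs(s_fix - clean), abs(s_mark - clean))

  # marks on the border cannot be interpolated
  expect_error(oblate_marks(draw_marks(flat, 1, thickness_mm = 2), 1,
                            thickness_mm = 2),
               class = "cm_cannot_interpolate")
})

test_that("strict 8-bit profile storage is available and close to default", {
  img <- ridge_image(0.06)
  tot_real <- score_image(img, c(2, 2), small_params())$total
  tot_q <- score_image(img, c(2, 2),
                       small_params(quantize_profile = TRUE))$total
  expect_gt(tot_q, 0)
  expect_lt(abs(tot_q - tot_real) / tot_real, 0.25)
})
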