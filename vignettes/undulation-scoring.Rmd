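---
title: "Quantifying cellulite from grazing-light photographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cellulite from grazing-light photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellumetry)
```

## The measurement problem

Cellulite presents as undulations of the thigh skin at roughly the 2-20 mm
scale. When a thigh is photographed under a near-grazing beam mounted below
the participant (elevation about 70 degrees from the body's vertical axis,
beam dispersion about 15 degrees), those undulations modulate the local
surface slope along the vertical axis and hence the reflected intensity:
ridges facing the light brighten, ridges facing away darken. Features that
vary only horizontally leave the vertical slope unchanged and are invisible
under this geometry, which is why only horizontal and diagonal ridges
contribute to the measurement.

`cellumetry` implements the image score built on this physics, plus
everything needed to exercise it end to end without the original
photographs: a ground-truth surface renderer, a contralateral-trial
simulator, and the trial's statistics stage.

## The undulation score

For a region of interest (ROI) of 4 x 60 mm (width x height), the pixel
rows are averaged across the ROI width into a single vertical intensity
profile (`extract_profile`). Two centred moving averages are then taken
(`moving_average`, window shifting one sample at a time):

* a **small window** (default 1 mm) producing `px1`, which removes sub-mm
  sensor noise and micro-texture;
* a **large window** (default 20 mm) applied to `px1`, producing the
  illumination baseline `px2`, which absorbs everything at or above the
  scale of the lighting gradient.

The ROI score is the summed absolute deviation of `px1 - px2` over the
interval where the large window fits entirely; `score_image` repeats this
for 12 adjacent non-overlapping ROIs (a 48 x 60 mm strip) and sums the 12
results into the overall score. A uniform image scores exactly 0, and so
does a perfectly linear illumination ramp, because the symmetric
shrinking-edge moving average reproduces straight lines exactly and the
summation is restricted to the fully-valid interval. Visibly cellulitic
texture, by contrast, produces scores in the hundreds to thousands.

Design choices worth knowing about:

* **Windows are physical, not pixel counts.** The two scales are specified
  in mm and converted through the image calibration (`px_per_mm`, default
  10, at which the small window is 11 px and the large 201 px). The
  conversion rounds to the nearest odd integer (ties upward) so the centred
  window introduces no half-pixel phase shift. A pixel-denominated override
  (`large_window_px`) exists for sensitivity analyses.
* **Profiles keep real precision.** Averaging ~40 columns produces sub-grey
  -level information that strict 8-bit storage would destroy;
  re-quantization is available as `quantize_profile = TRUE` for sensitivity
  checks and changes scores only modestly.
* **Absolute deviations by default.** Signed deviations of a bandpassed
  signal cancel to near zero; squared deviations are offered as a variant.
  Under absolute deviation the score is exactly invariant to intensity
  offsets and scales linearly with intensity contrast.
* **No normalization.** Raw deviation sums are reported; nothing rescales
  them toward any particular range.

### What the bandpass actually passes

A boxcar moving average is the field's "simple algorithm", not an ideal
filter. Its attenuation of a sinusoid of wavelength $\lambda$ by a window
of length $w$ follows the Dirichlet/sinc ratio, so the default
configuration passes a 10 mm undulation at about 98% while leaking about
9-10% of an 80 mm illumination-scale trend and up to ~10% of 0.4 mm
texture (the exact figure at 0.4 mm depends on the sampling phase at
4 px/period). Suppression outside the 2-20 mm band is therefore strong but
not better than ~90%: that is a mathematical property of the 20 mm boxcar
(its leak at 80 mm is $1-\mathrm{sinc}(\pi/4) \approx 10\%$ in the
continuum limit), and the package's tests assert the achieved attenuation
rather than an idealized one.

### Circumference marks

Trials of this kind draw indelible lines on the skin to position the
measuring tape; these dark bands would dominate a deviation score.
`draw_marks` emulates them and `oblate_marks` removes them by per-column
linear interpolation between the nearest unmarked rows. Interpolation
restores constant backgrounds exactly and brings ridge-image scores close
to their unmarked values; bands touching the frame border cannot be
interpolated and raise an error.

## The synthetic skin model

`surface_field` objects are height maps (mm) on a square grid (default
0.1 mm, matching the default pixel pitch). Three generators cover the
cases the scorer must distinguish: `make_flat_field` (featureless skin),
`make_undulation_field` (plane-wave ridges of controlled amplitude,
wavelength and orientation) and `make_dimple_field` (seeded random
Gaussian depressions as an orange-peel surrogate).

`render_image` shades a field with a Lambertian model: surface normals
come from central finite differences (one-sided at borders), the light
direction lies in the vertical plane at `elevation_deg` from vertical and
tilts linearly across the frame height by `dispersion_deg` to mimic beam
divergence, and an `ambient_fraction` (default 0.2) adds
shading-independent light. Intensities are normalized by the flat-surface
response so a flat field renders at exactly `base_level` (default 180)
before noise, then Gaussian sensor noise is added and the result is
quantized with a fixed round-half-away-from-zero rule, making renders
bit-reproducible for a given seed.

What this emulates — and what it does not. The renderer reproduces the
features the scorer depends on: slope-driven contrast, its orientation
selectivity, illumination gradients across the frame, sensor noise, and
drawn marks. It does not model specular reflection, subsurface scattering,
colour, lens distortion or auto-exposure. Passing tests on these renders
demonstrates that the scorer measures what it claims to measure on
surfaces of known geometry; they say nothing about segmentation of real
thighs or about photograph-to-photograph registration, which real use
must still handle. The physical field of view of the original study's
photographs is unknown, so `px_per_mm` is an explicit calibration input
(default 10 px/mm, at which the small window's "about ten pixels"
corresponds to the sub-mm cutoff).

## The simulated trial

`trial_config`/`simulate_trial` generate the contralateral design: 20
women enrolled, the treated side randomized in blocks of four, visits at
weeks 0/2/4/8/12/14, and one withdrawal at each of weeks 7 and 8 leaving
18 completers (withdrawn participants keep their records up to the
withdrawal week; analyses use `completers()`).

Each outcome is `trajectory(thigh, week) + participant effect +
residual`, with the participant effect shared by both thighs across all
weeks — this is what makes the two thighs of one person correlated, the
property the contralateral design exploits. Default trajectories are
anchored at the published values (herbal-thigh Cellulite Severity Scale
13.4 at baseline, 12.1 at week 2, 9.9 at week 12; baseline circumferences
47.1/47.6 and 55.4/55.6 cm; and so on), with unpublished intermediate
weeks filled by linear interpolation and a partial rebound after
treatment stops at week 14. CSS noise defaults (participant SD 1.0,
residual SD 0.8) give a between-subject SD of about 1.28, i.e. a standard
error near 0.3 at n = 18, matching the published baseline dispersion; a
time-constant noise model cannot simultaneously match the larger week-12
standard error, and the baseline was preferred. Published summaries of
the 13.4 baseline carry both a +/-0.3 and a +/-0.8 dispersion; these are
read as SEM and SD flavours of the same cohort, and the simulator's
defaults are compatible with both readings.

`simulate_grades` derives 0-3 evaluator grades from the latent severity
(`clamp(round(css / 5 + bias + noise), 0, 3)` per evaluator), and
`simulate_likert` draws paired 1-5 questionnaire responses. All
simulators are deterministic given a seed and export to plain CSV byte
-reproducibly.

## The statistics stage

* `rm_anova` computes the within-subject two-way decomposition (treatment
  x week, subject as the repeated block) from first-principles sums of
  squares, testing each effect against its interaction-with-subject mean
  square. It refuses unbalanced input rather than guessing; the published
  analysis population (completers) is balanced by construction. A one-way
  per-arm variant is provided because the original description does not
  pin down which model was fitted; the two-way model is the default.
* `baseline_contrasts` performs paired comparisons of each post-baseline
  week against week 0, on percent-of-baseline values by default (the
  trial normalized to baseline before testing; raw differences are
  selectable), Bonferroni-corrected over the five post-baseline weeks.
* `wilcoxon_signed_rank` drops zero differences, midranks ties, and uses
  exact enumeration of all sign assignments for up to 12 non-zero pairs
  (valid under ties), otherwise a normal approximation with tie-corrected
  variance and continuity correction. The degenerate all-zero case
  reports p = 1 with a flag: published tables show p = 0.500 for
  identical paired columns, which no standard convention yields, and the
  package documents rather than imitates that value.
* `summarize_trial` and `tabulate_comments` reproduce the summary-table
  arithmetic (mean/SD/SEM; diary comment counts as integer percentages of
  the 18 completers).

## Numerical and testing choices

Problem sizes were chosen so the whole test suite runs in well under a
minute: renders cover the 52 x 64 mm frame that holds the 12-ROI strip
(520 x 640 px at the default calibration) rather than a full 4000 x 3000
sensor, profile-level properties use 600-sample profiles, oracle
comparisons use brute-force reimplementations at tolerance 1e-9, the
week-12 power check uses 200 simulated trials and the type-I-error check
1000. Degenerate inputs fail loudly: images narrower than the ROI strip
report the required width, ROIs outside the raster, non-odd windows,
profiles shorter than the baseline window, and unbalanced ANOVA input all
raise classed errors.

## A worked example

```{r, eval = FALSE}
field <- make_undulation_field(amplitude_mm = 0.06, wavelength_mm = 10,
                               orientation_deg = 0, extent_mm = c(52, 64))
img <- render_image(field, noise_sd = 0)
score_image(img, region_origin_mm = c(2, 2), params = score_params())

ds <- completers(simulate_trial(trial_config(), seed = 42))
summarize_trial(ds, "css")
rm_anova(ds, "css")
baseline_contrasts(ds, "css", arm = "herbal")
```

## Known limitations

* The mapping from raw deviation sums to any particular clinical range is
  not normalized; scores are comparable within a calibration and scoring
  configuration, not across them.
* The renderer's linear-tilt dispersion model is a first-order stand-in
  for a divergent beam, adequate for testing orientation selectivity but
  not radiometrically exact.
* The simulator's trajectories are descriptive inputs, not a
  pharmacological model; week-4/8/14 defaults are interpolations.
* Out-of-band suppression is bounded near 90% by the boxcar smoother, as
  discussed above.
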