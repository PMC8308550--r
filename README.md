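# cellumetry

Photographic cellulite quantification and contralateral-trial analysis.

Cellulite — the dimpled, "orange-peel" texture of skin over subcutaneous
fat on the thighs of post-pubescent women — is usually graded by eye. An
objective alternative photographs the thigh under a near-grazing light
beam from below, so that skin undulations at the 2–20 mm scale modulate
surface slope and hence image intensity, and then scores the texture from
the photograph. `cellumetry` implements that score, the synthetic imagery
needed to validate it, and the statistics of the split-body (contralateral
thigh) trials in which it is used: topical treatment on one thigh, placebo
on the other, so each participant is her own control.

## The score

For a 4 × 60 mm region of interest, pixel rows are averaged across the
width into one vertical profile $P(y)$. Two centred moving averages at
physical scales give

$$\mathrm{px}_1 = \mathrm{MA}_{1\,\mathrm{mm}}(P), \qquad
  \mathrm{px}_2 = \mathrm{MA}_{20\,\mathrm{mm}}(\mathrm{px}_1),$$

and the ROI score is $\sum_y |\mathrm{px}_1(y) - \mathrm{px}_2(y)|$ over
the interval where the 20 mm window fits entirely. The small window
removes sub-millimetre noise; the large one estimates the illumination
baseline. Twelve adjacent ROIs (a 48 × 60 mm strip) are scored and summed
into the overall value. Smooth featureless skin — and any purely linear
illumination gradient — scores exactly 0; visibly cellulitic skin scores
in the hundreds to thousands. Because the light rakes upward, only
horizontal/diagonal ridges register; vertical ridges are invisible, and
the package's renderer and tests verify both behaviours.

Around the scorer the package provides ground-truth surface fields and a
Lambertian grazing-light renderer (`make_undulation_field`,
`make_dimple_field`, `render_image`, `draw_marks`/`oblate_marks` for the
drawn circumference lines), severity grading utilities
(`aggregate_grades`, `classify_css`, `normalize_to_baseline`), a seeded
trial simulator (`trial_config`, `simulate_trial`, `simulate_grades`,
`simulate_likert`), and the analysis stage (`rm_anova`,
`baseline_contrasts`, `wilcoxon_signed_rank`, `summarize_trial`,
`tabulate_comments`). See the vignette
`vignettes/undulation-scoring.Rmd` for the model and design notes.

## Worked example

```r
library(cellumetry)

# a 10 mm-wavelength horizontal ridge field, rendered noise-free
field <- make_undulation_field(amplitude_mm = 0.06, wavelength_mm = 10,
                               orientation_deg = 0, extent_mm = c(52, 64))
img <- render_image(field, noise_sd = 0)
img
#> <skin_image> 520 x 640 px @ 10 px/mm (52.0 x 64.0 mm)
#>   intensity: [177, 183]

score_image(img, region_origin_mm = c(2, 2), params = score_params())
#> <undulation_score> total = 5876 over 12 ROIs
#>   per ROI: 490 490 490 490 490 490 490 490 490 490 490 490
```

A 0.06 mm-amplitude undulation modulates the render by only ±3 grey
levels, yet scores 5876 — well inside the visibly-cellulitic range —
while the same frame rendered flat scores exactly 0. All twelve ROI
scores agree because the ridges are horizontally uniform.

```r
# a simulated trial at the published design and trajectories
ds <- completers(simulate_trial(trial_config(), seed = 42))
subset(summarize_trial(ds, "css"), thigh == "herbal")
#>  outcome  thigh week  n mean   sd   sem
#>      css herbal    0 18 14.0 1.19 0.280
#>      css herbal    2 18 12.5 1.03 0.242
#>      css herbal   12 18 10.3 1.22 0.287
#>      css herbal   14 18 11.1 1.28 0.302

baseline_contrasts(ds, "css", arm = "herbal")
#>   week  n mean_diff      t df    p_raw    p_adj
#> 1    2 18     -10.9  -6.88 17 2.64e-06 1.32e-05
#> 4   12 18     -26.1 -13.66 17 1.35e-10 6.75e-10
#> 5   14 18     -21.1 -12.14 17 8.48e-10 4.24e-09
```

The herbal-thigh Cellulite Severity Scale falls from ~13.4 (severe) at
baseline to ~9.9 by week 12 and partly rebounds after treatment stops;
the paired contrasts report the mean percent-of-baseline change at each
week with Bonferroni-adjusted p-values over the five post-baseline
visits.

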