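Package: cellumetry
Title: Photographic Cellulite Quantification and Contralateral Trial Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cellulite severity from oblique-illumination skin
    photographs using a vertical line-scan bandpass score (two-scale moving
    average smoothing, baseline subtraction, summed absolute deviations over
    twelve adjacent regions of interest), and provides the surrounding
    clinical-trial toolchain: a synthetic skin-surface renderer with
    near-grazing Lambertian illumination for ground-truth testing, evaluator
    grade aggregation and Cellulite Severity Scale classification, a
    contralateral-thigh longitudinal trial simulator, and the trial statistics
    stage (repeated-measures ANOVA, Bonferroni-corrected baseline contrasts,
    exact Wilcoxon signed-rank for paired Likert data, summaries and diary
    comment tabulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
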