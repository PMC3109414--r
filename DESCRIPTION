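Package: csfchange
Title: Change-Point Analysis of CSF Biomarkers Against Cognitive Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and validates change-points in cross-sectional relations
    between cerebrospinal-fluid biomarkers (Abeta1-40, Abeta1-42, total Tau,
    phospho-Tau-181) and CAMCOG cognitive scores. Provides a synthetic-cohort
    generator with piecewise-linear heteroscedastic biomarker responses,
    from-scratch robust statistics (MM-estimation regression, robust lowess,
    Spearman's rho, Wilcoxon-Mann-Whitney, variance-ratio, chi-square and
    Fisher exact tests), structural-change F scans and single-breakpoint
    search for level change-points, a tie-splitting piecewise-linear
    segmentation resampler for slope change-points, an inflection MANOVA,
    and an orchestration layer producing summary tables and four-model
    overlay figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
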