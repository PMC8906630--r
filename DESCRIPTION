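Package: dermachroma
Title: Colorimetric Assessment of Radiation Dermatitis from Skin Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies acute radiation dermatitis (radiodermatitis) in
    whole-breast radiotherapy from close-up skin images. Converts 8-bit RGB
    images into twelve colour-space parameters (RGB, HSV, CIE L*a*b*, and
    BT.601 studio-swing YCbCr), reduces a circular region of interest to one
    representative parameter vector per image, summarises optically stimulated
    luminescent dosimeter (OSLD) skin-dose tables, and runs the longitudinal
    statistics used in this setting: two-way repeated-measures ANOVA with
    Mauchly's sphericity test and the Greenhouse-Geisser correction, paired
    Wilcoxon signed-rank tests under Bonferroni control, and Spearman
    dose-response correlations. A seeded synthetic erythema cohort generator
    provides dose-dependent test data so the full pipeline is verifiable
    without clinical images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
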