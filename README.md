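# dermachroma

Objective, colorimetric assessment of acute radiation dermatitis
(radiodermatitis) from close-up skin images in whole-breast radiotherapy.

Physician scales such as RTOG grade skin toxicity by eye, which is
subjective and insensitive to the mild (grade ≤ 1) reactions typical of
modern treatment. `dermachroma` instead reduces each skin image to twelve
colour-space parameters — R, G, B (0–255); H, S, V ([0,1]); CIE L\*, a\*,
b\*; BT.601 studio-swing Y, Cb, Cr (16–240) — by converting every pixel in
a circular region of interest (design radius 300 px) and averaging
(*convert-then-average*). Erythema shows up as rising a\*, R, S, V and Cr
and falling G, H and L\*. The package then runs the longitudinal study
statistics:

* two-way repeated-measures ANOVA (breast × time, both within-subject),
  with Mauchly's sphericity test and the Greenhouse–Geisser correction
  applied when sphericity is rejected;
* paired Wilcoxon signed-rank tests (irradiated vs control breast) at the
  Bonferroni-adjusted level 0.05/3 ≈ 0.0167;
* Spearman rank correlations of each parameter against the measured OSLD
  skin dose, and of early time points against the final severity.

A seeded synthetic erythema cohort generator (dose-dependent a\* shift,
near-flat control breast, pixel texture noise) makes the entire pipeline
testable without clinical images, and the published 20-patient OSLD
skin-dose table ships as a CSV fixture.

## Worked example

```r
library(dermachroma)

# a single pure-red pixel through all four colour models
pixel_to_vector12(c(255, 0, 0))
#>   R   G   B   H   S   V   Lstar  astar  bstar      Y     Cb  Cr
#> 255   0   0   0   1   1   53.24  80.09  67.20  81.48  90.20 240

# the packaged dose table and its printed summaries
tbl <- osld_dose_table()
cohort_min_mean(tbl)                    # 214.9  (lowest patient mean, cGy)
site_extremes(tbl)$min_counts[["inner"]]  # 14   (inner site is row minimum)
site_extremes(tbl)$max_upper_or_lower     # 17   (row maximum on upper/lower)

# simulate a 20-patient cohort and run the full analysis
res <- run_study(outdir = "results", simulate = TRUE, n_patients = 20, seed = 1)
subset(res$table5, time_point == "RT_after" & parameter %in% c("R", "astar"))
#>   parameter time_point   rho        p  n significant rho_shown
#>           R   RT_after 0.767  8.0e-05 20        TRUE     0.767
#>       astar   RT_after 0.920  9.2e-09 20        TRUE     0.920
```

The last block writes `table3.csv` (mean ± SD per parameter × breast ×
time), `table4.csv` (paired Wilcoxon p per parameter × time),
`anova.csv`, `table5.csv` (dose correlations, nonsignificant cells
masked) and `table6.csv` (early-vs-final correlations) into `results/`.
A thin command-line wrapper over the same functions is installed at
`inst/scripts/dermachroma.R` (`simulate`, `analyze`, `doses`).

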