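# glioshape

Morphometrics of the tumor–basal-ganglia boundary in WHO grade II–III
insular glioma, and the prognostic models built on it.

On axial FLAIR imaging, an insular glioma meets the basal ganglia along a
well-defined interface whose shape reflects the tumor's growth pattern:
slowly growing tumors spread along the deep gray matter and leave a smooth
*curved* boundary, while proliferative tumors compress it into a sharp
*linear* margin. `glioshape` is for imaging researchers and biostatisticians
who want to quantify that interface from a binary segmentation mask and
carry the resulting label through a full cohort analysis:

* **Boundary geometry** — marching-squares extraction of the medial
  boundary arc; box-counting fractal dimension
  `FD = slope of log N(ε) vs log(1/ε)` with efficient-cover counting and
  seeded replicate averaging; the classification rule *L if FD ≤ 1, C if
  FD > 1*; spline-based curvature descriptors (total `∫|κ|ds`, maximum,
  arc-length-weighted mean, RMS `dκ/ds`) and tortuosity `L/D`.
* **Cohort analysis** — inclusive marker-status thresholds (IDH1 30%,
  ATRX/TP53/MGMT 10%, 1p/19q 25%), 2×2 tables against the shape label,
  cross-product odds ratios with 95% Woolf intervals, chi-square tests,
  Spearman/VIF collinearity screening.
* **Survival models** — Kaplan–Meier, Mantel–Cox and Breslow–Wilcoxon
  log-rank tests, Cox regression (Efron ties) with stepwise Wald
  selection, the two published risk scores

  `Risk_L = 0.78·Ki67 + 0.54·epilepsy − 0.77·TP53 − 0.90·1p/19q + 0.55·volume`

  `Risk_C = 0.04·Ki67 − 0.86·IDH1 + 1.31·age + 1.39·volume + 1.19·tortuosity − 1.70·1p/19q`

  over binary "status" covariates, nomogram-style points scales with
  log-rank threshold search, and internal validation: bootstrap
  optimism-corrected Harrell C, event-stratified k-fold cross-validated C,
  and IPCW calibration (ICI/E50) at a horizon.
* **Synthetic data** — seeded generators for boundary shapes with
  closed-form descriptor values and for cohorts with the published
  covariate frequencies and proportional-hazards survival, so the whole
  pipeline is testable without any patient data.

Everything takes and returns tibbles; fitted objects have `tidy()` /
`glance()` methods and result types have `autoplot()` methods.

## Worked example

Measure a synthetic curved interface, then run the cohort side on a
simulated 330-patient cohort:

```r
library(glioshape)

shp    <- make_shape(shape_spec("sinusoid", amplitude = 8, wavelength = 64, size = 256))
report <- measure_boundary(shp$mask)
generics::tidy(report)
#> # A tibble: 6 × 3
#>   descriptor             value unit
#>   <chr>                  <dbl> <chr>
#> 1 fd                   1.06    unitless
#> 2 total_curvature     11.6     radians
#> 3 max_curvature        0.0654  1/mm
#> 4 average_curvature    0.0384  1/mm
#> 5 curvature_variation  0.00363 1/mm^2
#> 6 tortuosity           1.19    unitless
```

The FD of 1.0648 exceeds 1, so the boundary is classified curved (`C`) and
the five curvature descriptors are reported; a straight-edge mask gives
FD ≈ 0.98 → `L` with the curvature fields absent.

```r
cohort <- make_cohort(n = 330, exact_margins = TRUE, seed = 7)
assoc  <- associate_shape(cohort)
assoc[1:4, c("variable", "l1", "c1", "l2", "c2", "p", "or", "ci_low", "ci_high")]
#>   variable      l1    c1    l2    c2         p    or ci_low ci_high
#> 1 age           91    58    70   111 0.0000510 0.402  0.258   0.627
#> 2 volume        22    12   139   157 0.0499    2.07   0.988   4.34
#> 3 ki67_index    38    64    70    67 0.0335    0.568  0.337   0.959
#> 4 gender        85    92    76    77 0.765     0.936  0.607   1.44
```

With `exact_margins = TRUE` the generator reproduces the published
summary-table cells exactly, so the odds ratios above are the published
ones (age 0.40, volume 2.07, Ki-67 0.57, gender 0.94) with their Woolf
intervals. Internal validation of the Risk_L score on a generated cohort:

```r
coded <- dplyr::bind_cols(cohort[, c("pfs_months", "event")],
                          code_covariates(cohort, risk_model_L()))
# (use a complete-case cohort: make_cohort(330, seed = 7))
bootstrap_validate(coded, names(risk_model_L()$coefficients), B = 200, seed = 1)
#> <validation_report: apparent C 0.698, optimism 0.010, corrected C 0.688 (B = 200, 200 used)>
crossvalidate(coded, names(risk_model_L()$coefficients), k = 5, horizon = 36, seed = 1)
#> <cv_report: 5-fold, mean C 0.690, ICI 0.025, E50 0.014 at 36 months>
```

The corrected C of ≈0.69 is the discrimination the generating Risk_L
signal actually supports at n = 330; the small ICI/E50 confirm the fold
models are calibrated at the 36-month horizon. `run_pipeline()` composes
all stages (geometry → association → subgroup models → validation) with a
reproducibility manifest.

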