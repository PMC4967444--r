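# synovadce

Dynamic contrast-enhanced (DCE) MRI analysis of knee synovitis, built to
compare the *responsiveness* of static versus dynamic synovial measures
after an anti-inflammatory intervention.

In knee osteoarthritis the volume of enhancing synovium is a common
structural outcome, but it mixes acutely reactive vascular tissue with
chronic fibrosis. DCE-MRI — imaging the knee every 20–40 s after a
gadolinium bolus — captures the kinetics of synovial enhancement
directly. This package implements the full analysis chain for a
two-visit (before/after treatment) cohort:

* **Semi-quantitative curve metrics**, per voxel: the maximum relative
  enhancement rate `RER = max_i (S_{i+1}-S_i)/(Δt_i·S0)` (min⁻¹), the
  maximum relative enhancement `RE_max = max_i S_i/S0`, and the late
  relative enhancement `RE_late = (S_n+…+S_{n−3})/(4·S0)`, with `S0` the
  mean pre-contrast signal.
* **Pharmacokinetic modelling** with the extended Tofts model,
  `C_t(t) = v_p·C_p(t) + K^trans ∫₀ᵗ C_p(τ) e^{−(K^trans/v_e)(t−τ)} dτ`,
  fitted per voxel by bounded multi-start Levenberg–Marquardt against a
  population arterial input function.
* **ROI aggregation**: synovial tissue volume from a binary mask (mm³)
  and the median of each parameter over evaluable in-mask voxels.
* **Responsiveness statistics**: pooled two-visit z-scoring and a
  random-effects panel regression
  `y_it = X_it1·β + X_it2·β + W_i + U_it` whose parameter-by-visit
  interaction coefficients are the standardized change scores (with 95%
  CIs); plus bivariate regression and Pearson correlation (Fisher-z CI)
  of each parameter's change against the change in KOOS pain.
* **A synthetic cohort generator** (seeded, with known ground truth)
  producing 4D NIfTI dynamic series, ROI masks and clinical tables, so
  the whole pipeline is testable without patient data.

## Worked example

Standardized change scores for a 93-subject two-visit cohort whose
per-visit sample moments are pinned to the published cohort summaries
(`moment_mode = "exact"`):

```r
library(synovadce)

co <- simulate_cohort(93, seed = 2024, moment_mode = "exact")
sc <- standardized_change_panel(co$truth)
sc[, c("parameter", "oriented_estimate", "oriented_ci_low", "oriented_ci_high")]
#>    parameter oriented_estimate oriented_ci_low oriented_ci_high
#> 1 volume_mm3            -0.305          -0.538          -0.0714
#> 2        rer            -0.600          -0.833          -0.3670
#> 3    re_late            -0.575          -0.809          -0.3424
#> 4     re_max            -0.620          -0.853          -0.3865
#> 5         ve            -0.393          -0.626          -0.1600
#> 6     ktrans            -0.507          -0.740          -0.2739
#> 7  koos_pain            -1.126          -1.359          -0.8930
```

Each row is the change at follow-up in pooled-SD units (the visit
interaction coefficient of the panel model), oriented so that response
to treatment is negative; the enhancement measures RE_late (−0.58) and
RE_max (−0.62) are markedly more responsive than synovial volume
(−0.30), and the KOOS pain improvement is −1.13. Because exact-moment
mode pins the sufficient statistics, these estimates do not depend on
the seed.

Associations between imaging change and pain change, on a sampled
(non-exact) cohort with the generator's default treatment effect and
pain link:

```r
co2 <- simulate_cohort(200, seed = 2024)
association_table(co2$truth)[, c("parameter", "b", "p", "r")]
#>    parameter        b       p        r
#> 1 volume_mm3   -0.013 0.99335 -0.00059
#> 2        rer   -9.348 0.00900 -0.18427
#> 3    re_late  -16.210 0.00011 -0.27000
#> 4     re_max  -15.083 0.00028 -0.25431
#> 5         ve  -56.783 0.01389 -0.17372
#> 6     ktrans -175.564 0.07550 -0.12597
```

`b` is the KOOS-pain-change slope per unit parameter change (per cm³
for volume); negative values mean that a larger drop in enhancement
accompanies a larger pain improvement. The generator's pain link targets
the RE_late correlation (−0.27); the other parameters correlate through
their coupling with RE_late.

An end-to-end run (simulate NIfTI volumes → extract voxelwise maps and
ROI medians → statistics) is one call, or one shell command via the
bundled CLI:

```r
res <- run_full(default_config(seed = 1), "results_dir")
```

```sh
inst/cli/synovadce run --config cfg.json --out results_dir
```

## Package layout

* `R/protocols.R`, `R/aif.R` — acquisition protocols, arterial input
  functions (parametric bolus, population averaging, text I/O)
* `R/kinetics.R` — extended Tofts forward model and voxel fitting
* `R/curve_metrics.R` — RER / RE_max / RE_late and voxelwise maps
* `R/roi.R` — masks, synovial volume, ROI medians, cohort assembly
* `R/synthetic.R` — ground-truth cohort generator and NIfTI rendering
* `R/stats.R` — pooled z-scores, panel GLS, mean change, associations
* `R/pipeline.R` — config, simulate/extract/stats orchestration,
  run manifests
* `vignettes/synovadce-methods.Rmd` — models, assumptions, parameter
  choices and limitations
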