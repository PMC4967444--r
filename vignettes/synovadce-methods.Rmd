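---
title: "Quantifying synovitis response with DCE-MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synovitis response with DCE-MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synovadce)
```

## The problem

Synovitis — inflammation of the synovial membrane — is a treatment target
in knee osteoarthritis. Its MRI assessment can be *static* (the volume of
enhancing synovial tissue on a post-contrast scan) or *dynamic*: with
dynamic contrast-enhanced (DCE) MRI the knee is imaged repeatedly every
20–40 s after an intravenous gadolinium bolus, and the shape of each
voxel's signal–time curve reflects synovial vascularity and capillary
permeability. This package implements both families of measures and the
statistics used to ask which is more *responsive*: which changes more,
in standardized units, after an anti-inflammatory intervention
(intra-articular corticosteroid), and which change correlates better with
the change in pain (the KOOS pain subscale, 0 = extreme pain, 100 = no
pain).

Because patient images cannot be redistributed, the package includes a
first-class synthetic-cohort generator with known ground truth; every
stage of the pipeline is exercised against it.

## Acquisition model

Two dynamic protocols are built in (`dce_protocol()`):

* **standard** — 18 three-dimensional volumes at 22 s intervals; contrast
  is injected between frames 3 and 4, so frames 1–3 are pre-contrast;
* **ltr** (lower temporal resolution, used when a large knee requires a
  different coil) — 12 volumes at 39 s intervals, contrast between
  frames 2 and 3.

The pre-contrast baseline signal `S0` is the mean of all pre-contrast
frames (3 or 2); averaging reduces noise relative to taking a single
frame. Bolus arrival is fixed midway between the last pre-contrast and
first post-contrast frame, not estimated per voxel, matching the fixed
injection timing of the protocols.

## Semi-quantitative enhancement parameters

For a voxel signal curve \(S_i\), \(i = 0 \dots n\) (internally 0-based
frame indexing maps to the conventional \(S_0 \dots S_n\) labels), with
baseline \(S_0\):

* **RE_late** \(= (S_n + S_{n-1} + S_{n-2} + S_{n-3}) / (4 S_0)\): the
  late enhancement plateau, the average of the last four frames relative
  to baseline;
* **RE_max** \(= \max_i S_i / S_0\): the curve maximum relative to
  baseline;
* **RER** \(= \max_i (S_{i+1} - S_i) / (\Delta t_i S_0)\) in min⁻¹: the
  maximum slope of the relative enhancement curve, by consecutive-frame
  finite differences (a 3-point centered option exists via `window = 3`
  but is not the default).

Relative enhancement is implemented as the ratio \(S/S_0\) (not
\((S-S_0)/S_0\)); that convention is forced by the RE_late formula above
and gives a no-enhancement value of 1. RER is identical under either
convention. All three metrics are invariant to positive rescaling of the
signal. Absolute RER values depend strongly on the slope estimator and
temporal resolution; they should be compared only within one analysis
convention, and the package does not treat published absolute RER means
as reproducible.

## The extended Tofts model

Tissue concentration follows the two-compartment extended Tofts form

\[
C_t(t) = v_p C_p(t) + K^{trans} \int_0^t C_p(\tau)
  e^{-(K^{trans}/v_e)(t-\tau)} d\tau ,
\]

with \(K^{trans}\) (min⁻¹) the volume transfer coefficient, \(v_e\) the
fractional extravascular extracellular space, and \(v_p\) the fractional
plasma volume. `extended_tofts_forward()` evaluates the convolution on
the arterial input function's dense grid (1 s resolution by default)
with an exponentially weighted recursion that is algebraically identical
to the trapezoidal rule, so the quadrature error is \(O(\Delta t^2)\);
against a boxcar-AIF closed form it agrees to better than \(10^{-4}\)
at 0.1 s resolution.

**Signal-to-concentration conversion.** No T1 mapping is performed; the
pipeline assumes the linear signal model \(S = S_0 (1 + g\,C_t)\) with a
single configured gain \(g\) (default 5 signal units per mM) shared
between the generator and the fitting code. \(K^{trans}\) and \(v_e\)
are identifiable up to this gain convention; absolute values are
comparable only within it.

**Fitting.** `fit_extended_tofts()` converts the series to relative
enhancement, divides by the gain, and minimizes squared residuals with a
bounded Levenberg–Marquardt optimizer (tolerances `ftol = ptol = 1e-8`,
at most 200 iterations). Bounds are \(K^{trans} \in [0, 5]\) min⁻¹,
\(v_e \in [10^{-3}, 1]\), \(v_p \in [0, 0.5]\) — physiological range
with margin. Initialization is a fixed 3×3×2 grid over
(\(K^{trans}\), \(v_e\), \(v_p\)); the residual is scored at all 18
starts and the optimizer is polished from the best three, making the fit
deterministic. The three-parameter (extended) fit is the default; the
two-parameter fit (\(v_p = 0\)) is available via `fit_vp = FALSE`.
\(v_p\) is fitted but not propagated into the cohort table, whose
variable list carries only \(K^{trans}\) and \(v_e\). Unusable series
(all-zero, non-finite, non-positive baseline) return an error-flagged
result at the lower bound corner with `converged = FALSE`.

On noiseless synthetic curves under the standard protocol, round-trip
recovery of \(K^{trans}\) and \(v_e\) is accurate to well under 1%
relative error (the test suite checks a 200-voxel random sweep). The
12-frame, 39 s LTR protocol constrains the bolus passage much more
poorly; accuracy there, particularly for \(K^{trans}\), is expected to
degrade and is not asserted.

## Population AIF

The model input \(C_p(t)\) is a population arterial input function. With
real data it is the pointwise average of subjects' popliteal-artery
curves on a common grid (`average_population_aif()`, which refuses
mismatched grids rather than resampling silently). The synthetic
stand-in (`make_population_aif()`) is a parametric bolus — linear
upslope over 10 s to a peak of 6 mM, then biexponential washout (70% of
the peak decaying at 0.02 s⁻¹, 30% at 4×10⁻⁴ s⁻¹), zero before the
bolus delay. The shape and units of a measured AIF are
acquisition-specific; these parameters are documented conventions chosen
to exercise the fitting code, not reproductions of any measured curve.

## ROI aggregation

Masks live in dynamic-image space; registration between the
high-resolution segmentation and the dynamic series is taken as the
identity (segmentation itself is out of scope — synthetic masks stand in
for it). Synovial tissue volume is voxel count × voxel volume in mm³
(reported as cm³ only for the volume regression slope). Each parameter
is summarized per subject-visit as the **median** across evaluable
in-mask voxels; voxels with non-positive baseline signal are excluded
and counted. A visit with no evaluable voxel is flagged missing and the
subject drops from the complete-case cohort with a logged reason, as do
subjects missing a visit; duplicate subject-visit records are a hard
error.

## Responsiveness statistics

To compare change across parameters with different units, each
parameter is converted to a z-score using the mean and SD of the
**pooled** two-visit sample (186 observations for 93 subjects). The
pooled convention is deliberate: the per-parameter standardized change
then equals the raw mean change divided by the pooled-sample SD, and it
reproduces the published standardized scores from published per-visit
moments.

Standardized change is estimated by a random-effects linear panel
regression

\[ y_{it} = X_{it1}\beta + X_{it2}\beta + W_i + U_{it} \]

with parameter-type dummies \(X_{it1}\), type-by-visit interactions
\(X_{it2}\) (the standardized change scores), a subject random effect
\(W_i\), and error \(U_{it}\). The estimator is feasible GLS with
Swamy–Arora variance components and normal-theory confidence intervals
(`panel_re_fit()`, written in the package; an independent mixed-model
fit cross-checks it in the tests). Because the fixed-effect design is
saturated in the (parameter, visit) cells, the interaction coefficients
equal the mean within-subject z-differences *exactly*, for any variance
components — the package asserts this balanced-panel identity to
1e-10 — so the point estimates are estimator-invariant, while the panel
formulation supplies interval estimates that a plain standardized
response mean would not. Both a pooled fit (all seven parameters share
one subject random effect, the default) and a per-parameter fit are
provided; their point estimates are identical and their intervals differ
only through the variance components.

KOOS pain rises with improvement while every imaging parameter falls,
so the KOOS row is additionally reported with its sign flipped
(`oriented_estimate`, orientation `"improvement-negative"`), letting all
seven rows read "more negative = more responsive".

Associations are bivariate: OLS of KOOS change on each parameter's
change (unstandardized slope `b` with CI and two-sided p), plus the
Pearson correlation with a Fisher-z 95% CI. Complete cases only; no
multiplicity adjustment is applied, matching the descriptive use of
these models.

## The synthetic cohort

`simulate_cohort()` draws per-subject baseline truth — lognormal
\(K^{trans}\) (mean 0.045, SD 0.033 min⁻¹), \(v_e\) (0.31, 0.22;
clipped to [0.02, 0.95]), \(v_p\) (0.02, 0.01), synovial volume
(9601, 5251 mm³) and truncated-normal baseline KOOS (46.75, 14.40) — and
applies a multiplicative treatment effect at follow-up with
subject-level lognormal heterogeneity (SD 0.25), mean reductions
35.6% (\(K^{trans}\), \(v_p\)), 29.0% (\(v_e\)) and 15.4% (volume),
truncated so follow-up never exceeds baseline. About 16/93 of subjects
are assigned the LTR protocol. True enhancement metrics derive from the
noiseless forward model; the observed metrics add Gaussian signal noise
(default SD 2 on a baseline of 100) and voxel-level lognormal parameter
jitter when volumes are rendered. Every subject's draws come from a
child seed hashed from the master seed and the subject id, so enlarging
a cohort never perturbs existing subjects.

**Pain link.** The KOOS change is linear in the standardized true
RE_late change (target correlation −0.27) plus a negative loading on
the standardized baseline score (−0.42, which keeps the follow-up score
dispersion near its observed value of ~19) plus independent noise, with
mean +22.93 and SD 19.8. Recorded scores are truncated to the 0–100
instrument range; because truncation would otherwise attenuate the
realized correlation, the generator by default calibrates the latent
loading so the *recorded* scores achieve the target correlation
(`pain_link(calibrate = TRUE)`) — the same philosophy as exact-moment
mode below, applied to a correlation target. `calibrate = FALSE` gives
the plain latent-scale link.

**Exact-moment mode.** `simulate_cohort(moment_mode = "exact")`
affine-rescales each variable per visit so the sample means and SDs
equal configured targets (`reference_visit_moments()`) to machine
precision, preserving ranks and cross-correlations. This makes the
responsiveness statistics a deterministic function of published summary
moments, which is how the package reconstructs the published
standardized change scores at n = 93 without patient data. Exact-moment
cohorts are tabular: the rescaled values are no longer tied to the
forward model and may exceed instrument bounds, so they are meant for
the statistics stage only. One published score is *not* exactly
recoverable this way: the RER row's −0.61 rebuilds to −0.60 from the
rounded per-visit moments, and is therefore documented rather than
asserted.

**What the generator does not emulate.** Signal noise is Gaussian, not
Rician — at the simulated SNR and after ROI medians the difference is
negligible, but voxelwise low-SNR behaviour is not represented. There is
no anatomy, no motion, no coil inhomogeneity, no k-space model, no
synovial-fluid contamination of late frames, and registration is the
identity. Passing tests therefore validate the *analysis*, not the
acquisition: conclusions about real scanners (e.g., the exact size of
protocol differences) are outside what the synthetic cohort can show.

## Numerical choices and degenerate inputs

* AIF grid 1 s (0.1 s in oracle tests); convolution by exact trapezoidal
  recursion; frame sampling by linear interpolation on the dense grid.
* Optimizer tolerances 1e-8, 200 iterations, fixed multi-start → fits are
  bit-reproducible.
* Median with even counts: mean of the two central order statistics.
* Zero pooled variance, unbalanced panels, duplicate subject-visits,
  constant predictors, sub-minimal sample sizes: all hard errors naming
  the offending quantity. Missing files or unreadable images during
  extraction exclude the subject-visit into a report and the run
  continues.
* Variance components are floored at zero (Swamy–Arora can go negative);
  the GLS quasi-demeaning weight is capped just below 1 to keep the
  design full rank when the within-subject variance estimate collapses.

## Problem sizes

The test suite simulates cohorts of 2–500 subjects (5000 for the
correlation-calibration check), fits ~300 voxel curves in the recovery
sweeps, and uses 2000 replicate null cohorts of n = 93 for the CI
coverage check; the full suite runs in about a minute. The pipeline
defaults (n = 93, 16×16×6 grids at 4×4×6 mm voxels) reflect the emulated
study and run in tens of minutes; examples and tests use smaller ROIs.

## Reproducing the headline numbers

`scripts/acceptance.R` (see the README) regenerates the exact-moment
cohort at n = 93 and reports the standardized change scores for synovial
volume, RE_late, RE_max, \(v_e\), \(K^{trans}\) and KOOS pain; with the
pooled z-scoring convention these equal the published values to two
decimals regardless of the seed, because exact-moment mode pins the
sufficient statistics.
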