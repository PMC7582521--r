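---
title: "Models and methods behind clotquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clotquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotquant)
```

# Scope

`clotquant` implements the quantitative layer of plasma-clot biophysics
studies that compare patient groups (here, diabetes mellitus versus
control) on three experimental read-outs — nonlinear shear rheology of
clots formed in plasma, electron-microscopy morphometry of the fibrin
fiber network, and fluorescence-based fibrinolysis kinetics — and then
relate those read-outs to clinical covariates with fibrinogen-adjusted
regression. Because raw data from such cohorts are rarely shared, every
analysis stage is paired with a synthetic-data generator with known
ground truth, so the whole pipeline is validated by parameter recovery
rather than by reference outputs.

This vignette records the models, the defaults and why they were chosen,
the numerically delicate choices, and the measured limitations.

# Rheology

## Stress-ramp protocol and constitutive stand-in

The standard ramp applies logarithmically spaced stresses from 0.01 Pa to
10,000 Pa, 20 points per decade, dwelling 10 s per point
(`ramp_protocol()`). All grid arithmetic treats "one grid step" =
1/20 decade ≈ a factor 1.122 in stress.

Fibrin clots are linear (differential modulus K′ = K0) up to an onset
stress σ0, strain-stiffen beyond it, and rupture at σR with a sudden drop
of K′. Published curves constrain no functional form, so the generator
uses a piecewise power law in stress,

K′(σ) = K0 for σ ≤ σ0; K0 (σ/σ0)^m for σ0 < σ ≤ σR; f · K0 (σR/σ0)^m beyond,

with default exponent m = 1.5 (the stiffening scaling expected for
semiflexible biopolymer networks) and residual fraction f = 0.01, which
renders the "sudden drop" a detector must find. Strain is obtained by
exact closed-form integration of dγ = dσ/K′(σ), and measurement noise is
multiplicative log-normal on strain because a log-spaced ramp spans
strain decades. These forms are documented stand-ins: they have the
right qualitative anatomy (linear regime, first-order kink at onset,
power-law stiffening, catastrophic rupture), not a validated
constitutive law.

## Differential modulus

`differential_modulus()` computes K′ as the local least-squares slope of
σ on γ over a centered 3-point window in linear coordinates (one-sided at
the boundaries). Local regression was preferred to raw finite differences
because adjacent strain increments on a log grid are small (≈11% of the
running strain in the linear regime) and finite differences amplify noise
by roughly the inverse of that fraction. Windows containing repeated
strain values yield flagged `NA` points.

## Onset detection

The classical operational rule for the onset is "grow a least-squares
window from the lowest stresses and call the onset where R² of the linear
fit first drops below 0.8". That rule is implemented verbatim as
`detect_onset(..., method = "r2")`, and a brute-force prefix-window
oracle in the test suite confirms the implementation. It is not the
default, for a measurable reason: just past the onset the strain deviates
from linearity only to *second* order, and on a log-spaced grid the
window R² is dominated by the largest stresses, so on noiseless
model curves the rule overshoots the true onset by 16–28 grid steps
(a factor 6–25 in stress). No prefix-window R² statistic can localize a
second-order departure to one grid step.

The default detector therefore works on u = log(γ/σ), which is exactly
constant in the linear regime (Hooke's law through the origin) and
drifts downward to *first* order once stiffening begins. A one-sided
CUSUM changepoint statistic with noise-adaptive slack (1·σ̂) and
threshold (8·σ̂), where σ̂ is a median-absolute-deviation estimate from
successive differences of u, accumulates that drift; the onset is
reported at the last point before the accumulation became positive for
good. Measured performance: ≤1 grid step error on a noiseless
27-point lattice (K0 ∈ {10, 50, 200} Pa, m ∈ {1, 1.5, 2},
σ0 ∈ {0.5, 2, 10} Pa), median ≈1 step at 2% strain noise. The linear
modulus K0 is then the free-intercept OLS slope of σ on γ over the
detected linear branch (the intercept absorbs instrument offsets); with
no detectable onset the curve is flagged `no_onset` and K0 is the global
slope.

K0 from the stress ramp is deliberately kept separate from the
steady-state storage modulus G′ of the polymerization fit: the two
measure the same physics through different protocols and are reported
side by side, not merged.

## Rupture detection

Rupture is nominally "the first K′ below half its running maximum"
(`drop_fraction = 0.5`, configurable). Applied raw, that rule is
extremely fragile: at 5% strain noise the pointwise slope estimates have
≈50% coefficient of variation and the raw rule fires on essentially
every curve. `detect_rupture()` therefore:

1. excludes non-positive slope estimates (differentiation noise — a
   ruptured network still has a small *positive* modulus);
2. slides two 5-point median windows and triggers when the trailing
   median falls below `min(drop_fraction, exp(-4·σ̂_logK))` times the
   leading one, tightening the threshold when the K′ curve itself is
   noisy;
3. localizes the rupture index inside the trigger neighborhood with the
   literal raw rule, and reports σR, γR at the last intact point.

Measured: exact localization on noiseless curves; ≈2% false-positive
rate on Hookean null curves at 5% strain noise (no-rupture curves are
flagged, features censored at the ramp end).

## Kmax and the boundary bias

On a 20-point-per-decade grid K′ grows 19–26% per step in the stiffening
regime, so any one-sided linear end-slope underestimates K′ at the last
intact point by 8–20% — enough to matter for Kmax. `extract_features()`
first refines the rupture boundary with raw two-point interval slopes
(so no smoothing window straddles the rupture), then evaluates K′ at the
boundary with a power-law-consistent end estimator: the local exponent
follows from the ratio of the last two strain increments, which makes
the estimate exact for the generator's constitutive family. Because the
same estimator is noise-sensitive, it is only trusted within 3× of the
interior maximum; otherwise the interior maximum stands. Ties in the
argmax break toward lower stress. Feature orderings
(σ0 ≤ σ\_max ≤ σR, γ0 ≤ γ\_max ≤ γR, K0 ≤ Kmax) are checked on every
extraction and violations are flagged, never silently returned.

## Measured limitation: information-limited regimes

With multiplicative strain noise, per-step strain increments shrink as
stiffening saturates (Δγ/γ ∝ σ/(K′γ)). Once increments fall below the
noise floor, no pointwise slope estimator carries information, and
rupture localization degrades (the detector tends to censor early).
At 2% noise this happens when σR/σ0 exceeds roughly two decades with
m ≥ 1.5. The pipeline's generator defaults keep σR/σ0 ≈ 5
(Kmax/K0 ≈ 11, matching the ≈8–10 ratio seen in plasma-clot rheology),
where increments stay measurable. Noiseless recovery is exact at any
span.

## Polymerization fits

`fit_polymerization()` fits G(t) = G\_ss (1 − e^(−t/τ)) to the storage
and loss channels independently (Levenberg–Marquardt via `minpack.lm`),
reporting plateau moduli, per-channel τ and R². Non-convergence falls
back to the mean of the last decile of samples, flagged `fallback_*`;
records spanning fewer than 3 fitted time constants are flagged
`low_confidence`. Default simulated protocol: 3 h at 0.5 Hz.

# Image morphometry

Inputs are binarized micrographs with white = fiber. Preprocessing is a
difference-of-Gaussians bandpass (`bandpass_preprocess()`) that removes
intensity variations above 20 px and structures below 3 px; cutoffs map
to Gaussian σ = cutoff/2, and the smoother uses first-moment-corrected
(local-linear) border weights so constants and linear illumination ramps
are reproduced exactly at the edges. The output is re-centered on the
input mean and clipped to the input range — deliberately *not*
contrast-stretched, so suppressed features stay suppressed.
Segmentation (`binarize()`) is a global 256-bin Otsu threshold
(maximum between-class variance), brighter class = fiber, with an
`invert` flag for reversed-contrast inputs. This simple global threshold
stands in for more elaborate segmentation pipelines used with scanning
electron micrographs; it is validated at ≥99% pixel agreement against
rendered ground-truth masks under mild noise.

The five structural metrics:

* **Fiber diameter** — the foreground is thinned to an 8-connected
  one-pixel skeleton (Zhang–Suen), and at every skeleton pixel the
  diameter is 2·d − 1, where d is the Euclidean distance to the nearest
  background pixel (`EBImage::distmap`); the −1 makes a bar exactly
  w pixels wide read w. Averaging is over skeleton pixels (a per-pixel
  measure, not per-fiber), and the per-pixel sample is returned for
  diameter histograms. An all-foreground image is degenerate: flagged,
  with the diameter bounded by the smaller image dimension.
* **Porosity** — background fraction; `foreground_fraction` is defined
  as its exact complement so conservation holds identically.
* **Pores** — 4-connected background components that do not touch the
  image border ("enclosed by fibers"); border-touching components are
  open pore space and are not counted. Background connectivity 4 with
  foreground/skeleton connectivity 8 is the standard duality that avoids
  topological paradoxes. Count and mean area are reported.
* **Intersection density** — skeleton pixels with ≥3 skeleton neighbors
  are branch points; branch points within 5 px are merged (thinning
  renders one crossing as a small cluster), and the merged count is
  divided by image area (per µm² when a pixel size in nm/px is given).

The synthetic renderer draws straight constant-width segments with
hard-thresholded rasterization (foreground where the pixel-center
distance to the segment is < w/2), which makes odd widths exact in
pixels; generator defaults use odd widths only. Real micrographs differ
from these rasters in essentially every textural respect — curved
fibers, depth-of-field, charging artifacts — so recovery tests validate
the *measurement definitions*, not segmentation performance on real
images. Very thin co-occurring structures (tens of nm, such as
extracellular DNA fibers) are below the diameter histogram's influence
and are not simulated.

# Fibrinolysis

Release curves F(t) = F\_max (1 − e^(−kt)) are sampled every 15 min
(the manual sampling interval) with additive Gaussian noise, truncated
at zero. `extract_lysis_features()` reports the fluorescence released at
15 and 90 min and the lysis rate as the OLS slope of fluorescence on
time over 0–90 min. Samples are routinely 12-fold diluted before
reading, so corrected values multiply by the dilution factor; because it
is not always clear whether published release values are corrected, raw
and corrected values are both emitted. Off-grid read-out times are
linearly interpolated and flagged. No blank subtraction by default
(an optional `blank` argument exists).

# Cohort statistics

* `spearman_cor()` — midrank ties, Pearson-of-ranks, two-sided p from
  the t approximation on n − 2 degrees of freedom.
* `group_compare()` — Student's t (equal variances) when both groups
  pass a Shapiro–Wilk screen at α = 0.05, otherwise Mann–Whitney;
  the screen is a stated convention, since publications typically report
  the normal/non-normal split without the rule. Summaries mirror
  clinical-table formatting (mean ± SD or median [IQR]). The
  screen-then-test compound is measured slightly conservative
  (type-I ≈ 3.5–4% at n = 20/26), inside the 5% ± 2% calibration band.
* `adjusted_group_effect()` — OLS of outcome on group + fibrinogen
  (and group alone), B with t-based 95% CI and p. Mechanical parameters
  are modeled on the natural-log scale (log-normal-like distributions);
  natural log is a convention choice. Missing data: listwise deletion.
  Constant or collinear predictors raise an error naming the column.
* `timecourse_compare()` — per-timepoint two-group tests with Bonferroni
  over timepoints. This deliberately replaces repeated-measures ANOVA:
  the published per-timepoint comparisons are Bonferroni-adjusted
  anyway, and the per-timepoint formulation needs no sphericity
  machinery. Power is preserved for localized divergence (measured ≥90%
  detection of a 2.5 SD shift at a single timepoint, n = 10/group).
* `cohort_descriptives()` — n (%) with χ² for categoricals, mean ± SD or
  median [IQR] with the matching test for numerics.

The cohort generator draws fibrinogen N(3.8, 0.7²) g/L for 20 DM
subjects and N(3.3, 0.6²) for 26 controls, glucose and HbA1c log-normal
matched to the group medians and quartiles of such cohorts, and outcomes
from `outcome = intercept + β_DM·[DM] + β_fib·fibrinogen + ε`. The
default outcome emulates mean fiber diameter: β_DM = 6.70 nm (the
fibrinogen-adjusted group effect magnitude reported for fiber diameter),
β_fib = 3.5 nm per g/L (so the *unadjusted* group difference is ≈8.5 nm,
matching the reported unadjusted effect) and residual SD 8.7 nm (chosen
to reproduce the published CI half-width ≈5.2 nm at n = 46). Recovery is
the direct calibration check: over 500 simulated cohorts the mean
adjusted B̂ is within 5% of 6.70 and 95% CI coverage is ≈0.95.

# Pipeline

`run_pipeline()` simulates (or ingests) per-subject assays, extracts
features with the modules above, and emits: a per-subject feature table;
a Spearman table of features against fibrinogen/glucose/HbA1c; a
regression table with unadjusted and fibrinogen-adjusted B [95% CI], p
per feature (mechanical features log-transformed); per-subject
normalized curves K′/K0 vs σ/σ0; and a JSON provenance record (package
version, seed, full configuration). Subject-level simulation parameters
are tied to fibrinogen and group on the log scale with coefficients
chosen so the synthetic study reproduces the qualitative structure of
real cohorts (e.g. median G′ ≈ 50 vs 35 Pa between groups,
rs(G′, fibrinogen) ≈ 0.55). Replicate images per subject are averaged
before cohort statistics (the averaging level is a stated convention,
configurable via `n_images`). Everything derives deterministically from
`config$seed`; per-subject seeds are fixed offsets from it.

Default problem sizes (46 subjects, 121-point ramps, 96×96 px images,
13-point lysis curves, 3-h polymerization traces) run the full pipeline
in a few seconds on one core; recovery and calibration studies in the
test suite use 100–1000 replicates at the same sizes.

# Numerical conventions collected

* One grid step = 1/20 decade; recovery tolerances are stated in grid
  steps because the generator's σ0 values generally fall between grid
  points.
* The closed-form Kmax = K0(σR/σ0)^m is attained by a sampled curve only
  when σR lies on the stress grid; recovery fixtures therefore place σR
  on-grid (off-grid σR leaves the last sample up to one step, i.e. up to
  r^m ≈ 26%, below the closed form by construction).
* CUSUM noise floor `tol_min = 0.004` on log(γ/σ) prevents a zero
  threshold on noiseless input; all detector thresholds are relative,
  making every rheology feature exactly scale-equivariant in stress.
* Ties in argmax K′ → lowest stress. Degenerate inputs (constant images,
  all-foreground masks, zero-variance ranks, constant predictor columns)
  are flagged or raise errors naming the offending input, never silently
  absorbed.

# Known limitations

* The constitutive stand-in has a sharp onset kink; real clots bend
  smoothly, so sub-grid-step onset accuracy on real data should not be
  inferred from the recovery tests.
* Rupture localization under noise is information-limited in deeply
  saturated stiffening regimes (see above); σR and Kmax from noisy
  curves carry more spread than onset features.
* The image validation covers the metric definitions on rendered
  rasters, not segmentation of real electron micrographs.
* The per-timepoint lysis comparison ignores within-subject correlation
  across timepoints (it is a per-timepoint marginal analysis with a
  family-wise correction, as published figures report).
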