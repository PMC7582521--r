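# clotquant

Quantitative analysis of fibrin clot mechanics, structure and
fibrinolysis for plasma-clot cohort studies.

Blood clots formed from patient plasma differ in mechanics (how stiff
the fibrin network is and when it ruptures), in architecture (how thick
the fibers are and how porous the network is), and in how fast they are
enzymatically degraded. Studies comparing patient groups — for example
subjects with and without diabetes mellitus, in models where neutrophil
extracellular traps interpenetrate the clot — quantify all three with a
common recipe: nonlinear rheology of clots under a logarithmic stress
ramp, morphometry of electron micrographs of the fiber network, and
fluorescence-release lysis assays, followed by group comparisons
adjusted for fibrinogen concentration (the dominant confounder).
`clotquant` implements that recipe as a tested, reusable R package, for
researchers who want to run the same analysis on their own curves and
images — or to study its statistical behavior on simulated cohorts.

## What it computes

**Rheology** (`extract_features`, `fit_polymerization`): from a
stress-ramp curve (σ, γ) the differential modulus K′ = dσ/dγ and the
standard nonlinear parameter set —

* K₀, the linear modulus; (σ₀, γ₀), the strain-stiffening onset, located
  by a CUSUM changepoint on log(γ/σ) (the classical expanding-window
  "R² < 0.8" rule is available as `method = "r2"`);
* K\_max with (σ\_max, γ\_max), the peak differential modulus before
  rupture, boundary-corrected for the log-spaced grid;
* (σ_R, γ_R), the rupture point, from a noise-robust sudden-drop
  detector; plus K′/K₀ vs σ/σ₀ master-curve normalization and
  exponential plateau fits G(t) = G_ss(1 − e^(−t/τ)) for polymerization
  traces.

**Image morphometry** (`measure_image`): from a binarized fiber-network
image, mean fiber diameter (2·EDT − 1 along the skeleton), porosity,
enclosed-pore count and mean area, and intersection density (merged
skeleton branch points per area), with difference-of-Gaussian bandpass
and Otsu segmentation for grayscale input.

**Fibrinolysis** (`extract_lysis_features`): dilution-corrected release
at 15 and 90 min and the lysis rate (OLS slope over 0–90 min).

**Cohort statistics** (`spearman_cor`, `group_compare`,
`adjusted_group_effect`, `timecourse_compare`, `cohort_descriptives`):
Spearman correlations with midrank ties, t/Mann-Whitney comparisons with
a normality screen, fibrinogen-adjusted regression
`outcome ~ group + fibrinogen` reporting B [95% CI], per-timepoint lysis
comparisons with Bonferroni correction, and characteristics tables.

**Synthetic data** (`simulate_stress_ramp`, `simulate_polymerization`,
`simulate_lysis`, `render_fiber_network`, `simulate_cohort`): generators
for every input with known ground truth, calibrated to published
protocol and cohort values (0.01–10,000 Pa at 20 points/decade,
15-min lysis sampling, 12-fold dilution, fibrinogen 3.8 ± 0.7 vs
3.3 ± 0.6 g/L at n = 20/26, an injectable group effect of 6.70 on fiber
diameter).

**Pipeline** (`run_pipeline`): simulate or ingest per-subject assays,
extract features, and emit the three standard cohort outputs (feature
table, correlation table, adjusted-regression table) plus normalized
curves and a JSON provenance record, deterministically from one seed.
A thin command-line wrapper lives at `inst/cli/clotquant.R`.

## Worked example

Recover the mechanical parameter set from a noiseless simulated ramp:

```r
library(clotquant)
tr <- nonlinear_truth(K0 = 50, sigma0 = 2, m = 1.5, sigmaR = 501.19)
curve <- simulate_stress_ramp(tr)
extract_features(curve)
#> <nonlinear_features>
#>   K0      = 50 Pa   sigma0 = 1.995 Pa   gamma0 = 0.03991
#>   Kmax    = 1.983e+05 Pa   sigma_max = 501.2 Pa   gamma_max = 0.1149
#>   sigmaR  = 501.2 Pa   gammaR = 0.1149
```

The onset is recovered at 1.995 Pa — the nearest grid point below the
true 2 Pa (stresses are sampled 20 points per decade, so features are
resolved to one grid step, a factor 1.122) — the rupture stress exactly,
and K\_max matches the closed form K₀(σ_R/σ₀)^1.5 = 1.98 × 10⁵ Pa.

Run a full synthetic cohort study:

```r
res <- run_pipeline(list(seed = 1))
res
#> <clot_pipeline_result> 46 subjects (seed 1)
#>   features: 46 x 22; regression rows: 17
subset(res$regression, feature %in% c("Gp_ss", "fiber_diameter", "lysis_rate"),
       select = c(feature, log_transformed, B_adj, ci_lo_adj, ci_hi_adj, p_adj))
#>           feature log_transformed       B_adj    ci_lo_adj    ci_hi_adj        p_adj
#> 1           Gp_ss            TRUE   -0.131294   -0.4055585    0.1429704 3.397342e-01
#> 11 fiber_diameter           FALSE   -6.183459  -16.9085842    4.5416663 2.513624e-01
#> 16     lysis_rate           FALSE -242.014310 -316.8761205 -167.1524991 6.410843e-08
```

Each row is the fibrinogen-adjusted group effect (DM − control) on one
extracted clot feature with its 95% confidence interval: in this
simulated cohort the clot stiffness G′ shows no group effect at fixed
fibrinogen (B on the log scale, CI spanning 0), while the lysis rate is
markedly lower in the DM group — the qualitative pattern such studies
report. A single-cohort fiber-diameter estimate is noisy by design
(residual SD 8.7 nm at n = 46); averaged over 500 simulated cohorts the
adjusted B̂ recovers the injected 6.70 nm within 5% (that calibration is
part of the acceptance checks below).

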