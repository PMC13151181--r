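---
title: "Methods: intrinsic timescale mapping and voxel-wise group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic timescale mapping and voxel-wise group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(intmap)
```

## What the package computes

`intmap` implements the analysis chain of a two-group pediatric
resting-state fMRI / voxel-based-morphometry study: per-voxel intrinsic
neural timescale (INT) maps from BOLD runs, voxel-wise two-sample
general linear models with Gaussian random-field (GRF) cluster
correction on both the INT and modulated gray-matter-volume (GMV)
modalities, cohort-level tabular statistics, and a Spearman
structure–cognition screen. A synthetic-cohort generator with known
AR(1) ground truth makes every stage testable without access to any
scanner data.

## The timescale statistic

For a preprocessed voxel time series the biased sample autocorrelation
function (ACF) is

$$\hat\rho_k \;=\; \frac{\sum_{t=1}^{T-k}(x_t-\bar x)(x_{t+k}-\bar x)}
{\sum_{t=1}^{T}(x_t-\bar x)^2},$$

and the intrinsic timescale is the *positive area* under the ACF: the
sum of coefficients from the starting lag up to, but not including, the
first lag at which the ACF becomes non-positive, multiplied by the
repetition time (TR) to give seconds. Two conventions exist for the
starting lag; `include_lag0 = TRUE` (the default) starts at lag 0,
where the ACF equals 1, so white noise maps to INT ≈ TR rather than
≈ 0. Because lag 0 contributes the constant TR at every voxel, group
*contrasts* are unaffected by the choice; the flag exists because the
convention differs between published implementations. The ACF is
computed by direct summation with early exit at the first non-positive
lag, which makes the implementation exactly comparable with a
brute-force double-loop oracle.

For an AR(1) process $x_t = \varphi x_{t-1} + \varepsilon_t$ the
population ACF is $\varphi^k$, so the population positive area is the
geometric sum and

$$\mathrm{INT}_\infty \;=\; \mathrm{TR}\,
\Bigl(1 + \frac{\varphi}{1-\varphi}\Bigr),$$

which is the closed-form ground truth the synthetic generator is built
around.

**Finite-run bias.** The stopping rule makes the estimator biased in a
T-dependent way: short runs (T ≈ 100) truncate the positive run of the
noisy ACF and *shorten* the estimate; at intermediate runs the random
positive excursions of the near-zero ACF tail *lengthen* it slightly
(the walk keeps adding small positive noise values until one dips below
zero); the error decays slowly with T and is below 5 % of the closed
form at T = 10⁴ over φ ∈ [0.1, 0.8]. The tests assert
this actual shape rather than a monotone decay.

## Temporal preprocessing

The chain runs in a fixed order — volume dropping, linear detrending,
ideal band-pass filtering, nuisance regression, despiking/scrubbing —
and is deterministic.

* **Volume dropping** removes the first 10 volumes (signal
  equilibrium); configurable.
* **Detrending** is exact OLS on an intercept + ramp.
* **Band-pass** (default 0.01–0.08 Hz) is an ideal rectangular filter
  in the DFT domain: bins inside the band are kept, all others zeroed.
  It is a projection (idempotent) and removes the DC component whenever
  the low edge is positive.
* **Nuisance regression** removes an intercept plus up to 27
  regressors: the Friston-24 motion expansion (parameters, their one-
  volume lags, and both squared) and global / white-matter / CSF mean
  signals. Regressors are band-pass filtered with the same filter
  first, so regression cannot reintroduce out-of-band energy. Collinear
  columns are dropped with a warning — on short runs this is expected,
  because band-limited signals span only as many dimensions as there
  are retained DFT bins. A run is only analyzable when the band retains
  more real dimensions (twice the bin count) than nuisance regressors;
  below that the regression removes the data entirely. At the study's
  acquisition (190 retained volumes, TR 2 s) the band spans 54
  dimensions against 28 regressors.
* **Despiking** flags frames with framewise displacement above 0.5 mm
  and amplitude outliers more than 5 robust SDs (1.4826 × MAD) from an
  11-point running median, then replaces flagged frames with a natural
  cubic spline through unflagged points (clamped to the nearest
  unflagged value at the run edges). The upstream study names a
  despiking tool but no thresholds; these defaults are configurable
  (`fd_threshold_mm`, `c_mad`, `window`) and the detector is a
  Hampel-style filter with the same contract (outliers replaced by
  smooth interpolation).

Framewise displacement uses Power's formulation: the sum of absolute
backward differences of the six realignment parameters with rotations
converted to arc length on a 50 mm sphere; the first retained volume
gets FD = 0. The head-motion exclusion rule is strict: a subject is
dropped only when translation exceeds 2.5 mm or rotation exceeds 2.5°.

After the timescale map is computed it is smoothed with a 6 mm FWHM
mask-aware Gaussian kernel (`smooth(map·mask)/smooth(mask)`, which
preserves constants and keeps out-of-mask values from bleeding in) and
then z-transformed — smoothing strictly before standardization. The
phrase "standardized within groups" is ambiguous between per-subject
spatial z-scoring and per-voxel z-scoring across subjects within each
group; the default is per-subject (`zscore_map()`), with the group-wise
variant available as `zscore_maps_groupwise()`. Per-subject scoring was
chosen because it keeps each subject's map self-normalized (robust to
global scale differences) and leaves the between-group contrast
interpretable voxel by voxel.

## Voxel-wise inference

`voxel_glm()` fits the same OLS model at every in-mask voxel; the group
effect is the t statistic of the group indicator with covariates age,
education years, corticosteroid months (coded 0 for controls, where the
quantity is undefined), mean framewise displacement, and total
intracranial volume. TIV is always a covariate for the GMV model; for
the INT model it defaults to included (`include_tiv_int = TRUE`)
because the source lists a single covariate set for both analyses, and
can be switched off.

Cluster inference follows the standard GRF recipe. Residual smoothness
is estimated from the standardized residual maps: per axis,
$\lambda$ = the mean squared first difference of the unit-norm residual
vectors over in-mask neighbour pairs, and
$\mathrm{FWHM} = \sqrt{4\ln 2/\lambda}$ voxels; the search volume in
resels is the voxel count divided by the product of the per-axis FWHMs.
The corrected p for a cluster of k voxels above the Gaussianized
threshold u is

$$p = 1 - \exp\{-E[m]\,P(n \ge k)\},\qquad
P(n\ge k)=\exp\{-\beta k^{2/3}\},\qquad
\beta = \Bigl(\Gamma(\tfrac52)\,E[m]/E[N]\Bigr)^{2/3},$$

with $E[m] = R\,(4\ln 2)^{3/2}(2\pi)^{-2}(u^2-1)e^{-u^2/2}$ the
expected cluster count over $R$ resels and $E[N]$ the expected
suprathreshold voxel count. t maps are Gaussianized through the probit
of the voxel-level p (adequate at the residual df ≈ 59 used here). The
defaults mirror the study's printed thresholds: one-sided voxel
p < 0.001 per direction (the two directions are run separately, as the
published cluster table separates them), cluster p < 0.05, minimum
extent 22 voxels, 18-connectivity (faces + edges, the SPM convention;
6 and 26 are available). The extent filter and the corrected-p filter
both apply, since both thresholds are stated.

Because cluster-level GRF is known to be approximate at low smoothness
(the 6 mm kernel on a 3 mm grid is only 2 voxels FWHM), the package
carries its own calibration guard: `permutation_cluster_test()` builds
the max-cluster-extent null by permuting group labels (refitting all
covariates each time) and scores observed clusters as
$(1+\#\{\text{null} \ge k\})/(n_{\mathrm{perm}}+1)$. The test suite
checks both that the GRF family-wise rate on simulated null cohorts
stays near its nominal level and that GRF-significant clusters agree
with the permutation test on effect cohorts.

## Cohort statistics

* **Group comparisons** of demographic, cognitive and global volumetric
  measures use two-sample t-tests with a Levene gate replicating the
  SPSS reporting convention: pooled variance when Levene's test (on
  absolute deviations from group means) has p > 0.05, Welch otherwise.
  The published volumetric t statistics are reproducible from the
  printed summaries under exactly this convention (pooled for TIV, GM,
  WM; Welch for CSF), which is what `t_from_summary()` verifies.
  The printed t values for the five WISC-IV rows are *not* consistent
  with their printed means/SDs at n = 36/30 under either variant, so
  only the volumetric rows serve as numeric anchors.
* **Age trends**: per measure, OLS of value on group, age and
  group × age (control is the reference); the interaction p is
  two-tailed and Benjamini–Hochberg-adjusted over the four-measure
  family. A quadratic pre-step (age² and group × age²) is available
  behind `quadratic_screen`, but the default model is linear: the
  source kept the linear model after discarding non-significant
  quadratic terms, and retaining quadratics whenever any of 8 chance
  p-values dips below 0.05 would change the meaning of the interaction
  test more than half the time.
* **Structure–cognition screen**: average-rank Spearman correlations
  between significant-cluster means and the five WISC-IV indices within
  the patient group, p from the t approximation
  $t=\rho\sqrt{(n-2)/(1-\rho^2)}$, BH-FDR over the full
  cluster × index family per modality (the most conservative reading of
  "corrected using the FDR method"). Pairs are handled
  pairwise-complete; cells with fewer than 5 complete pairs or a
  constant margin report NA.

## The synthetic cohort

The generator emulates the study design: 36 patients vs 30 controls,
200-volume runs at TR 2 s on a 3 mm grid (default 30×36×30), GMV maps
on a 2 mm grid (default 45×54×45), ages uniform on 5–14 years.

* **BOLD**: each in-mask voxel is AR(1) with unit stationary variance
  ($\varepsilon\sim N(0,1-\varphi^2)$), so the true INT is available in
  closed form. Baselines: φ = 0.3 in the posterior ("sensory",
  y ≤ 0) stratum and 0.7 in the anterior ("association") stratum —
  reproducing the canonical short-sensory/long-association gradient —
  and φ = 0.65 inside two spherical effect regions (9 mm radius),
  where patients are shifted by − 0.2 to 0.45. A shared linear
  drift (amplitude 0.3, removed exactly by detrending) and a
  small-amplitude random-walk motion trace (well below the exclusion
  limits) are added; observation noise defaults to 0 so the analytic
  ground truth stays exact.
* **GMV**: baseline tissue fraction 0.5 plus fixed Gaussian anatomical
  bumps, a subject-specific noise field (white noise smoothed to 6 mm
  FWHM and rescaled to SD 0.04 using the kernel's exact variance
  factor, so the smoothness estimator has a known target), and for
  patients a uniform ±0.08 shift inside the effect spheres: two
  decrease regions and one increase region, mirroring the published
  dual profile. Values are clipped to [0, 1].
* **Tables**: global volumes follow group-specific linear age slopes
  (patients' TIV/GM/CSF fall with age while controls' rise; WM rises in
  both, more shallowly in patients) around Table-1-scale means with
  residual SDs of 20–40 ml. WMI is coupled to the region-A GMV mean and
  PRI to region B at 600 index points per unit tissue fraction with
  residual SD 8 — chosen once, by power analysis, so the population
  correlation is ≈ 0.7 and an FDR-corrected screen at n = 36 detects it
  with > 95 % power; FSIQ/VCI/PSI are uncoupled draws at
  Table-1-scale group means. Steroid months are positive for patients
  and 0 for controls.
* `null_config()` removes every planted effect (φ shift, GMV
  deltas, couplings, slope divergence) while keeping everything else,
  giving an exact negative control.

One master seed fans out to per-subject, per-modality child seeds by a
stable integer hash, so any single subject is regenerable in isolation.

**What the generator does not emulate**: hemodynamic response shape,
physiological noise, spatially correlated BOLD noise, registration
error, partial-volume structure in the GMV maps, or realistic atlas
geometry (the bundled atlas is an arbitrary octant parcellation).
Passing the recovery tests therefore demonstrates that the *machinery*
is correct and calibrated on its stated model, not that the published
effect sizes would be recovered from real scanner data.

## Problem sizes and numerical choices

The simulation tests and the acceptance script run the full pipeline on
a reduced grid (BOLD 16×18×16 at 3 mm, GMV 24×28×24 at 2 mm) with the
full group sizes, run length, effect sizes and thresholds; the physical
layout is identical because region centers are specified as fractions
of the brain's half-extent and radii in mm. Calibration experiments use
200 simulated null cohorts; recovery and agreement experiments use 10–20
master seeds; the permutation cross-check uses 199 permutations.

Other numerical conventions: voxel indices are 0-based against the
NIfTI affine (reported coordinates are mm); grids must agree bitwise in
shape and to 1e-4 mm in the affine; constant voxels inside the mask are
flagged NaN and excluded rather than erroring the whole run; smoothness
FWHM estimates are clamped below at half a voxel; cluster-network
assignment breaks ties toward the smallest atlas label and flags the
tie; the analysis mask is always an explicit input (the source does not
state one).

## Known limitations

* Cluster-level GRF at 2-voxel smoothness is conservative; the
  permutation route is the recommended check for borderline clusters.
* The published cluster p-values themselves cannot be reproduced
  because the raw data, estimated smoothness and search volume are not
  available; only the thresholds and machinery are.
* The Satterthwaite/Levene gating reproduces a reporting convention,
  not a recommendation; Welch throughout would be the modern default.
* No slice-timing, realignment estimation or spatial normalization:
  inputs are assumed registered to a common grid.
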