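# intmap

Voxel-wise **intrinsic neural timescale (INT)** mapping and two-group
neuroimaging inference in R.

In resting-state fMRI, the intrinsic timescale of a voxel measures how
long its spontaneous activity stays correlated with itself: the sum of
the initial run of strictly positive autocorrelation coefficients,
stopped at the first non-positive lag and multiplied by the repetition
time,

    INT = TR * (rho_0 + rho_1 + ... + rho_{k-1}),   rho_k <= 0 first.

Short timescales indicate fast, transient dynamics (primary sensory
cortex); long timescales indicate sustained integrative dynamics
(association cortex). For an AR(1) signal with coefficient phi the
population value is `TR * (1 + phi / (1 - phi))`, which is the closed
form the package's synthetic ground truth is built on.

Around that statistic the package implements the full analysis chain of
a case–control developmental study (e.g. children with Duchenne
muscular dystrophy vs healthy controls):

* temporal preprocessing of BOLD runs — volume dropping, linear
  detrending, ideal 0.01–0.08 Hz band-pass, Friston-24 + global/WM/CSF
  nuisance regression, Hampel-style despiking with spline replacement,
  Power's framewise displacement, and the 2.5 mm / 2.5° motion
  exclusion rule;
* INT maps with 6 mm mask-aware Gaussian smoothing and per-subject
  z-transform;
* voxel-wise two-sample GLMs with covariates (age, education, steroid
  months, mean FD, TIV) for INT and modulated gray-matter-volume (GMV)
  maps, residual-based smoothness estimation, Gaussian random-field
  cluster correction (voxel p < 0.001, cluster p < 0.05, ≥ 22 voxels,
  18-connectivity) and a permutation cross-check;
* cohort statistics: Levene-gated two-sample t-tests, group × age
  interaction models with BH-FDR, and an FDR-corrected Spearman screen
  of cluster means against WISC-IV indices;
* a synthetic-cohort generator (36 vs 30 subjects, 200 volumes at
  TR 2 s) with known regional AR(1) timescales, GMV group shifts of
  both signs, divergent volumetric age trends and planted
  structure–cognition couplings, plus its matched null.

## Worked example

Simulate a reduced-grid cohort with every planted effect, analyze it,
and print the cluster table:

```r
library(intmap)
cfg <- synth_config(bold_shape = c(16L, 18L, 16L),
                    gmv_shape = c(24L, 28L, 24L))
cohort <- simulate_cohort(cfg, seed = 7)      # ~20 s
analysis <- analyze_cohort(cohort)
print(analysis)
```

Output (seed 7):

```
cohort_analysis
-- timescale clusters --
cluster_set: 2 cluster(s) (voxel p < 0.001, cluster p < 0.05, >= 22 voxels, 18-connectivity)
 direction size_voxels peak_t peak_x_mm peak_y_mm peak_z_mm cluster_p network
    group<          50  -7.56      10.5      10.5      -1.5  5.36e-07    <NA>
    group<          44  -6.68     -10.5      -7.5       1.5  1.79e-06    <NA>
-- gray-matter clusters --
cluster_set: 3 cluster(s) (voxel p < 0.001, cluster p < 0.05, >= 22 voxels, 18-connectivity)
 direction size_voxels peak_t peak_x_mm peak_y_mm peak_z_mm cluster_p network
    group<         148  -7.60        15        11        -1  6.39e-07    <NA>
    group<         144  -7.40        -5       -11         1  8.35e-07    <NA>
    group>         137   6.38         1        -5        15  1.34e-06    <NA>
-- group x age interaction --
 measure interaction interaction_p        q
  tiv_ml       -5.23      1.60e-01 1.60e-01
   gm_ml      -15.78      6.56e-06 2.62e-05
   wm_ml       -4.76      1.05e-01 1.40e-01
  csf_ml       -6.16      7.52e-03 1.50e-02
-- int correlations with q < 0.05: 0
-- gmv correlations with q < 0.05: 2
```

Reading it: the two timescale clusters are the two planted
effect spheres (patients' AR coefficient 0.45 vs controls' 0.65 —
shorter timescales, hence `group<` with negative peak t at the sphere
centers ±(10, 9, 0) mm). The gray-matter table recovers both planted
decrease regions and the planted increase region. The two significant
gray-matter correlations are the planted WMI and PRI couplings
(rho ≈ 0.70, q ≈ 2e-5 in this cohort, visible via
`analysis$correlations$gmv`). This particular seed illustrates an
honest miss as well: the TIV interaction (true value −14 ml/yr) drew
−5.2 ± 4.3 and lands at p = 0.16, which is why the validation suite
scores recovery over ten seeds rather than one.

File-based use mirrors the in-memory path: `write_cohort()` emits a
cohort directory (NIfTI volumes, motion text files, covariate TSV), and
`run_pipeline(cohort_dir, out_dir)` preprocesses every subject, runs
both voxel-wise analyses and writes the report tables, cluster masks
and a manifest recording every threshold used. A thin CLI wrapper lives
at `inst/cli/intmap.R`.

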