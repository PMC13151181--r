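Package: intmap
Title: Intrinsic Neural Timescale Mapping and Voxel-Wise Group Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes voxel-wise intrinsic neural timescale (INT) maps from
    resting-state BOLD fMRI as the positive area under the temporal
    autocorrelation function scaled by the repetition time, together with
    the temporal preprocessing that precedes it (volume dropping, linear
    detrending, band-pass filtering, nuisance regression, despiking).
    Provides voxel-wise two-sample general linear models with covariates,
    residual-based smoothness estimation, Gaussian random-field cluster
    correction with a permutation cross-check, cluster extraction against
    an atlas, cohort-level statistics (Levene-gated two-sample t-tests,
    group-by-age interaction models with false-discovery-rate control,
    Spearman structure-cognition screens), and a synthetic-cohort
    generator with known AR(1) ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    car,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
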