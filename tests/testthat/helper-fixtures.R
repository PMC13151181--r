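# Shared fixtures. All data are generated in code at test time.

# Reduced-grid study configuration used by the heavier simulation tests:
# same physical layout, group sizes, effect sizes and acquisition
# parameters as the default configuration, on smaller grids so a cohort
# simulates in tens of seconds.
small_config <- function(...) {
  synth_config(bold_shape = c(16L, 18L, 16L), gmv_shape = c(24L, 28L, 24L),
               ...)
}

# Memoized effect/null cohorts + analyses so the acceptance blocks can
# share them. Master seeds are fixed a priori: 101.. for effect
# cohorts, 201.. for matched null cohorts.
.cohorts <- new.env(parent = emptyenv())

effect_case <- function(i) {
  key <- paste0("eff", i)
  if (is.null(.cohorts[[key]])) {
    cohort <- simulate_cohort(small_config(), seed = 100L + i)
    .cohorts[[key]] <- list(cohort = cohort,
                            analysis = analyze_cohort(cohort))
  }
  .cohorts[[key]]
}

null_case <- function(i) {
  key <- paste0("null", i)
  if (is.null(.cohorts[[key]])) {
    cohort <- simulate_cohort(null_config(small_config()), seed = 200L + i)
    .cohorts[[key]] <- list(cohort = cohort,
                            analysis = analyze_cohort(cohort))
  }
  .cohorts[[key]]
}

# Simple AR(1) series with unit stationary variance.
ar1_series <- function(T, phi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(T)
  x[1] <- rnorm(1)
  s <- sqrt(1 - phi^2)
  for (t in 2:T) x[t] <- phi * x[t - 1] + s * rnorm(1)
  x
}

# Wrap a T x V matrix of voxel time series into a bold_image whose mask
# covers every voxel.
bold_from_matrix <- function(Y, shape, tr = 2, voxel_mm = 3) {
  stopifnot(prod(shape) == ncol(Y))
  grid <- centered_grid(shape, voxel_mm)
  dat <- aperm(array(Y, dim = c(nrow(Y), shape)), c(2, 3, 4, 1))
  list(bold = bold_image(grid, dat, tr),
       mask = brain_mask(grid, array(TRUE, shape)))
}
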