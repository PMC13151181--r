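#' Biased sample autocorrelation function
#'
#' Demeans the series and computes the biased (divide-by-T) estimator
#' `rho[k] = sum_t (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`,
#' the standard signal-processing default. `rho[0] = 1` for any
#' non-constant input.
#'
#' @param series numeric vector, length >= 20, not constant.
#' @param max_lag largest lag computed (default `T - 2`).
#' @return An `acf_series`: list with `rho` (lags 0..max_lag) and
#'   `estimator = "biased"`.
#' @export
acf_biased <- function(series, max_lag = NULL) {
  x <- as.numeric(series)
  T <- length(x)
  if (T < 20L) stop("need at least 20 time points")
  if (is.null(max_lag)) max_lag <- T - 2L
  max_lag <- min(as.integer(max_lag), T - 1L)
  d <- x - mean(x)
  denom <- sum(d^2)
  if (denom <= 0) stop("constant series: ACF undefined")
  rho <- vapply(0:max_lag, function(k)
    sum(d[seq_len(T - k)] * d[seq.int(k + 1L, T)]) / denom, numeric(1))
  structure(list(rho = rho, estimator = "biased"), class = "acf_series")
}

#' Positive-area timescale from an ACF
#'
#' Walks the ACF from the starting lag, accumulating coefficients while
#' they remain strictly positive, and stops at the first lag with a
#' non-positive coefficient (which is not included, nor is anything
#' after it). The sum is multiplied by the repetition time to give a
#' timescale in seconds. With `include_lag0 = TRUE` the walk starts at
#' lag 0 (where rho = 1); otherwise at lag 1, and a non-positive rho[1]
#' yields 0 s.
#'
#' @param acf an `acf_series` or a plain numeric vector `rho[0..L]`.
#' @param tr repetition time in seconds.
#' @param include_lag0 include the lag-0 coefficient (default TRUE).
#' @return list with `seconds` and `n_positive_lags` (number of summed
#'   coefficients).
#' @export
int_from_acf <- function(acf, tr, include_lag0 = TRUE) {
  rho <- if (inherits(acf, "acf_series")) acf$rho else as.numeric(acf)
  stopifnot(tr > 0, length(rho) >= 1)
  start <- if (include_lag0) 1L else 2L
  s <- 0
  n <- 0L
  k <- start
  while (k <= length(rho) && rho[k] > 0) {
    s <- s + rho[k]
    n <- n + 1L
    k <- k + 1L
  }
  list(seconds = s * tr, n_positive_lags = n)
}

#' Voxel-wise intrinsic-timescale map
#'
#' Applies [acf_biased()] + [int_from_acf()] to every in-mask voxel of a
#' (preprocessed) BOLD image: the per-voxel autocorrelation function is
#' accumulated lag by lag until it first becomes non-positive, and the
#' running sum times TR is the intrinsic neural timescale in seconds.
#' Voxels outside the mask, and constant voxels (flagged with a warning),
#' are NaN. Fully deterministic.
#'
#' @param bold a `bold_image` (already preprocessed).
#' @param mask a `brain_mask` on the same grid.
#' @param include_lag0 see [int_from_acf()].
#' @param max_lag largest lag examined (default `T - 2`).
#' @return A `voxel_map` of kind `int_seconds`.
#' @export
compute_int_map <- function(bold, mask, include_lag0 = TRUE,
                            max_lag = NULL) {
  stop_unless_same_grid(bold$grid, mask$grid, "BOLD and mask")
  T <- bold$n_volumes
  if (is.null(max_lag)) max_lag <- T - 2L
  max_lag <- min(as.integer(max_lag), T - 1L)
  idx <- which(mask$data)
  Y <- matrix(aperm(bold$data, c(4, 1, 2, 3)), nrow = T)[, idx, drop = FALSE]
  Y <- sweep(Y, 2, colMeans(Y))
  denom <- colSums(Y^2)
  V <- ncol(Y)
  int <- rep(NaN, V)
  ok <- denom > 0
  if (any(!ok))
    warning(sum(!ok), " constant voxel(s) inside the mask set to NaN")
  # walk lags jointly; retire voxels at their first non-positive rho
  s <- rep(if (include_lag0) 1 else 0, V)
  active <- ok
  for (k in seq_len(max_lag)) {
    if (!any(active)) break
    a <- which(active)
    num <- colSums(Y[seq_len(T - k), a, drop = FALSE] *
                     Y[seq.int(k + 1L, T), a, drop = FALSE])
    rho <- num / denom[a]
    stopnow <- rho <= 0
    s[a[!stopnow]] <- s[a[!stopnow]] + rho[!stopnow]
    active[a[stopnow]] <- FALSE
  }
  int[ok] <- s[ok] * bold$tr
  dat <- array(NaN, dim = bold$grid$shape)
  dat[idx] <- int
  voxel_map(bold$grid, dat, kind = "int_seconds")
}

.gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- ceiling(4 * sigma_vox)
  w <- stats::dnorm(-r:r, sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    inb <- j >= 1 & j <= n
    K[i, j[inb]] <- w[inb]
  }
  K
}

.smooth_axis <- function(arr, K, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- K %*% matrix(a, nrow = d[1])
  aperm(array(m, dim = d), order(perm))
}

#' Mask-aware Gaussian smoothing of a 3D map
#'
#' Separable Gaussian convolution with per-axis sigma
#' `fwhm / (voxel_size * 2 sqrt(2 ln 2))` voxels. With a mask, the
#' normalized form `smooth(map * mask) / smooth(mask)` is used inside the
#' mask (so constant maps are preserved and no signal bleeds in from
#' outside); voxels outside the mask are NaN. `fwhm_mm = 0` is the
#' identity.
#'
#' @param map a `voxel_map` (NaN/NA allowed outside the mask).
#' @param fwhm_mm kernel full width at half maximum, mm (>= 0).
#' @param mask optional `brain_mask`.
#' @return A smoothed `voxel_map` of the same kind.
#' @export
smooth_map <- function(map, fwhm_mm, mask = NULL) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(map)
  sig <- fwhm_mm / (map$grid$voxel_size * 2 * sqrt(2 * log(2)))
  Ks <- lapply(1:3, function(a)
    .gaussian_kernel_matrix(map$grid$shape[a], sig[a]))
  sm <- function(arr) {
    for (a in 1:3) arr <- .smooth_axis(arr, Ks[[a]], a)
    arr
  }
  if (is.null(mask)) {
    dat <- sm(map$data)
  } else {
    stop_unless_same_grid(map$grid, mask$grid, "map and mask")
    m <- array(as.numeric(mask$data), dim = map$grid$shape)
    x <- map$data
    x[!mask$data | !is.finite(x)] <- 0
    num <- sm(x)
    den <- sm(m)
    dat <- array(NaN, dim = map$grid$shape)
    inm <- mask$data & den > 0
    dat[inm] <- num[inm] / den[inm]
  }
  voxel_map(map$grid, dat, kind = map$kind, units = map$units)
}

#' Z-transform a map over its in-mask voxels
#'
#' Subtracts the mean and divides by the standard deviation computed over
#' the finite in-mask voxels of this map (per-subject spatial
#' standardization). The output has in-mask mean 0 and SD 1, preserves
#' voxel rank order, and is invariant to positive affine rescaling of the
#' input.
#'
#' @param map a `voxel_map`.
#' @param mask a `brain_mask`.
#' @return A `voxel_map` of kind `int_z`.
#' @export
zscore_map <- function(map, mask) {
  stop_unless_same_grid(map$grid, mask$grid, "map and mask")
  inm <- mask$data & is.finite(map$data)
  v <- map$data[inm]
  if (length(v) < 2L) stop("need at least 2 finite in-mask voxels")
  s <- stats::sd(v)
  if (s <= 0) stop("zero variance inside the mask; cannot z-transform")
  dat <- array(NaN, dim = map$grid$shape)
  dat[inm] <- (v - mean(v)) / s
  voxel_map(map$grid, dat, kind = "int_z")
}

#' Z-transform a set of maps per voxel within groups
#'
#' Alternative standardization: each voxel is standardized across
#' subjects within its group (mean 0, SD 1 per voxel per group). Provided
#' as a switch alongside the per-subject default of [zscore_map()].
#'
#' @param maps list of `voxel_map`s on one grid.
#' @param group factor/vector of group labels, one per map.
#' @param mask a `brain_mask`.
#' @return list of `voxel_map`s of kind `int_z`.
#' @export
zscore_maps_groupwise <- function(maps, group, mask) {
  stopifnot(length(maps) == length(group))
  group <- as.factor(group)
  idx <- which(mask$data)
  Y <- vapply(maps, function(m) {
    stop_unless_same_grid(m$grid, mask$grid, "map and mask")
    m$data[idx]
  }, numeric(length(idx)))
  for (g in levels(group)) {
    cols <- which(group == g)
    mu <- rowMeans(Y[, cols, drop = FALSE])
    sd <- apply(Y[, cols, drop = FALSE], 1, stats::sd)
    if (any(sd <= 0, na.rm = TRUE))
      stop("zero across-subject variance at some voxel in group ", g)
    Y[, cols] <- (Y[, cols, drop = FALSE] - mu) / sd
  }
  lapply(seq_along(maps), function(i) {
    dat <- array(NaN, dim = mask$grid$shape)
    dat[idx] <- Y[, i]
    voxel_map(mask$grid, dat, kind = "int_z")
  })
}

#' Full single-subject timescale pipeline
#'
#' Convenience wrapper: temporal preprocessing ([preprocess_bold()]),
#' timescale map ([compute_int_map()]), 6 mm smoothing
#' ([smooth_map()]), then per-subject z-transform ([zscore_map()]) —
#' smoothing strictly before standardization.
#'
#' @param bold a raw `bold_image`.
#' @param mask a `brain_mask`.
#' @param motion optional `motion_params` (full-length series).
#' @param fwhm_mm smoothing kernel FWHM (default 6).
#' @param include_lag0 see [int_from_acf()].
#' @param ... further arguments to [preprocess_bold()].
#' @return list with `int_seconds` and `int_z` maps and `mean_fd`.
#' @export
int_subject_pipeline <- function(bold, mask, motion = NULL, fwhm_mm = 6,
                                 include_lag0 = TRUE, ...) {
  pp <- preprocess_bold(bold, mask, motion = motion, ...)
  raw <- compute_int_map(pp, mask, include_lag0 = include_lag0)
  sm <- smooth_map(raw, fwhm_mm, mask)
  z <- zscore_map(sm, mask)
  list(int_seconds = raw, int_smoothed = sm, int_z = z,
       mean_fd = if (!is.null(attr(pp, "motion")))
         attr(pp, "motion")$mean_fd else NA_real_)
}
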