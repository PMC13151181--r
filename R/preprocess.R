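#' Realignment parameters with derived motion summaries
#'
#' Holds per-volume rigid-body realignment estimates and computes the
#' Friston-24 expansion and Power's framewise displacement (FD): the sum
#' of absolute backward differences of the six parameters, rotations
#' converted to mm of arc on a 50 mm sphere; FD of the first volume is 0.
#'
#' @param params T x 6 numeric matrix: translations x/y/z in mm, then
#'   rotations in degrees.
#' @param sphere_radius_mm head radius used to convert rotations to mm.
#' @return A `motion_params` object with fields `trans`, `rot`, `fd`,
#'   `mean_fd`, `friston24`.
#' @export
motion_params <- function(params, sphere_radius_mm = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion parameters must have 6 columns")
  storage.mode(params) <- "double"
  trans <- params[, 1:3, drop = FALSE]
  rot <- params[, 4:6, drop = FALSE]
  d <- diff(params)
  fd <- c(0, rowSums(abs(d[, 1:3, drop = FALSE])) +
            sphere_radius_mm * rowSums(abs(d[, 4:6, drop = FALSE]) * pi / 180))
  lag1 <- rbind(0, params[-nrow(params), , drop = FALSE])
  f24 <- cbind(params, lag1, params^2, lag1^2)
  colnames(f24) <- c(paste0("rp", 1:6), paste0("rp", 1:6, "_lag"),
                     paste0("rp", 1:6, "_sq"), paste0("rp", 1:6, "_lagsq"))
  structure(list(trans = trans, rot = rot, fd = fd, mean_fd = mean(fd),
                 friston24 = f24),
            class = "motion_params")
}

#' Head-motion exclusion rule
#'
#' A subject is excluded when any absolute translation exceeds
#' `trans_limit_mm` or any absolute rotation exceeds `rot_limit_deg`
#' (strict inequalities; a subject exactly at the limit is kept).
#'
#' @param motion a `motion_params` object.
#' @param trans_limit_mm,rot_limit_deg positive limits (defaults 2.5).
#' @return list with `exclude`, `max_translation_mm`, `max_rotation_deg`.
#' @export
motion_exclusion <- function(motion, trans_limit_mm = 2.5,
                             rot_limit_deg = 2.5) {
  stopifnot(trans_limit_mm > 0, rot_limit_deg > 0)
  mt <- max(abs(motion$trans))
  mr <- max(abs(motion$rot))
  list(exclude = (mt > trans_limit_mm) || (mr > rot_limit_deg),
       max_translation_mm = mt, max_rotation_deg = mr)
}

#' Drop initial volumes of a BOLD series
#'
#' Removes the first `n_drop` time points (signal-equilibrium scrub).
#' @param bold a `bold_image`.
#' @param n_drop non-negative integer, strictly less than the number of
#'   volumes.
#' @return A `bold_image` with `n_volumes - n_drop` time points.
#' @export
drop_initial_volumes <- function(bold, n_drop) {
  n_drop <- as.integer(n_drop)
  if (n_drop < 0L) stop("n_drop must be non-negative")
  if (n_drop >= bold$n_volumes)
    stop("n_drop (", n_drop, ") must be < number of volumes (",
         bold$n_volumes, ")")
  if (n_drop == 0L) return(bold)
  bold_image(bold$grid, bold$data[, , , -seq_len(n_drop), drop = FALSE],
             bold$tr)
}

#' Remove a linear trend
#'
#' Residualizes each series on an intercept plus linear ramp by ordinary
#' least squares. Output has zero mean and zero linear trend; a constant
#' series maps to the zero vector.
#'
#' @param series numeric vector (length >= 3) or T x V matrix (columns are
#'   voxels).
#' @return Same shape as the input.
#' @export
detrend_linear <- function(series) {
  y <- as.matrix(series)
  T <- nrow(y)
  if (T < 3L) stop("need at least 3 time points")
  X <- cbind(1, seq_len(T) - (T + 1) / 2)
  res <- y - X %*% solve(crossprod(X), crossprod(X, y))
  if (is.vector(series)) drop(res) else res
}

#' Ideal band-pass filter in the discrete Fourier domain
#'
#' Retains DFT bins whose frequency lies in `[low_hz, high_hz]` (both
#' positive- and negative-frequency copies), zeroes all others, and
#' returns the real part of the inverse transform. The DC bin is removed
#' whenever `low_hz > 0`, so the output is mean-free. Applying the filter
#' twice equals applying it once (it is a projection).
#'
#' @param series numeric vector or T x V matrix.
#' @param tr sampling interval in seconds.
#' @param low_hz,high_hz pass band; `0 <= low < high <= 1/(2 tr)`.
#' @return Filtered series, same shape as input.
#' @export
bandpass_fft <- function(series, tr, low_hz = 0.01, high_hz = 0.08) {
  y <- as.matrix(series)
  T <- nrow(y)
  nyq <- 1 / (2 * tr)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz <= nyq + 1e-12))
    stop("require 0 <= low < high <= Nyquist (", signif(nyq, 4), " Hz)")
  j <- 0:(T - 1)
  freq <- pmin(j, T - j) / (T * tr)
  keep <- freq >= low_hz - 1e-12 & freq <= high_hz + 1e-12
  if (!any(keep)) stop("pass band contains no DFT bin for this T and TR")
  F <- stats::mvfft(y)
  F[!keep, ] <- 0
  out <- Re(stats::mvfft(F, inverse = TRUE)) / T
  if (is.vector(series)) drop(out) else out
}

#' Build the 27-column nuisance regressor set
#'
#' Friston-24 motion expansion plus global, white-matter and CSF mean
#' signals. Any component may be omitted.
#'
#' @param motion a `motion_params` object, or NULL.
#' @param global_signal,wm_signal,csf_signal numeric T-vectors or NULL.
#' @return T x q matrix with column names (q = 27 when all enabled).
#' @export
build_nuisance <- function(motion = NULL, global_signal = NULL,
                           wm_signal = NULL, csf_signal = NULL) {
  parts <- list()
  if (!is.null(motion)) parts$f24 <- motion$friston24
  if (!is.null(global_signal)) parts$global <- cbind(global = global_signal)
  if (!is.null(wm_signal)) parts$wm <- cbind(wm = wm_signal)
  if (!is.null(csf_signal)) parts$csf <- cbind(csf = csf_signal)
  if (!length(parts)) stop("no nuisance components supplied")
  do.call(cbind, unname(parts))
}

#' Regress nuisance covariates out of time series
#'
#' OLS residualization on an intercept plus the nuisance matrix. The
#' nuisance regressors are band-pass filtered with the same filter as the
#' data first (unless `band` is NULL), so the regression cannot
#' reintroduce frequencies outside the pass band. Collinear columns are
#' dropped with a warning.
#'
#' @param series numeric vector or T x V matrix.
#' @param nuisance T x q regressor matrix.
#' @param tr sampling interval (seconds), needed when `band` is given.
#' @param band length-2 pass band in Hz applied to the regressors, or
#'   NULL to use them unfiltered.
#' @return Residual series, same shape as input; orthogonal to every
#'   retained regressor.
#' @export
regress_nuisance <- function(series, nuisance, tr = NULL,
                             band = c(0.01, 0.08)) {
  y <- as.matrix(series)
  N <- as.matrix(nuisance)
  if (nrow(N) != nrow(y)) stop("nuisance rows must match series length")
  if (!is.null(band)) {
    if (is.null(tr)) stop("tr required to filter nuisance regressors")
    keepcol <- apply(N, 2, function(v) stats::sd(v) > 0)
    N[, keepcol] <- bandpass_fft(N[, keepcol, drop = FALSE], tr,
                                 band[1], band[2])
  }
  X <- cbind(intercept = 1, N)
  if (nrow(y) <= ncol(X))
    stop("need more time points than regressors (T > q + 1)")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(X))]
    warning("dropping ", length(drop_idx),
            " collinear nuisance column(s): ",
            paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
    qrX <- qr(X)
  }
  res <- qr.resid(qrX, y)
  if (is.vector(series)) drop(res) else res
}

#' Flag motion/amplitude outliers for despiking
#'
#' Union of FD-flagged frames (`fd > fd_threshold`) and amplitude
#' outliers lying more than `c_mad` robust standard deviations
#' (1.4826 x MAD) from an 11-point running median of the series
#' (Hampel-style detector).
#'
#' @param series numeric T-vector.
#' @param fd framewise displacement T-vector or NULL.
#' @param fd_threshold_mm scrub threshold on FD.
#' @param c_mad outlier threshold in MAD units.
#' @param window running-median window (odd integer).
#' @return logical T-vector of flags.
#' @export
flag_outliers <- function(series, fd = NULL, fd_threshold_mm = 0.5,
                          c_mad = 5, window = 11L) {
  T <- length(series)
  # endrule "keep": the first/last half-window keep their raw values,
  # so amplitude flagging starts half a window into the run (FD-based
  # flags still cover the edges)
  med <- stats::runmed(series, k = min(window, T - (1 - T %% 2)),
                       endrule = "keep")
  dev <- series - med
  s <- stats::mad(dev)
  flags <- if (s > 0) abs(dev) > c_mad * s else rep(FALSE, T)
  if (!is.null(fd)) flags <- flags | (fd > fd_threshold_mm)
  flags
}

#' Replace flagged time points by spline interpolation
#'
#' Flagged frames are replaced with a natural cubic spline fitted through
#' the unflagged points; flagged frames outside the unflagged range are
#' clamped to the nearest unflagged value. Unflagged points pass through
#' unchanged.
#'
#' @param series numeric T-vector.
#' @param flags logical T-vector; at least 4 points must be unflagged.
#' @return Despiked T-vector.
#' @export
despike_interpolate <- function(series, flags) {
  T <- length(series)
  flags <- as.logical(flags)
  if (length(flags) != T) stop("flags must match series length")
  if (!any(flags)) return(series)
  good <- which(!flags)
  if (length(good) < 4L) stop("fewer than 4 unflagged points")
  bad <- which(flags)
  f <- stats::splinefun(good, series[good], method = "natural")
  inside <- bad >= good[1] & bad <= good[length(good)]
  out <- series
  out[bad[inside]] <- f(bad[inside])
  out[bad[!inside & bad < good[1]]] <- series[good[1]]
  out[bad[!inside & bad > good[length(good)]]] <- series[good[length(good)]]
  out
}

#' Temporal preprocessing chain for one BOLD run
#'
#' Applies, in fixed order: (1) initial-volume drop, (2) linear
#' detrending, (3) ideal band-pass filtering, (4) nuisance regression
#' (Friston-24 + global/WM/CSF means, themselves band-pass filtered),
#' (5) despiking/scrubbing by spline replacement of FD-flagged and
#' amplitude-outlier frames. Deterministic; the grid and (after the drop)
#' the number of volumes never change.
#'
#' @param bold a `bold_image`.
#' @param mask a `brain_mask`; voxels outside are left untouched at 0.
#' @param motion a `motion_params` object with rows matching the
#'   *undropped* series, or NULL to skip motion-derived regressors.
#' @param wm_mask,csf_mask optional `brain_mask`s for tissue mean signals.
#' @param n_drop initial volumes removed (default 10).
#' @param band pass band in Hz (default 0.01-0.08).
#' @param use_global include the in-mask global mean signal as a nuisance.
#' @param fd_threshold_mm,c_mad,window despiking parameters, see
#'   [flag_outliers()].
#' @param despike logical; apply step (5).
#' @return A preprocessed `bold_image`; attribute `"motion"` carries the
#'   (dropped-frame) `motion_params`.
#' @export
preprocess_bold <- function(bold, mask, motion = NULL,
                            wm_mask = NULL, csf_mask = NULL,
                            n_drop = 10L, band = c(0.01, 0.08),
                            use_global = TRUE,
                            fd_threshold_mm = 0.5, c_mad = 5, window = 11L,
                            despike = TRUE) {
  stop_unless_same_grid(bold$grid, mask$grid, "BOLD and mask")
  bold <- drop_initial_volumes(bold, n_drop)
  if (!is.null(motion)) {
    p <- cbind(motion$trans, motion$rot)
    if (nrow(p) < bold$n_volumes + n_drop)
      stop("motion parameters shorter than the BOLD series")
    motion <- motion_params(p[seq.int(n_drop + 1L, n_drop + bold$n_volumes), ,
                              drop = FALSE])
  }
  T <- bold$n_volumes
  idx <- which(mask$data)
  flatT <- matrix(aperm(bold$data, c(4, 1, 2, 3)), nrow = T)
  Y <- flatT[, idx, drop = FALSE]

  Y <- detrend_linear(Y)
  Y <- bandpass_fft(Y, bold$tr, band[1], band[2])

  tissue_mean <- function(m) {
    if (is.null(m)) return(NULL)
    stop_unless_same_grid(bold$grid, m$grid, "BOLD and tissue mask")
    rowMeans(flatT[, which(m$data), drop = FALSE])
  }
  nuis <- NULL
  gs <- if (use_global) rowMeans(Y) else NULL
  has_any <- !is.null(motion) || !is.null(gs) ||
    !is.null(wm_mask) || !is.null(csf_mask)
  if (has_any) {
    nuis <- build_nuisance(motion, gs, tissue_mean(wm_mask),
                           tissue_mean(csf_mask))
    Y <- regress_nuisance(Y, nuis, tr = bold$tr, band = band)
  }

  if (despike) {
    fd <- if (!is.null(motion)) motion$fd else NULL
    for (v in seq_len(ncol(Y))) {
      fl <- flag_outliers(Y[, v], fd = fd,
                          fd_threshold_mm = fd_threshold_mm,
                          c_mad = c_mad, window = window)
      if (any(fl)) Y[, v] <- despike_interpolate(Y[, v], fl)
    }
  }

  flat <- matrix(0, nrow = T, ncol = prod(bold$grid$shape))
  flat[, idx] <- Y
  out <- aperm(array(flat, dim = c(T, bold$grid$shape)), c(2, 3, 4, 1))
  res <- bold_image(bold$grid, out, bold$tr)
  attr(res, "motion") <- motion
  res
}
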