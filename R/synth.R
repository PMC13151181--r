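#' Synthetic cohort configuration
#'
#' Defines the simulated two-group study: 36 patients vs 30 controls,
#' 200-volume BOLD runs at TR 2 s on a 3 mm grid, modulated gray-matter
#' maps on a 2 mm grid, region-specific AR(1) temporal structure with a
#' patient shift in designated effect regions, gray-matter group shifts
#' of both signs, divergent group-specific age slopes for the global
#' volumes, and cognition scores linearly coupled to regional gray
#' matter. Region centers are placed at fixed fractions of the brain's
#' half-extent so the same physical layout scales to any grid size;
#' radii are in mm.
#'
#' AR(1) voxels have unit stationary variance (`eps ~ N(0, 1 - phi^2)`),
#' so the ground-truth timescale is available in closed form:
#' `TR * (1 + phi / (1 - phi))` when lag 0 is included.
#'
#' @param n_patient,n_control group sizes.
#' @param bold_shape,bold_voxel_mm BOLD grid (voxels, mm).
#' @param n_volumes,tr volumes per run and repetition time (s).
#' @param gmv_shape,gmv_voxel_mm gray-matter grid.
#' @param phi_sensory,phi_association baseline AR coefficients for the
#'   posterior ("sensory", y <= 0) and anterior ("association", y > 0)
#'   strata.
#' @param phi_roi baseline AR coefficient inside the timescale effect
#'   regions.
#' @param phi_delta added to `phi_roi` for patients in effect regions
#'   (default -0.2: patients 0.45 vs controls 0.65).
#' @param drift_amplitude shared linear drift amplitude (removed by
#'   detrending).
#' @param observation_noise_sd white measurement noise added on top of
#'   the AR signal (default 0, keeping the analytic ground truth exact).
#' @param motion_step_mm,motion_step_deg per-volume random-walk steps of
#'   the simulated realignment parameters (small enough to stay well
#'   under the 2.5 mm / 2.5 deg exclusion limits).
#' @param int_roi_radius_mm,null_roi_radius_mm radii of the timescale
#'   effect / null spheres.
#' @param gmv_baseline,gmv_bump_amplitude baseline tissue fraction and
#'   shared anatomical bump height.
#' @param gmv_delta group shift amplitude in gray-matter effect regions
#'   (decrease regions get `-gmv_delta`, the increase region
#'   `+gmv_delta`).
#' @param gmv_roi_radius_mm radius of the gray-matter effect spheres.
#' @param gmv_noise_sd standard deviation of the smooth subject noise
#'   field (after smoothing).
#' @param gmv_noise_fwhm_mm smoothness of the subject noise field.
#' @param age_range uniform age range in years, both groups.
#' @param wmi_coupling,pri_coupling linear coupling (index points per
#'   unit tissue fraction) of WMI to region A and PRI to region B.
#' @param cognition_noise_sd residual SD of the coupled indices.
#' @param mask_fraction ellipsoid semi-axes as a fraction of the grid
#'   half-extent.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patient = 36L, n_control = 30L,
                         bold_shape = c(30L, 36L, 30L), bold_voxel_mm = 3,
                         n_volumes = 200L, tr = 2,
                         gmv_shape = c(45L, 54L, 45L), gmv_voxel_mm = 2,
                         phi_sensory = 0.3, phi_association = 0.7,
                         phi_roi = 0.65, phi_delta = -0.2,
                         drift_amplitude = 0.3,
                         observation_noise_sd = 0,
                         motion_step_mm = 0.01, motion_step_deg = 0.008,
                         int_roi_radius_mm = 9, null_roi_radius_mm = 7,
                         gmv_baseline = 0.5, gmv_bump_amplitude = 0.1,
                         gmv_delta = 0.08, gmv_roi_radius_mm = 7,
                         gmv_noise_sd = 0.04, gmv_noise_fwhm_mm = 6,
                         age_range = c(5, 14),
                         wmi_coupling = 600, pri_coupling = 600,
                         cognition_noise_sd = 8,
                         mask_fraction = 0.92) {
  stopifnot(n_patient >= 2, n_control >= 2,
            abs(phi_sensory) < 0.95, abs(phi_association) < 0.95,
            abs(phi_roi) < 0.95, abs(phi_roi + phi_delta) < 0.95)
  cfg <- list(
    n_patient = as.integer(n_patient), n_control = as.integer(n_control),
    bold_shape = as.integer(bold_shape), bold_voxel_mm = bold_voxel_mm,
    n_volumes = as.integer(n_volumes), tr = tr,
    gmv_shape = as.integer(gmv_shape), gmv_voxel_mm = gmv_voxel_mm,
    phi_sensory = phi_sensory, phi_association = phi_association,
    phi_roi = phi_roi, phi_delta = phi_delta,
    drift_amplitude = drift_amplitude,
    observation_noise_sd = observation_noise_sd,
    motion_step_mm = motion_step_mm, motion_step_deg = motion_step_deg,
    int_roi_radius_mm = int_roi_radius_mm,
    null_roi_radius_mm = null_roi_radius_mm,
    gmv_baseline = gmv_baseline, gmv_bump_amplitude = gmv_bump_amplitude,
    gmv_delta = gmv_delta, gmv_roi_radius_mm = gmv_roi_radius_mm,
    gmv_noise_sd = gmv_noise_sd, gmv_noise_fwhm_mm = gmv_noise_fwhm_mm,
    age_range = age_range,
    wmi_coupling = wmi_coupling, pri_coupling = pri_coupling,
    cognition_noise_sd = cognition_noise_sd,
    mask_fraction = mask_fraction,
    # volumetric trend parameters: Table-1-scale means at the group mean
    # age, group-specific slopes (ml / year), residual SDs (ml)
    vol_params = list(
      tiv = list(pat = c(1580, -6), ctl = c(1468, 8), sd = 40),
      gm  = list(pat = c(805, -5),  ctl = c(786, 6),  sd = 30),
      wm  = list(pat = c(508, 3),   ctl = c(469, 9),  sd = 25),
      csf = list(pat = c(271, -3),  ctl = c(213, 4),  sd = 20)),
    # WISC-IV group means/SDs for the uncoupled indices and the coupled
    # baselines (coupled indices get cognition_noise_sd residuals)
    wisc_params = list(
      fsiq = list(pat = c(92, 16.3), ctl = c(107.7, 9.7)),
      vci  = list(pat = c(92.3, 17.7), ctl = c(100.8, 11.2)),
      psi  = list(pat = c(97.1, 17.4), ctl = c(107.1, 14.5)),
      wmi_base = c(pat = 88.6, ctl = 93.9),
      pri_base = c(pat = 95.3, ctl = 108.6)))
  class(cfg) <- "synth_config"
  cfg
}

#' Deterministic child seed from a master seed
#'
#' Stable integer hash so any subject/modality is regenerable in
#' isolation. Values stay below 2^25.
#'
#' @param master master seed (integer).
#' @param ... further integer components (subject index, modality code).
#' @export
child_seed <- function(master, ...) {
  h <- 0
  for (v in c(master, ...)) h <- (h * 69069 + as.numeric(v) + 1) %% 33554393
  as.integer(h)
}

#' Spherical region mask in mm coordinates
#'
#' @param grid an `image_grid`.
#' @param center_mm length-3 center.
#' @param radius_mm radius.
#' @return logical 3D array.
#' @export
sphere_mask <- function(grid, center_mm, radius_mm) {
  ijk <- arrayInd(seq_len(prod(grid$shape)), grid$shape)
  mm <- voxel_to_mm(grid, ijk)
  d2 <- (mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2 +
    (mm[, 3] - center_mm[3])^2
  array(d2 <= radius_mm^2, dim = grid$shape)
}

.ellipsoid_mask <- function(grid, fraction) {
  half <- (grid$shape - 1) / 2 * grid$voxel_size
  ijk <- arrayInd(seq_len(prod(grid$shape)), grid$shape)
  mm <- voxel_to_mm(grid, ijk)
  r <- fraction * half
  d <- (mm[, 1] / r[1])^2 + (mm[, 2] / r[2])^2 + (mm[, 3] / r[3])^2
  array(d <= 1, dim = grid$shape)
}

.mm_coords <- function(grid) {
  voxel_to_mm(grid, arrayInd(seq_len(prod(grid$shape)), grid$shape))
}

#' Resolve the cohort geometry (grids, masks, regions)
#'
#' Expands a `synth_config` into concrete grids, brain/tissue masks and
#' region masks. Region centers are fixed fractions of the half-extent:
#' timescale effect regions A/B at (-/+0.45, -/+0.35, 0), a timescale
#' null region at (0, 0, 0.5); gray-matter decrease regions A/B at the
#' same lateral fractions, an increase region at (0, 0, 0.45) and a null
#' region at (0, 0, -0.45).
#'
#' @param config a `synth_config`.
#' @return list with `bold_grid`, `gmv_grid`, masks, region masks, and
#'   the per-voxel group AR maps (`phi_control`, `phi_patient`).
#' @export
synth_geometry <- function(config) {
  bg <- centered_grid(config$bold_shape, config$bold_voxel_mm)
  gg <- centered_grid(config$gmv_shape, config$gmv_voxel_mm)
  bhalf <- (bg$shape - 1) / 2 * bg$voxel_size
  ghalf <- (gg$shape - 1) / 2 * gg$voxel_size
  at <- function(half, f) half * f

  bold_mask <- .ellipsoid_mask(bg, config$mask_fraction)
  gmv_mask <- .ellipsoid_mask(gg, config$mask_fraction)

  int_rois <- list(
    A = sphere_mask(bg, at(bhalf, c(-0.45, -0.35, 0)),
                    config$int_roi_radius_mm),
    B = sphere_mask(bg, at(bhalf, c(0.45, 0.35, 0)),
                    config$int_roi_radius_mm),
    none = sphere_mask(bg, at(bhalf, c(0, 0, 0.5)),
                       config$null_roi_radius_mm))
  int_roles <- c(A = "effect", B = "effect", none = "null")

  gmv_rois <- list(
    A = sphere_mask(gg, at(ghalf, c(-0.45, -0.35, 0)),
                    config$gmv_roi_radius_mm),
    B = sphere_mask(gg, at(ghalf, c(0.45, 0.35, 0)),
                    config$gmv_roi_radius_mm),
    up = sphere_mask(gg, at(ghalf, c(0, 0, 0.45)),
                     config$gmv_roi_radius_mm),
    none = sphere_mask(gg, at(ghalf, c(0, 0, -0.45)),
                       config$null_roi_radius_mm))
  gmv_deltas <- c(A = -config$gmv_delta, B = -config$gmv_delta,
                  up = config$gmv_delta, none = 0)

  # tissue-signal masks for nuisance regression (small spheres away from
  # the effect regions)
  wm_mask <- sphere_mask(bg, at(bhalf, c(0, -0.55, 0.4)), 4) & bold_mask
  csf_mask <- sphere_mask(bg, at(bhalf, c(0, 0.55, -0.4)), 4) & bold_mask

  mm <- .mm_coords(bg)
  phi <- array(ifelse(mm[, 2] > 0, config$phi_association,
                      config$phi_sensory), dim = bg$shape)
  for (nm in names(int_rois)) phi[int_rois[[nm]]] <- config$phi_roi
  phi_pat <- phi
  for (nm in names(int_rois)[int_roles == "effect"])
    phi_pat[int_rois[[nm]]] <- config$phi_roi + config$phi_delta

  list(bold_grid = bg, gmv_grid = gg,
       bold_mask = brain_mask(bg, bold_mask),
       gmv_mask = brain_mask(gg, gmv_mask),
       wm_mask = brain_mask(bg, wm_mask),
       csf_mask = brain_mask(bg, csf_mask),
       int_rois = int_rois, int_roles = int_roles,
       gmv_rois = gmv_rois, gmv_deltas = gmv_deltas,
       phi_control = phi, phi_patient = phi_pat)
}

#' Simulate one subject's BOLD run and motion trace
#'
#' Per in-mask voxel, `x_t = phi x_{t-1} + eps_t` with
#' `eps ~ N(0, 1 - phi^2)` (unit stationary variance; `x_0` drawn from
#' the stationary distribution), plus a shared low-amplitude linear
#' drift and optional white observation noise. The motion trace is a
#' small-amplitude random walk well below the exclusion limits.
#' Deterministic given `(config, subject index, seed)`.
#'
#' @param config a `synth_config`.
#' @param subject subject index (integer, used in the child seed).
#' @param group `"patient"` or `"control"`.
#' @param seed master seed.
#' @param geometry optional precomputed [synth_geometry()] result.
#' @return list with `bold` (a `bold_image`) and `motion`
#'   (a `motion_params`).
#' @export
generate_bold <- function(config, subject, group, seed,
                          geometry = NULL) {
  if (is.null(geometry)) geometry <- synth_geometry(config)
  group <- match.arg(group, c("patient", "control"))
  phi <- if (group == "patient") geometry$phi_patient else
    geometry$phi_control
  idx <- which(geometry$bold_mask$data)
  ph <- phi[idx]
  V <- length(idx)
  T <- config$n_volumes
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(child_seed(seed, subject, 1L))
  Y <- matrix(0, nrow = T, ncol = V)
  x <- stats::rnorm(V)
  sig <- sqrt(1 - ph^2)
  Y[1, ] <- x
  for (t in 2:T) {
    x <- ph * x + sig * stats::rnorm(V)
    Y[t, ] <- x
  }
  if (config$drift_amplitude != 0)
    Y <- Y + config$drift_amplitude * seq(-1, 1, length.out = T)
  if (config$observation_noise_sd > 0)
    Y <- Y + stats::rnorm(T * V, sd = config$observation_noise_sd)
  flat <- matrix(0, nrow = T, ncol = prod(config$bold_shape))
  flat[, idx] <- Y
  dat <- array(aperm(array(flat, dim = c(T, config$bold_shape)),
                     c(2, 3, 4, 1)), dim = c(config$bold_shape, T))
  steps <- cbind(matrix(stats::rnorm(3 * T, sd = config$motion_step_mm),
                        ncol = 3),
                 matrix(stats::rnorm(3 * T, sd = config$motion_step_deg),
                        ncol = 3))
  mp <- apply(steps, 2, cumsum)
  list(bold = bold_image(geometry$bold_grid, dat, config$tr),
       motion = motion_params(mp))
}

.smooth_noise_field <- function(grid, fwhm_mm, sd) {
  # white noise smoothed to the requested FWHM, then rescaled so the
  # marginal SD equals `sd` exactly (using the kernel's variance factor)
  z <- array(stats::rnorm(prod(grid$shape)), dim = grid$shape)
  sig <- fwhm_mm / (grid$voxel_size * 2 * sqrt(2 * log(2)))
  fac <- 1
  for (a in 1:3) {
    K <- .gaussian_kernel_matrix(grid$shape[a], sig[a])
    z <- .smooth_axis(z, K, a)
    r <- ceiling(4 * sig[a])
    w <- stats::dnorm(-r:r, sd = sig[a])
    w <- w / sum(w)
    fac <- fac * sum(w^2)
  }
  z * sd / sqrt(fac)
}

#' Simulate one subject's modulated gray-matter map
#'
#' Baseline tissue fraction plus fixed smooth anatomical bumps at the
#' region centers, a subject-specific smooth Gaussian noise field
#' (white noise smoothed to `gmv_noise_fwhm_mm`, rescaled to
#' `gmv_noise_sd`), and — for patients — the group shift applied
#' uniformly inside each effect sphere (`gmv_deltas`). Values are
#' clipped to [0, 1].
#'
#' @inheritParams generate_bold
#' @return A `voxel_map` of kind `gmv`.
#' @export
generate_gmv <- function(config, subject, group, seed, geometry = NULL) {
  if (is.null(geometry)) geometry <- synth_geometry(config)
  group <- match.arg(group, c("patient", "control"))
  gg <- geometry$gmv_grid
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(child_seed(seed, subject, 2L))
  dat <- array(config$gmv_baseline, dim = gg$shape)
  mm <- .mm_coords(gg)
  ghalf <- (gg$shape - 1) / 2 * gg$voxel_size
  centers <- list(A = ghalf * c(-0.45, -0.35, 0),
                  B = ghalf * c(0.45, 0.35, 0),
                  up = ghalf * c(0, 0, 0.45),
                  none = ghalf * c(0, 0, -0.45))
  sig <- config$gmv_roi_radius_mm / 2
  for (nm in names(centers)) {
    d2 <- (mm[, 1] - centers[[nm]][1])^2 + (mm[, 2] - centers[[nm]][2])^2 +
      (mm[, 3] - centers[[nm]][3])^2
    prof <- array(exp(-d2 / (2 * sig^2)), dim = gg$shape)
    dat <- dat + config$gmv_bump_amplitude * prof
    if (group == "patient" && geometry$gmv_deltas[nm] != 0)
      dat <- dat + geometry$gmv_deltas[nm] * geometry$gmv_rois[[nm]]
  }
  dat <- dat + .smooth_noise_field(gg, config$gmv_noise_fwhm_mm,
                                   config$gmv_noise_sd)
  dat[dat < 0] <- 0
  dat[dat > 1] <- 1
  voxel_map(gg, dat, kind = "gmv")
}

#' Simulate the covariate / cognition table
#'
#' Ages are uniform over the configured range in both groups. Global
#' volumes follow group-specific linear age trends (patients' TIV/GM/CSF
#' decrease with age while controls' increase; WM rises in both with a
#' shallower patient slope). WMI is linearly coupled to the region-A
#' gray-matter mean and PRI to region B; FSIQ/VCI/PSI are uncoupled
#' draws at Table-1-scale group means. Steroid months are positive for
#' patients and 0 for controls.
#'
#' @param config a `synth_config`.
#' @param seed master seed.
#' @param gmv_roi_means optional data.frame/list with per-subject region
#'   means (columns `A`, `B`); when NULL, latent standins with the same
#'   spread are simulated.
#' @param mean_fd optional per-subject mean framewise displacement.
#' @return data.frame of subject records (patients first, then
#'   controls).
#' @export
generate_tables <- function(config, seed, gmv_roi_means = NULL,
                            mean_fd = NULL) {
  n <- config$n_patient + config$n_control
  grp <- factor(rep(c("patient", "control"),
                    c(config$n_patient, config$n_control)),
                levels = c("control", "patient"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(child_seed(seed, 0L, 3L))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  edu <- pmax(0, round(age - 6 + stats::rnorm(n, sd = 1), 1))
  ster <- ifelse(grp == "patient",
                 pmax(1, round(stats::rnorm(n, 19.1, 15.2))), 0)
  if (is.null(mean_fd))
    mean_fd <- pmax(0.01, stats::rnorm(n, 0.08, 0.02))
  mid <- mean(config$age_range)
  volgen <- function(par) {
    mu <- ifelse(grp == "patient",
                 par$pat[1] + par$pat[2] * (age - mid),
                 par$ctl[1] + par$ctl[2] * (age - mid))
    mu + stats::rnorm(n, sd = par$sd)
  }
  vp <- config$vol_params
  tiv <- volgen(vp$tiv); gm <- volgen(vp$gm)
  wm <- volgen(vp$wm); csf <- volgen(vp$csf)

  wiscgen <- function(par) {
    mu <- ifelse(grp == "patient", par$pat[1], par$ctl[1])
    sd <- ifelse(grp == "patient", par$pat[2], par$ctl[2])
    round(mu + stats::rnorm(n) * sd)
  }
  wpar <- config$wisc_params
  fsiq <- wiscgen(wpar$fsiq); vci <- wiscgen(wpar$vci)
  psi <- wiscgen(wpar$psi)
  if (is.null(gmv_roi_means)) {
    gmv_roi_means <- data.frame(A = stats::rnorm(n, sd = 0.02),
                                B = stats::rnorm(n, sd = 0.02))
  }
  devA <- gmv_roi_means$A - mean(gmv_roi_means$A)
  devB <- gmv_roi_means$B - mean(gmv_roi_means$B)
  wmi_base <- ifelse(grp == "patient", wpar$wmi_base["pat"],
                     wpar$wmi_base["ctl"])
  pri_base <- ifelse(grp == "patient", wpar$pri_base["pat"],
                     wpar$pri_base["ctl"])
  wmi <- round(wmi_base + config$wmi_coupling * devA +
                 stats::rnorm(n, sd = config$cognition_noise_sd))
  pri <- round(pri_base + config$pri_coupling * devB +
                 stats::rnorm(n, sd = config$cognition_noise_sd))
  clip <- function(v) pmin(160, pmax(40, v))
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = grp, age_years = round(age, 1), education_years = edu,
    steroid_months = ster, mean_fd_mm = round(mean_fd, 4),
    tiv_ml = round(tiv, 2), gm_ml = round(gm, 2), wm_ml = round(wm, 2),
    csf_ml = round(csf, 2),
    fsiq = clip(fsiq), vci = clip(vci), pri = clip(pri),
    wmi = clip(wmi), psi = clip(psi),
    stringsAsFactors = FALSE)
}

#' Simulate and analyze-ready cohort (in memory)
#'
#' Generates every subject's BOLD run, runs the single-subject timescale
#' pipeline (preprocessing, timescale map, smoothing, z-transform),
#' generates the gray-matter maps and the covariate table, and returns
#' in-mask data matrices ready for [voxel_glm()]. BOLD volumes are
#' discarded after use to bound memory.
#'
#' @param config a `synth_config`.
#' @param seed master seed.
#' @param fwhm_mm smoothing kernel for the timescale maps (default 6).
#' @param include_lag0 see [int_from_acf()].
#' @param preprocess run the temporal preprocessing chain before the
#'   timescale map (default TRUE).
#' @param verbose print per-subject progress.
#' @return A `synth_cohort`: geometry, `int_z` and `int_raw`
#'   (V x n in-mask matrices), `gmv` (V x n), `covariates`,
#'   `ground_truth` (true timescale maps and region masks).
#' @export
simulate_cohort <- function(config, seed, fwhm_mm = 6,
                            include_lag0 = TRUE, preprocess = TRUE,
                            verbose = FALSE) {
  geom <- synth_geometry(config)
  n <- config$n_patient + config$n_control
  grp <- rep(c("patient", "control"), c(config$n_patient, config$n_control))
  bidx <- which(geom$bold_mask$data)
  gidx <- which(geom$gmv_mask$data)
  int_z <- matrix(NA_real_, length(bidx), n)
  int_raw <- matrix(NA_real_, length(bidx), n)
  gmv <- matrix(NA_real_, length(gidx), n)
  mean_fd <- numeric(n)
  for (i in seq_len(n)) {
    sb <- generate_bold(config, i, grp[i], seed, geom)
    if (preprocess) {
      res <- int_subject_pipeline(sb$bold, geom$bold_mask,
                                  motion = sb$motion,
                                  wm_mask = geom$wm_mask,
                                  csf_mask = geom$csf_mask,
                                  fwhm_mm = fwhm_mm,
                                  include_lag0 = include_lag0)
    } else {
      raw <- compute_int_map(sb$bold, geom$bold_mask,
                             include_lag0 = include_lag0)
      sm <- smooth_map(raw, fwhm_mm, geom$bold_mask)
      res <- list(int_seconds = raw, int_smoothed = sm,
                  int_z = zscore_map(sm, geom$bold_mask),
                  mean_fd = sb$motion$mean_fd)
    }
    int_z[, i] <- res$int_z$data[bidx]
    int_raw[, i] <- res$int_smoothed$data[bidx]
    mean_fd[i] <- if (is.finite(res$mean_fd)) res$mean_fd else
      sb$motion$mean_fd
    g <- generate_gmv(config, i, grp[i], seed, geom)
    gmv[, i] <- g$data[gidx]
    if (verbose) message("subject ", i, "/", n, " done")
  }
  roiA <- colMeans(gmv[geom$gmv_rois$A[gidx], , drop = FALSE])
  roiB <- colMeans(gmv[geom$gmv_rois$B[gidx], , drop = FALSE])
  cov <- generate_tables(config, seed,
                         gmv_roi_means = data.frame(A = roiA, B = roiB),
                         mean_fd = mean_fd)
  tr <- config$tr
  true_int <- function(phi) tr * (1 + phi / (1 - phi))
  gt <- list(phi_control = geom$phi_control,
             phi_patient = geom$phi_patient,
             int_control = true_int(geom$phi_control),
             int_patient = true_int(geom$phi_patient),
             int_rois = geom$int_rois, int_roles = geom$int_roles,
             gmv_rois = geom$gmv_rois, gmv_deltas = geom$gmv_deltas,
             couplings = c(wmi = "A", pri = "B"))
  structure(list(config = config, geometry = geom, group = grp,
                 int_z = int_z, int_raw = int_raw, gmv = gmv,
                 covariates = cov, ground_truth = gt, seed = seed),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("synth_cohort:", x$config$n_patient, "patients vs",
      x$config$n_control, "controls; seed", x$seed, "\n")
  cat("  BOLD grid", paste(x$config$bold_shape, collapse = "x"),
      "@", x$config$bold_voxel_mm, "mm;",
      "GMV grid", paste(x$config$gmv_shape, collapse = "x"),
      "@", x$config$gmv_voxel_mm, "mm\n")
  invisible(x)
}

#' Octant network atlas fixture
#'
#' Partitions the in-mask volume into eight octant "networks" (sign of
#' x, y, z around the volume center) with arbitrary large-scale network
#' names — a stand-in parcellation for exercising cluster-network
#' assignment.
#'
#' @param grid an `image_grid`.
#' @param mask optional `brain_mask`; outside voxels get background 0.
#' @return An `atlas_labels` object.
#' @export
synthetic_atlas <- function(grid, mask = NULL) {
  mm <- .mm_coords(grid)
  lab <- 1L + (mm[, 1] > 0) + 2L * (mm[, 2] > 0) + 4L * (mm[, 3] > 0)
  lab <- array(as.integer(lab), dim = grid$shape)
  if (!is.null(mask)) lab[!mask$data] <- 0L
  nms <- data.frame(label = 1:8,
                    name = c("VN", "SMN", "DAN", "SN",
                             "LMB", "FPN", "DMN", "CB"),
                    stringsAsFactors = FALSE)
  atlas_labels(grid, lab, nms)
}

#' Write a synthetic cohort to disk
#'
#' Emits the file layout the file-based pipeline consumes: per-subject
#' BOLD NIfTI and motion text files, gray-matter NIfTI maps, brain/WM/
#' CSF masks, an atlas with its names table, the covariate TSV, and a
#' ground-truth directory (region masks and true timescale maps).
#'
#' @param config a `synth_config`.
#' @param dir output directory (created).
#' @param seed master seed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(config, dir, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- synth_geometry(config)
  n <- config$n_patient + config$n_control
  grp <- rep(c("patient", "control"), c(config$n_patient, config$n_control))
  mean_fd <- numeric(n)
  dir.create(file.path(dir, "bold"), showWarnings = FALSE)
  dir.create(file.path(dir, "gmv"), showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  roiA <- roiB <- numeric(n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    sb <- generate_bold(config, i, grp[i], seed, geom)
    write_bold(sb$bold, file.path(dir, "bold", paste0(sid, ".nii.gz")))
    p <- cbind(sb$motion$trans, sb$motion$rot)
    utils::write.table(p, file.path(dir, "motion", paste0(sid, ".txt")),
                       row.names = FALSE, col.names = FALSE)
    mean_fd[i] <- sb$motion$mean_fd
    g <- generate_gmv(config, i, grp[i], seed, geom)
    write_volume(g, file.path(dir, "gmv", paste0(sid, ".nii.gz")))
    roiA[i] <- mean(g$data[geom$gmv_rois$A & geom$gmv_mask$data])
    roiB[i] <- mean(g$data[geom$gmv_rois$B & geom$gmv_mask$data])
  }
  write_volume(geom$bold_mask, file.path(dir, "bold_mask.nii.gz"))
  write_volume(geom$gmv_mask, file.path(dir, "gmv_mask.nii.gz"))
  write_volume(geom$wm_mask, file.path(dir, "wm_mask.nii.gz"))
  write_volume(geom$csf_mask, file.path(dir, "csf_mask.nii.gz"))
  atl <- synthetic_atlas(geom$bold_grid, geom$bold_mask)
  .write_nifti(array(as.numeric(atl$data), dim = geom$bold_grid$shape),
               geom$bold_grid, file.path(dir, "atlas.nii.gz"))
  utils::write.table(atl$names, file.path(dir, "atlas_names.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  cov <- generate_tables(config, seed,
                         gmv_roi_means = data.frame(A = roiA, B = roiB),
                         mean_fd = mean_fd)
  utils::write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  gtdir <- file.path(dir, "ground_truth")
  dir.create(gtdir, showWarnings = FALSE)
  for (nm in names(geom$int_rois))
    .write_nifti(array(as.numeric(geom$int_rois[[nm]]),
                       dim = geom$bold_grid$shape), geom$bold_grid,
                 file.path(gtdir, paste0("int_roi_", nm, ".nii.gz")))
  for (nm in names(geom$gmv_rois))
    .write_nifti(array(as.numeric(geom$gmv_rois[[nm]]),
                       dim = geom$gmv_grid$shape), geom$gmv_grid,
                 file.path(gtdir, paste0("gmv_roi_", nm, ".nii.gz")))
  tr <- config$tr
  .write_nifti(tr * (1 + geom$phi_control / (1 - geom$phi_control)),
               geom$bold_grid, file.path(gtdir, "int_true_control.nii.gz"))
  .write_nifti(tr * (1 + geom$phi_patient / (1 - geom$phi_patient)),
               geom$bold_grid, file.path(gtdir, "int_true_patient.nii.gz"))
  invisible(dir)
}

#' Matched null configuration
#'
#' Returns a copy of the configuration with every planted effect
#' removed: no AR shift in the effect regions, no gray-matter group
#' deltas, no cognition couplings, and identical (control) age slopes in
#' both groups for all four global volumes. Group sizes, grids, noise
#' levels and all other parameters are untouched, so the null cohort is
#' the exact negative control for the effect cohort.
#'
#' @param config a `synth_config`.
#' @return A `synth_config` with all effects zeroed.
#' @export
null_config <- function(config) {
  config$phi_delta <- 0
  config$gmv_delta <- 0
  config$wmi_coupling <- 0
  config$pri_coupling <- 0
  for (m in names(config$vol_params))
    config$vol_params[[m]]$pat[2] <- config$vol_params[[m]]$ctl[2]
  config
}

#' Score an analysis against the synthetic ground truth
#'
#' Checks which planted effects a [analyze_cohort()] result recovered:
#' a timescale-decrease cluster peaking inside each effect region, a
#' gray-matter decrease cluster in each decrease region and an increase
#' cluster in the increase region, FDR-significant positive WMI
#' (region A) and PRI (region B) correlations, and an FDR-significant
#' TIV group x age interaction. `any_findings` flags whether anything at
#' all was detected (clusters, q < `alpha` correlations, or a
#' q < `alpha` interaction) — the quantity that must stay FALSE on null
#' cohorts.
#'
#' @param analysis a `cohort_analysis`.
#' @param geometry the cohort's [synth_geometry()].
#' @param alpha significance level for the FDR-corrected checks.
#' @return list of logicals: `int_both_rois`, `gmv_decrease`,
#'   `gmv_increase`, `wmi_positive`, `pri_positive`, `tiv_interaction`,
#'   `any_findings`.
#' @export
evaluate_recovery <- function(analysis, geometry, alpha = 0.05) {
  peak_in <- function(tab, roi, dir) {
    tab <- tab[tab$direction == dir, , drop = FALSE]
    nrow(tab) > 0 && any(roi[tab$peak_vox])
  }
  ti <- analysis$int_clusters$table
  tg <- analysis$gmv_clusters$table
  int_both <- peak_in(ti, geometry$int_rois$A, "group<") &&
    peak_in(ti, geometry$int_rois$B, "group<")
  gmv_dec <- peak_in(tg, geometry$gmv_rois$A, "group<") &&
    peak_in(tg, geometry$gmv_rois$B, "group<")
  gmv_inc <- peak_in(tg, geometry$gmv_rois$up, "group>")

  sig_pos <- function(co, index, roi_name) {
    if (is.null(co) || !nrow(co)) return(FALSE)
    # match clusters to the region by peak location
    tabg <- analysis$gmv_clusters$table
    hit <- which(geometry$gmv_rois[[roi_name]][tabg$peak_vox] &
                   tabg$direction == "group<")
    if (!length(hit)) return(FALSE)
    rows <- co[co$index == index &
                 co$region %in% paste0("cluster", hit), , drop = FALSE]
    any(!is.na(rows$q) & rows$q < alpha & rows$rho > 0)
  }
  wmi_ok <- sig_pos(analysis$correlations$gmv, "wmi", "A")
  pri_ok <- sig_pos(analysis$correlations$gmv, "pri", "B")
  tiv_ok <- {
    tr <- analysis$trend
    any(tr$measure == "tiv_ml" & tr$q < alpha)
  }
  any_corr <- any(vapply(analysis$correlations, function(co)
    !is.null(co) && any(!is.na(co$q) & co$q < alpha), logical(1)))
  any_findings <- nrow(ti) > 0 || nrow(tg) > 0 || any_corr ||
    any(analysis$trend$q < alpha)
  list(int_both_rois = int_both, gmv_decrease = gmv_dec,
       gmv_increase = gmv_inc, wmi_positive = wmi_ok,
       pri_positive = pri_ok, tiv_interaction = tiv_ok,
       any_findings = any_findings)
}
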