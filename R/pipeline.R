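#' Group-level analysis of an assembled cohort
#'
#' Runs the full statistical stage on per-subject maps: voxel-wise
#' two-sample GLMs with covariates for the timescale (z maps) and
#' gray-matter modalities, random-field cluster correction in both
#' directions, cohort tables (Levene-gated t-tests), group x age trend
#' models with FDR over the four global volumes, and the Spearman
#' structure-cognition screen over significant-cluster means (patients
#' only, BH family = clusters x 5 indices per modality).
#'
#' @param cohort a `synth_cohort` from [simulate_cohort()], or any list
#'   with the same fields (`int_z`, `gmv`, `covariates`, `geometry`,
#'   `group`).
#' @param voxel_p,cluster_p,min_size,connectivity cluster-inference
#'   thresholds (defaults 0.001, 0.05, 22 voxels, 18).
#' @param include_tiv_int include TIV among the timescale-model
#'   covariates (default TRUE; it is always included for gray matter).
#' @param alpha_levene Levene gate level for the cohort table.
#' @param atlas optional `atlas_labels` on the BOLD grid for network
#'   assignment of timescale clusters.
#' @return A `cohort_analysis`: `int_clusters`, `gmv_clusters`
#'   (`cluster_set`s), `table1`, `trend`, `correlations`
#'   (list int/gmv), `int_fit`, `gmv_fit`.
#' @export
analyze_cohort <- function(cohort, voxel_p = 0.001, cluster_p = 0.05,
                           min_size = 22L, connectivity = 18L,
                           include_tiv_int = TRUE, alpha_levene = 0.05,
                           atlas = NULL) {
  cov <- cohort$covariates
  geom <- cohort$geometry

  des_int <- group_design(cov, include_tiv = include_tiv_int)
  fit_int <- voxel_glm(cohort$int_z, des_int$X, des_int$contrast,
                       geom$bold_mask)
  cl_int <- extract_clusters(fit_int, voxel_p, cluster_p, min_size,
                             "both", connectivity, atlas = atlas)

  des_gmv <- group_design(cov, include_tiv = TRUE)
  fit_gmv <- voxel_glm(cohort$gmv, des_gmv$X, des_gmv$contrast,
                       geom$gmv_mask)
  cl_gmv <- extract_clusters(fit_gmv, voxel_p, cluster_p, min_size,
                             "both", connectivity)

  vols <- intersect(c("tiv_ml", "gm_ml", "wm_ml", "csf_ml"), names(cov))
  wisc <- intersect(c("fsiq", "vci", "pri", "wmi", "psi"), names(cov))
  table1 <- cohort_table(cov, c(wisc, vols), alpha_levene)
  trend <- fit_group_age_trend(cov, vols)

  pat <- cov$group == "patient"
  corr <- list()
  for (mod in c("int", "gmv")) {
    cl <- if (mod == "int") cl_int else cl_gmv
    if (nrow(cl$table) == 0 || !length(wisc)) {
      corr[[mod]] <- NULL
      next
    }
    cm <- t(cl$means)[pat, , drop = FALSE]
    colnames(cm) <- paste0("cluster", seq_len(ncol(cm)))
    corr[[mod]] <- spearman_screen(cm, cov[pat, wisc, drop = FALSE])
  }

  structure(list(int_clusters = cl_int, gmv_clusters = cl_gmv,
                 table1 = table1, trend = trend, correlations = corr,
                 int_fit = fit_int, gmv_fit = fit_gmv,
                 thresholds = list(voxel_p = voxel_p,
                                   cluster_p = cluster_p,
                                   min_size = min_size,
                                   connectivity = connectivity,
                                   include_tiv_int = include_tiv_int,
                                   alpha_levene = alpha_levene)),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("cohort_analysis\n")
  cat("-- timescale clusters --\n"); print(x$int_clusters)
  cat("-- gray-matter clusters --\n"); print(x$gmv_clusters)
  cat("-- group x age interaction --\n")
  tr <- x$trend
  tr$interaction <- round(tr$interaction, 2)
  tr$interaction_p <- signif(tr$interaction_p, 3)
  tr$q <- signif(tr$q, 3)
  print(tr[, c("measure", "interaction", "interaction_p", "q")],
        row.names = FALSE)
  for (mod in names(x$correlations)) {
    co <- x$correlations[[mod]]
    sig <- co[!is.na(co$q) & co$q < 0.05, , drop = FALSE]
    cat("-- ", mod, " correlations with q < 0.05: ", nrow(sig), "\n",
        sep = "")
  }
  invisible(x)
}

#' Load a cohort directory into analysis-ready form
#'
#' Reads the file layout written by [write_cohort()] (or assembled by
#' hand to the same convention), runs the single-subject timescale
#' pipeline on every BOLD run, applies the head-motion exclusion rule,
#' and returns the same structure [simulate_cohort()] produces.
#'
#' @param dir cohort directory.
#' @param n_drop,fwhm_mm,include_lag0,band preprocessing parameters.
#' @param trans_limit_mm,rot_limit_deg motion-exclusion limits.
#' @param verbose print progress.
#' @return A `synth_cohort`-shaped list (with `excluded` subject ids, if
#'   any).
#' @export
load_cohort <- function(dir, n_drop = 10L, fwhm_mm = 6,
                        include_lag0 = TRUE, band = c(0.01, 0.08),
                        trans_limit_mm = 2.5, rot_limit_deg = 2.5,
                        verbose = FALSE) {
  cov <- read_covariates(file.path(dir, "covariates.tsv"))
  mask <- read_volume(file.path(dir, "bold_mask.nii.gz"))
  bold_mask <- brain_mask(mask$grid, mask$data > 0.5)
  gmask <- read_volume(file.path(dir, "gmv_mask.nii.gz"))
  gmv_mask <- brain_mask(gmask$grid, gmask$data > 0.5)
  wm <- csf <- NULL
  if (file.exists(file.path(dir, "wm_mask.nii.gz"))) {
    w <- read_volume(file.path(dir, "wm_mask.nii.gz"))
    wm <- brain_mask(w$grid, w$data > 0.5)
  }
  if (file.exists(file.path(dir, "csf_mask.nii.gz"))) {
    w <- read_volume(file.path(dir, "csf_mask.nii.gz"))
    csf <- brain_mask(w$grid, w$data > 0.5)
  }
  n <- nrow(cov)
  bidx <- which(bold_mask$data)
  gidx <- which(gmv_mask$data)
  int_z <- int_raw <- matrix(NA_real_, length(bidx), n)
  gmv <- matrix(NA_real_, length(gidx), n)
  keep <- rep(TRUE, n)
  mean_fd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sid <- cov$subject_id[i]
    bold <- read_bold(file.path(dir, "bold", paste0(sid, ".nii.gz")))
    mot <- read_motion(file.path(dir, "motion", paste0(sid, ".txt")))
    excl <- motion_exclusion(mot, trans_limit_mm, rot_limit_deg)
    if (excl$exclude) {
      keep[i] <- FALSE
      if (verbose) message(sid, " excluded for motion")
      next
    }
    res <- int_subject_pipeline(bold, bold_mask, motion = mot,
                                wm_mask = wm, csf_mask = csf,
                                fwhm_mm = fwhm_mm,
                                include_lag0 = include_lag0,
                                n_drop = n_drop, band = band)
    int_z[, i] <- res$int_z$data[bidx]
    int_raw[, i] <- res$int_smoothed$data[bidx]
    mean_fd[i] <- res$mean_fd
    g <- read_volume(file.path(dir, "gmv", paste0(sid, ".nii.gz")), "gmv")
    stop_unless_same_grid(g$grid, gmv_mask$grid, "GMV maps")
    gmv[, i] <- g$data[gidx]
    if (verbose) message(sid, " done")
  }
  cov$mean_fd_mm <- ifelse(is.na(mean_fd), cov$mean_fd_mm, mean_fd)
  geom <- list(bold_mask = bold_mask, gmv_mask = gmv_mask,
               bold_grid = bold_mask$grid, gmv_grid = gmv_mask$grid)
  structure(list(geometry = geom, group = as.character(cov$group[keep]),
                 int_z = int_z[, keep, drop = FALSE],
                 int_raw = int_raw[, keep, drop = FALSE],
                 gmv = gmv[, keep, drop = FALSE],
                 covariates = cov[keep, , drop = FALSE],
                 excluded = cov$subject_id[!keep]),
            class = "synth_cohort")
}

.cluster_table_tsv <- function(cl, path) {
  tab <- cl$table
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' Run the full file-based pipeline
#'
#' Orchestrates the stages in dependency order on a cohort directory:
#' subject-level preprocessing and timescale mapping, voxel-wise group
#' inference for both modalities, cohort tables, trend models and
#' correlation screens, then writes the report tables (TSV), cluster
#' masks (NIfTI) and a run manifest recording every threshold used.
#'
#' @param cohort_dir input directory (layout of [write_cohort()]).
#' @param out_dir report directory (created; outputs are new files,
#'   inputs are never modified).
#' @param voxel_p,cluster_p,min_size,connectivity,fwhm_mm,include_lag0,
#'   n_drop,band,alpha_levene analysis parameters (defaults are the
#'   study's printed thresholds).
#' @param seed recorded in the manifest (the analysis stage itself is
#'   deterministic).
#' @param verbose print progress.
#' @return The `cohort_analysis`, invisibly.
#' @export
run_pipeline <- function(cohort_dir, out_dir,
                         voxel_p = 0.001, cluster_p = 0.05,
                         min_size = 22L, connectivity = 18L,
                         fwhm_mm = 6, include_lag0 = TRUE,
                         n_drop = 10L, band = c(0.01, 0.08),
                         alpha_levene = 0.05, seed = 1L,
                         verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort(cohort_dir, n_drop = n_drop, fwhm_mm = fwhm_mm,
                        include_lag0 = include_lag0, band = band,
                        verbose = verbose)
  atlas <- NULL
  ap <- file.path(cohort_dir, "atlas.nii.gz")
  an <- file.path(cohort_dir, "atlas_names.tsv")
  if (file.exists(ap) && file.exists(an)) {
    a <- read_volume(ap)
    atlas <- atlas_labels(a$grid, a$data, read_atlas_names(an))
  }
  res <- analyze_cohort(cohort, voxel_p, cluster_p, min_size,
                        connectivity, atlas = atlas,
                        alpha_levene = alpha_levene)
  .cluster_table_tsv(res$int_clusters, file.path(out_dir, "int_clusters.tsv"))
  .cluster_table_tsv(res$gmv_clusters, file.path(out_dir, "gmv_clusters.tsv"))
  utils::write.table(res$table1, file.path(out_dir, "table1.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$trend, file.path(out_dir, "trend.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (mod in names(res$correlations))
    utils::write.table(res$correlations[[mod]],
                       file.path(out_dir, paste0("correlations_", mod, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  for (k in seq_along(res$int_clusters$masks))
    .write_nifti(array(as.numeric(res$int_clusters$masks[[k]]),
                       dim = cohort$geometry$bold_grid$shape),
                 cohort$geometry$bold_grid,
                 file.path(out_dir, sprintf("int_cluster_%02d.nii.gz", k)))
  for (k in seq_along(res$gmv_clusters$masks))
    .write_nifti(array(as.numeric(res$gmv_clusters$masks[[k]]),
                       dim = cohort$geometry$gmv_grid$shape),
                 cohort$geometry$gmv_grid,
                 file.path(out_dir, sprintf("gmv_cluster_%02d.nii.gz", k)))
  manifest <- c(
    paste0("tool_version\t", as.character(utils::packageVersion("intmap"))),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("cohort_dir\t", normalizePath(cohort_dir)),
    paste0("covariates_md5\t",
           unname(tools::md5sum(file.path(cohort_dir, "covariates.tsv")))),
    paste0("seed\t", seed),
    paste0("voxel_p\t", voxel_p),
    paste0("cluster_p\t", cluster_p),
    paste0("min_size\t", min_size),
    paste0("connectivity\t", connectivity),
    paste0("fwhm_mm\t", fwhm_mm),
    paste0("include_lag0\t", include_lag0),
    paste0("n_drop\t", n_drop),
    paste0("band_hz\t", paste(band, collapse = "-")),
    paste0("alpha_levene\t", alpha_levene),
    paste0("excluded\t", paste(cohort$excluded, collapse = ",")))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(res)
}
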