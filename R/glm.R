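#' Build a two-group voxel-wise design
#'
#' Assembles the design matrix for the group comparison: intercept, group
#' indicator (patient = 1, control = 0), and the nuisance covariates age,
#' education years, corticosteroid months, mean FD, and (optionally,
#' default on) total intracranial volume. Steroid months for controls is
#' coded 0.
#'
#' @param covariates data.frame as returned by [read_covariates()].
#' @param include_tiv include TIV as a covariate (default TRUE; the GMV
#'   analysis always wants it, the timescale analysis keeps it by default).
#' @return list with `X` (n x p design), `contrast` (picks the group
#'   column), and `group` (0/1 vector).
#' @export
group_design <- function(covariates, include_tiv = TRUE) {
  g <- as.integer(covariates$group == "patient")
  ster <- covariates$steroid_months
  ster[is.na(ster)] <- 0
  X <- cbind(intercept = 1, group = g,
             age = covariates$age_years,
             education = covariates$education_years,
             steroid = ster,
             mean_fd = covariates$mean_fd_mm)
  if (include_tiv) X <- cbind(X, tiv = covariates$tiv_ml)
  contrast <- as.numeric(colnames(X) == "group")
  list(X = X, contrast = contrast, group = g)
}

#' Voxel-wise general linear model
#'
#' Fits the same OLS model at every in-mask voxel: response = subject
#' maps, design = `X`. The group comparison is the t statistic for
#' `contrast`: `t = c'b / sqrt(s2 * c'(X'X)^-1 c)`. Standardized
#' residual maps (each voxel's residual vector scaled to unit norm) are
#' retained for smoothness estimation. With no covariates and a group
#' contrast this reduces exactly to the pooled two-sample t-test.
#'
#' @param maps list of `voxel_map`s (one per subject, common grid), or a
#'   V x n matrix of in-mask values.
#' @param X n x p design matrix (full rank, n > p).
#' @param contrast length-p contrast vector.
#' @param mask a `brain_mask`.
#' @return A `voxel_glm` object: `tmap` (`voxel_map` of kind tstat),
#'   `df`, `beta`, `resid_std` (V x n), `Y` (V x n in-mask data), `X`,
#'   `contrast`, `mask`.
#' @export
voxel_glm <- function(maps, X, contrast, mask) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more subjects than design columns (n > p)")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (length(contrast) != p) stop("contrast length must equal ncol(X)")
  idx <- which(mask$data)
  if (is.matrix(maps)) {
    Y <- maps
    if (nrow(Y) != length(idx) || ncol(Y) != n)
      stop("matrix input must be n_mask_voxels x n_subjects")
  } else {
    if (length(maps) != n) stop("number of maps must match design rows")
    for (m in maps) stop_unless_same_grid(m$grid, mask$grid, "maps")
    Y <- vapply(maps, function(m) m$data[idx], numeric(length(idx)))
  }
  if (any(!is.finite(Y)))
    stop("non-finite in-mask values; tighten the mask")
  XtXi <- solve(crossprod(X))
  B <- Y %*% (X %*% XtXi)            # V x p coefficient estimates
  R <- Y - B %*% t(X)                # residuals
  rss <- rowSums(R^2)
  df <- n - p
  s2 <- rss / df
  vc <- drop(t(contrast) %*% XtXi %*% contrast)
  tvals <- drop(B %*% contrast) / sqrt(s2 * vc)
  tdat <- array(NaN, dim = mask$grid$shape)
  tdat[idx] <- tvals
  rs <- R / sqrt(pmax(rss, .Machine$double.eps))
  structure(list(tmap = voxel_map(mask$grid, tdat, kind = "tstat"),
                 df = df, beta = B, resid_std = rs, Y = Y, X = X,
                 contrast = contrast, mask = mask, n = n),
            class = "voxel_glm")
}

#' @export
print.voxel_glm <- function(x, ...) {
  tv <- x$tmap$data[x$mask$data]
  cat("voxel_glm: n =", x$n, ", df =", x$df, ",",
      length(tv), "in-mask voxels\n")
  cat(sprintf("  t range [%.3f, %.3f]\n", min(tv), max(tv)))
  invisible(x)
}

#' @export
summary.voxel_glm <- function(object, voxel_p = 0.001, ...) {
  tv <- object$tmap$data[object$mask$data]
  tcrit <- stats::qt(1 - voxel_p, object$df)
  out <- list(n = object$n, df = object$df, n_voxels = length(tv),
              t_range = range(tv), voxel_p = voxel_p, t_crit = tcrit,
              n_above = sum(tv > tcrit), n_below = sum(tv < -tcrit))
  class(out) <- "summary.voxel_glm"
  out
}

#' @export
print.summary.voxel_glm <- function(x, ...) {
  cat("Voxel-wise GLM: n =", x$n, ", residual df =", x$df, "\n")
  cat(sprintf("  %d in-mask voxels; t in [%.3f, %.3f]\n",
              x$n_voxels, x$t_range[1], x$t_range[2]))
  cat(sprintf("  one-sided p < %g (|t| > %.3f): %d positive, %d negative\n",
              x$voxel_p, x$t_crit, x$n_above, x$n_below))
  invisible(x)
}

#' Residual-based smoothness (FWHM / resel) estimate
#'
#' Estimates the spatial smoothness of the error field from the
#' standardized GLM residuals: for each axis, `lambda = ` mean over
#' in-mask neighbour pairs of the squared first difference summed over
#' subjects (each voxel's residual vector has unit norm, so `lambda =
#' 2 (1 - rho(1))` for spatial lag-1 correlation `rho`), and
#' `FWHM = sqrt(4 ln 2 / lambda)` voxels. Scale-invariant by
#' construction. The resel count is the in-mask volume divided by the
#' product of the per-axis FWHMs.
#'
#' @param resid_std V x n standardized residual matrix (from
#'   [voxel_glm()]), or a `voxel_glm` object.
#' @param mask a `brain_mask` (ignored when a `voxel_glm` is given).
#' @return A `smoothness_estimate`: `fwhm_mm`, `fwhm_vox`,
#'   `resels_per_voxel`, `resels`, `n_voxels`, `voxel_size`.
#' @export
estimate_smoothness <- function(resid_std, mask = NULL) {
  if (inherits(resid_std, "voxel_glm")) {
    mask <- resid_std$mask
    resid_std <- resid_std$resid_std
  }
  if (is.null(mask)) stop("mask required")
  if (ncol(resid_std) < 3L) stop("need at least 3 residual maps")
  # normalize each voxel's residual vector to unit norm; makes the
  # estimate invariant to the residual scale
  nrm <- sqrt(rowSums(resid_std^2))
  resid_std <- resid_std / ifelse(nrm > 0, nrm, 1)
  shape <- mask$grid$shape
  idx <- which(mask$data)
  vol <- array(NaN, dim = shape)
  lam <- numeric(3)
  for (a in 1:3) {
    # mean squared first difference along axis a over in-mask pairs
    num <- 0
    cnt <- 0
    for (j in seq_len(ncol(resid_std))) {
      vol[idx] <- resid_std[, j]
      d <- switch(a,
                  vol[-1, , , drop = FALSE] - vol[-shape[1], , , drop = FALSE],
                  vol[, -1, , drop = FALSE] - vol[, -shape[2], , drop = FALSE],
                  vol[, , -1, drop = FALSE] - vol[, , -shape[3], drop = FALSE])
      good <- is.finite(d)
      num <- num + sum(d[good]^2)
      cnt <- cnt + sum(good)
    }
    # cnt counts pair-map combinations; residual vectors have unit norm,
    # so dividing by pairs (cnt / n maps) gives the per-pair variance
    lam[a] <- num / (cnt / ncol(resid_std))
  }
  fwhm_vox <- sqrt(4 * log(2) / lam)
  low <- 0.5
  if (any(fwhm_vox < low)) {
    warning("smoothness below half a voxel on some axis; clamping")
    fwhm_vox <- pmax(fwhm_vox, low)
  }
  vs <- mask$grid$voxel_size
  fwhm_mm <- fwhm_vox * vs
  rpv <- prod(1 / fwhm_vox)
  structure(list(fwhm_mm = fwhm_mm, fwhm_vox = fwhm_vox,
                 resels_per_voxel = rpv,
                 resels = length(idx) * rpv,
                 n_voxels = length(idx), voxel_size = vs),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("smoothness: FWHM = [%s] mm; %d voxels; %.1f resels\n",
              paste(sprintf("%.2f", x$fwhm_mm), collapse = ", "),
              x$n_voxels, x$resels))
  invisible(x)
}

#' Random-field corrected cluster p-value
#'
#' Standard Gaussian random-field cluster-extent inference: the expected
#' number of clusters above the (Gaussianized) threshold `u` is
#' `E[m] = R * rho3(u)` with the 3D EC density
#' `rho3(u) = (4 ln 2)^{3/2} (2 pi)^{-2} (u^2 - 1) exp(-u^2 / 2)` and
#' `R` the search volume in resels; the expected suprathreshold voxel
#' count is `E[N] = S (1 - Phi(u))`; cluster extents follow the
#' exponentiated size model `P(n >= k) = exp(-beta k^{2/3})` with
#' `beta = (Gamma(5/2) E[m] / E[N])^{2/3}`; the corrected p is
#' `1 - exp(-E[m] P(n >= k))`. Extent 0 returns 1. For t statistic maps
#' the voxel threshold is Gaussianized via the probit of the voxel-level
#' p (adequate at the residual df used here; the permutation test is the
#' calibration guard).
#'
#' @param extent_voxels cluster size in voxels (>= 0).
#' @param smoothness a `smoothness_estimate`.
#' @param u cluster-forming threshold as an equivalent z value (> 1).
#' @return Corrected cluster-level probability in (0, 1].
#' @export
grf_cluster_p <- function(extent_voxels, smoothness, u) {
  stopifnot(extent_voxels >= 0, u > 1)
  if (!is.finite(smoothness$resels) || smoothness$resels <= 0)
    stop("degenerate smoothness estimate")
  if (extent_voxels == 0) return(1)
  rho3 <- (4 * log(2))^(3 / 2) * (2 * pi)^(-2) * (u^2 - 1) * exp(-u^2 / 2)
  Em <- smoothness$resels * rho3
  EN <- smoothness$n_voxels * stats::pnorm(u, lower.tail = FALSE)
  beta <- (gamma(5 / 2) * Em / EN)^(2 / 3)
  Pk <- exp(-beta * extent_voxels^(2 / 3))
  min(1, 1 - exp(-Em * Pk))
}

.connectivity_offsets <- function(connectivity = 18L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1,
                 "18" = s >= 1 & s <= 2,
                 "26" = s >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3D binary array
#'
#' Flood-fill labelling under 6-, 18- (default, face + edge) or
#' 26-connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background), with
#'   attribute `"sizes"` (voxels per label).
#' @export
label_components <- function(mask, connectivity = 18L) {
  mask <- as.array(mask)
  dims <- dim(mask)
  labels <- array(0L, dim = dims)
  vox <- which(mask)
  if (!length(vox)) {
    attr(labels, "sizes") <- integer(0)
    return(labels)
  }
  off <- .connectivity_offsets(connectivity)
  stride <- c(1L, dims[1], dims[1] * dims[2])
  loff <- as.integer(off %*% stride)
  coords <- arrayInd(vox, dims)
  inmask <- logical(prod(dims))
  inmask[vox] <- TRUE
  cur <- 0L
  sizes <- integer(0)
  for (v in vox) {
    if (labels[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    labels[v] <- cur
    count <- 0L
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      count <- count + 1L
      qc <- arrayInd(q, dims)
      nb <- q + loff
      nc <- cbind(qc[1] + off[, 1], qc[2] + off[, 2], qc[3] + off[, 3])
      okb <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
        nc[, 2] >= 1 & nc[, 2] <= dims[2] &
        nc[, 3] >= 1 & nc[, 3] <= dims[3]
      nb <- nb[okb]
      nb <- nb[inmask[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    sizes[cur] <- count
  }
  attr(labels, "sizes") <- sizes
  labels
}

#' Extract significant clusters from a voxel-wise GLM
#'
#' Thresholds the t map one-sidedly at the voxel-level p quantile for the
#' model's df, labels connected components (18-connectivity by default),
#' drops components smaller than `min_size`, attaches the random-field
#' corrected cluster p ([grf_cluster_p()]) computed with the residual
#' smoothness, and keeps clusters with corrected p below
#' `cluster_p`. Both filters apply: a cluster must reach `min_size`
#' voxels *and* the corrected significance level. An empty result is a
#' valid outcome.
#'
#' @param fit a `voxel_glm`.
#' @param voxel_p one-sided voxel-level threshold (default 0.001).
#' @param cluster_p corrected cluster-level threshold (default 0.05).
#' @param min_size minimum cluster extent in voxels (default 22).
#' @param direction `"neg"` (patient < control for a +1 group contrast),
#'   `"pos"`, or `"both"` (runs each side separately and concatenates).
#' @param connectivity 6, 18 or 26.
#' @param smoothness optional precomputed `smoothness_estimate`.
#' @param atlas optional `atlas_labels` for network assignment.
#' @return A `cluster_set`: data.frame `table` (one row per cluster:
#'   direction, size, peak t, peak MNI mm, cluster p, network) plus
#'   `masks` (list of logical arrays), `means` (per-subject cluster
#'   means, clusters x n), `smoothness`, and the thresholds used.
#' @export
extract_clusters <- function(fit, voxel_p = 0.001, cluster_p = 0.05,
                             min_size = 22L,
                             direction = c("both", "neg", "pos"),
                             connectivity = 18L, smoothness = NULL,
                             atlas = NULL) {
  direction <- match.arg(direction)
  if (direction == "both") {
    neg <- extract_clusters(fit, voxel_p, cluster_p, min_size, "neg",
                            connectivity, smoothness, atlas)
    pos <- extract_clusters(fit, voxel_p, cluster_p, min_size, "pos",
                            connectivity, smoothness, atlas)
    return(.bind_cluster_sets(neg, pos))
  }
  if (is.null(smoothness)) smoothness <- estimate_smoothness(fit)
  tcrit <- stats::qt(1 - voxel_p, fit$df)
  u <- stats::qnorm(1 - voxel_p)
  tdat <- fit$tmap$data
  supra <- if (direction == "pos") tdat > tcrit else tdat < -tcrit
  supra[!is.finite(tdat)] <- FALSE
  labels <- label_components(supra, connectivity)
  sizes <- attr(labels, "sizes")
  keep <- which(sizes >= min_size)
  rows <- list()
  masks <- list()
  means <- NULL
  idx <- which(fit$mask$data)
  for (k in keep) {
    p <- grf_cluster_p(sizes[k], smoothness, u)
    if (p >= cluster_p) next
    cm <- labels == k
    vox <- which(cm)
    tv <- tdat[vox]
    pk <- vox[which.max(abs(tv))]
    mni <- drop(voxel_to_mm(fit$mask$grid, arrayInd(pk, dim(tdat))))
    net <- if (!is.null(atlas)) label_cluster_network(cm, atlas)$name
           else NA_character_
    cmean <- colMeans(fit$Y[match(vox, idx), , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      direction = if (direction == "neg") "group<" else "group>",
      size_voxels = sizes[k], peak_t = tdat[pk],
      peak_x_mm = mni[1], peak_y_mm = mni[2], peak_z_mm = mni[3],
      cluster_p = p, network = net, peak_vox = pk,
      stringsAsFactors = FALSE)
    masks[[length(masks) + 1L]] <- cm
    means <- rbind(means, cmean)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(), size_voxels = integer(),
               peak_t = numeric(), peak_x_mm = numeric(),
               peak_y_mm = numeric(), peak_z_mm = numeric(),
               cluster_p = numeric(), network = character(),
               peak_vox = integer(), stringsAsFactors = FALSE)
  if (nrow(tab)) {
    o <- order(-tab$size_voxels)
    tab <- tab[o, , drop = FALSE]
    masks <- masks[o]
    means <- means[o, , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, masks = masks, means = means,
                 smoothness = smoothness,
                 thresholds = list(voxel_p = voxel_p,
                                   cluster_p = cluster_p,
                                   min_size = min_size,
                                   connectivity = connectivity)),
            class = "cluster_set")
}

.bind_cluster_sets <- function(a, b) {
  structure(list(table = rbind(a$table, b$table),
                 masks = c(a$masks, b$masks),
                 means = rbind(a$means, b$means),
                 smoothness = a$smoothness,
                 thresholds = a$thresholds),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf(
    "cluster_set: %d cluster(s) (voxel p < %g, cluster p < %g, >= %d voxels, %d-connectivity)\n",
    nrow(x$table), th$voxel_p, th$cluster_p, th$min_size, th$connectivity))
  if (nrow(x$table)) {
    tab <- x$table
    tab$peak_vox <- NULL
    tab$cluster_p <- signif(tab$cluster_p, 3)
    tab$peak_t <- round(tab$peak_t, 2)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Permutation cluster-extent test
#'
#' Group-label permutation null for cluster extent: for each permutation
#' the group column of the design is shuffled, the voxel-wise GLM refit
#' with all covariates, the t map thresholded exactly as in
#' [extract_clusters()], and the maximum component size recorded. The
#' empirical corrected p for an observed cluster of size k is
#' `(1 + #\{null max >= k\}) / (n_perm + 1)`. Seeded and reproducible.
#'
#' @param fit a `voxel_glm` whose design contains a `group` column.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @param voxel_p one-sided voxel-level threshold.
#' @param direction `"neg"` or `"pos"` (matching the observed contrast
#'   side).
#' @param connectivity 6, 18 or 26.
#' @param observed_sizes integer vector of observed cluster extents to
#'   score (e.g. `cluster_set$table$size_voxels`).
#' @return list with `p` (per observed cluster), `null_max_sizes`
#'   (length `n_perm`), `n_perm`.
#' @export
permutation_cluster_test <- function(fit, n_perm = 499L, seed = 1L,
                                     voxel_p = 0.001,
                                     direction = c("neg", "pos"),
                                     connectivity = 18L,
                                     observed_sizes = integer(0)) {
  direction <- match.arg(direction)
  if (n_perm < 100L) stop("need at least 100 permutations")
  gcol <- which(colnames(fit$X) == "group")
  if (!length(gcol)) stop("design has no 'group' column")
  X <- fit$X
  Y <- fit$Y
  contrast <- fit$contrast
  tcrit <- stats::qt(1 - voxel_p, fit$df)
  shape <- fit$mask$grid$shape
  idx <- which(fit$mask$data)
  vol <- array(FALSE, dim = shape)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nullmax <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    Xp <- X
    Xp[, gcol] <- X[sample.int(nrow(X)), gcol]
    XtXi <- tryCatch(solve(crossprod(Xp)), error = function(e) NULL)
    if (is.null(XtXi)) { nullmax[b] <- 0L; next }
    B <- Y %*% (Xp %*% XtXi)
    R <- Y - B %*% t(Xp)
    s2 <- rowSums(R^2) / fit$df
    vc <- drop(t(contrast) %*% XtXi %*% contrast)
    tv <- drop(B %*% contrast) / sqrt(s2 * vc)
    supra <- if (direction == "pos") tv > tcrit else tv < -tcrit
    if (!any(supra)) { nullmax[b] <- 0L; next }
    vol[] <- FALSE
    vol[idx[supra]] <- TRUE
    sizes <- attr(label_components(vol, connectivity), "sizes")
    nullmax[b] <- max(sizes)
  }
  p <- vapply(observed_sizes, function(k)
    (1 + sum(nullmax >= k)) / (n_perm + 1), numeric(1))
  list(p = p, null_max_sizes = nullmax, n_perm = n_perm)
}
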