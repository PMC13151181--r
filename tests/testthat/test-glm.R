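make_maps <- function(Y, grid) {
  lapply(seq_len(ncol(Y)), function(i)
    voxel_map(grid, array(Y[, i], grid$shape)))
}

test_that("group-only GLM equals the pooled two-sample t-test", {
  set.seed(31)
  n1 <- 7; n2 <- 6; V <- 24
  grid <- centered_grid(c(2, 3, 4), 3)
  mask <- brain_mask(grid, array(TRUE, c(2, 3, 4)))
  Y <- matrix(rnorm(V * (n1 + n2)), V)
  g <- rep(c(1, 0), c(n1, n2))
  X <- cbind(intercept = 1, group = g)
  fit <- voxel_glm(Y, X, c(0, 1), mask)
  for (v in c(1, 9, 24)) {
    tt <- t.test(Y[v, g == 1], Y[v, g == 0], var.equal = TRUE)
    expect_equal(fit$tmap$data[v], unname(tt$statistic), tolerance = 1e-10)
  }
  expect_equal(fit$df, n1 + n2 - 2)
})

test_that("voxel-wise GLM matches the brute-force OLS oracle", {
  set.seed(32)
  n <- 20; V <- 40
  grid <- centered_grid(c(4, 5, 2), 3)
  mask <- brain_mask(grid, array(TRUE, c(4, 5, 2)))
  X <- cbind(1, rep(0:1, each = 10), rnorm(n), rnorm(n), rnorm(n))
  colnames(X) <- c("intercept", "group", "age", "education", "mean_fd")
  ctr <- c(0, 1, 0, 0, 0)
  Y <- matrix(rnorm(V * n), V)
  fit <- voxel_glm(Y, X, ctr, mask)
  XtXi <- solve(t(X) %*% X)
  for (v in seq_len(V)) {
    b <- XtXi %*% t(X) %*% Y[v, ]
    res <- Y[v, ] - X %*% b
    s2 <- sum(res^2) / (n - ncol(X))
    tv <- drop(t(ctr) %*% b) / sqrt(s2 * drop(t(ctr) %*% XtXi %*% ctr))
    expect_equal(fit$tmap$data[v], tv, tolerance = 1e-8)
  }
  # adding a constant to every subject's map changes no t value
  fit2 <- voxel_glm(Y + 100, X, ctr, mask)
  expect_equal(fit2$tmap$data, fit$tmap$data, tolerance = 1e-8)
  # guard rails
  expect_error(voxel_glm(Y, X[, c(1, 1, 2:5)], c(0, 0, 1, 0, 0, 0), mask),
               "rank")
  expect_error(voxel_glm(Y[, 1:4], X[1:4, ], ctr, mask), "n > p")
})

test_that("null permutation t-values behave like the t distribution", {
  set.seed(33)
  n <- 20; V <- 10
  grid <- centered_grid(c(2, 5, 1), 3)
  mask <- brain_mask(grid, array(TRUE, c(2, 5, 1)))
  Y <- matrix(rnorm(V * n), V)
  g0 <- rep(0:1, each = 10)
  tv <- replicate(500, {
    X <- cbind(intercept = 1, group = sample(g0))
    voxel_glm(Y, X, c(0, 1), mask)$tmap$data[3]
  })
  df <- n - 2
  expect_lt(abs(mean(tv)), 0.15)
  expect_lt(abs(sd(tv) - sqrt(df / (df - 2))), 0.2)
})

test_that("smoothness estimation recovers the applied kernel", {
  set.seed(34)
  shape <- c(40, 40, 40)
  grid <- centered_grid(shape, 3)
  mask <- brain_mask(grid, array(TRUE, shape))
  nmaps <- 6
  R <- vapply(seq_len(nmaps), function(i)
    as.vector(smooth_map(voxel_map(grid,
      array(rnorm(prod(shape)), shape)), 6)$data), numeric(prod(shape)))
  est <- estimate_smoothness(R, mask)
  # target: combined smoothness of the 6 mm kernel and the lattice's
  # intrinsic white-noise smoothness sqrt(4 ln 2 / 2) voxels (= 3.53 mm)
  intrinsic <- sqrt(4 * log(2) / 2) * 3
  target <- sqrt(6^2 + intrinsic^2)
  expect_lt(max(abs(est$fwhm_mm - target) / target), 0.15)
  # unsmoothed white noise: close to the voxel size
  R0 <- matrix(rnorm(prod(shape) * 3), ncol = 3)
  est0 <- estimate_smoothness(R0, mask)
  expect_lt(max(abs(est0$fwhm_mm - 3) / 3), 0.25)
  # scale invariance
  est7 <- estimate_smoothness(7 * R, mask)
  expect_equal(est7$fwhm_mm, est$fwhm_mm, tolerance = 1e-10)
  expect_error(estimate_smoothness(R[, 1:2], mask), "at least 3")
})

test_that("corrected cluster p is monotone and handles extent 0", {
  sm <- structure(list(fwhm_mm = c(6, 6, 6), fwhm_vox = c(2, 2, 2),
                       resels_per_voxel = 1 / 8, resels = 27000 / 8,
                       n_voxels = 27000, voxel_size = c(3, 3, 3)),
                  class = "smoothness_estimate")
  u <- qnorm(1 - 0.001)
  expect_equal(grf_cluster_p(0, sm, u), 1)
  p <- vapply(c(1, 5, 10, 20, 40, 80), grf_cluster_p, numeric(1),
              smoothness = sm, u = u)
  expect_true(all(diff(p) < 0))
  # larger search volume -> larger p at fixed extent
  sm2 <- sm; sm2$resels <- sm$resels * 4; sm2$n_voxels <- sm$n_voxels * 4
  expect_gt(grf_cluster_p(20, sm2, u), grf_cluster_p(20, sm, u))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("component labelling respects the connectivity scheme", {
  a <- array(FALSE, c(6, 6, 6))
  a[2, 2, 2] <- TRUE
  a[3, 3, 3] <- TRUE            # touches only at a corner
  l18 <- label_components(a, 18)
  expect_equal(length(attr(l18, "sizes")), 2)
  l26 <- label_components(a, 26)
  expect_equal(length(attr(l26, "sizes")), 1)
  b <- array(FALSE, c(6, 6, 6))
  b[2, 2, 2] <- TRUE
  b[3, 3, 2] <- TRUE            # edge neighbour
  expect_equal(length(attr(label_components(b, 18), "sizes")), 1)
  expect_equal(length(attr(label_components(b, 6), "sizes")), 2)
  # sizes count every member voxel
  c3 <- array(FALSE, c(6, 6, 6)); c3[2:4, 3, 3] <- TRUE
  expect_equal(attr(label_components(c3, 6), "sizes"), 3L)
})

fake_fit_with_blob <- function(blob_voxels, shape = c(12, 12, 12),
                               tblob = 6, df = 59) {
  grid <- centered_grid(shape, 3)
  mask <- brain_mask(grid, array(TRUE, shape))
  tdat <- array(0, shape)
  tdat[blob_voxels] <- tblob
  n <- df + 2
  Y <- matrix(rnorm(prod(shape) * n), ncol = n)
  structure(list(tmap = voxel_map(grid, tdat, kind = "tstat"), df = df,
                 Y = Y, mask = mask,
                 X = cbind(intercept = 1, group = rep(0:1, length.out = n)),
                 contrast = c(0, 1), n = n,
                 resid_std = Y / sqrt(rowSums(Y^2))),
            class = "voxel_glm")
}

test_that("minimum-cluster-size filter has an exact 22-voxel boundary", {
  # hand-built supra-threshold blob of exactly 22 voxels
  a <- array(FALSE, c(12, 12, 12))
  a[4:6, 4:6, 4] <- TRUE        # 9
  a[4:6, 4:6, 5] <- TRUE        # 18
  a[4:5, 4:5, 6] <- TRUE        # 22
  expect_equal(sum(a), 22)
  fit <- fake_fit_with_blob(which(a))
  sm <- estimate_smoothness(fit)
  cl22 <- extract_clusters(fit, min_size = 22, direction = "pos",
                           smoothness = sm)
  expect_equal(nrow(cl22$table), 1)
  expect_equal(cl22$table$size_voxels, 22)
  cl23 <- extract_clusters(fit, min_size = 23, direction = "pos",
                           smoothness = sm)
  expect_equal(nrow(cl23$table), 0)
  # 21-voxel blob fails a min_size of 22
  a[4, 4, 6] <- FALSE
  fit21 <- fake_fit_with_blob(which(a))
  cl21 <- extract_clusters(fit21, min_size = 22, direction = "pos",
                           smoothness = sm)
  expect_equal(nrow(cl21$table), 0)
})

test_that("cluster extraction reports peaks in mm and subject means", {
  set.seed(36)
  shape <- c(10, 10, 10)
  grid <- centered_grid(shape, 3)
  mask <- brain_mask(grid, array(TRUE, shape))
  n <- 30
  g <- rep(0:1, each = 15)
  blob <- array(FALSE, shape); blob[3:5, 3:5, 3:5] <- TRUE
  Y <- matrix(rnorm(prod(shape) * n, sd = 0.3), ncol = n)
  Y[which(blob), g == 1] <- Y[which(blob), g == 1] + 3
  X <- cbind(intercept = 1, group = g)
  fit <- voxel_glm(Y, X, c(0, 1), mask)
  cl <- extract_clusters(fit, direction = "pos", min_size = 10)
  expect_equal(nrow(cl$table), 1)
  expect_true(blob[cl$table$peak_vox])
  # per-subject means separate the groups by about the planted shift
  mns <- cl$means[1, ]
  expect_gt(mean(mns[g == 1]) - mean(mns[g == 0]), 2)
  # peak mm maps back to the peak voxel through the affine
  ijk <- arrayInd(cl$table$peak_vox, shape)
  expect_equal(unname(as.vector(voxel_to_mm(grid, ijk))),
               c(cl$table$peak_x_mm, cl$table$peak_y_mm,
                 cl$table$peak_z_mm))
})

test_that("permutation test is seeded and uses the add-one rule", {
  set.seed(37)
  shape <- c(8, 8, 8)
  grid <- centered_grid(shape, 3)
  mask <- brain_mask(grid, array(TRUE, shape))
  n <- 24
  g <- rep(0:1, each = 12)
  blob <- array(FALSE, shape); blob[3:5, 3:5, 3:5] <- TRUE
  Y <- matrix(rnorm(prod(shape) * n, sd = 0.3), ncol = n)
  Y[which(blob), g == 1] <- Y[which(blob), g == 1] + 4
  X <- cbind(intercept = 1, group = g)
  fit <- voxel_glm(Y, X, c(0, 1), mask)
  p1 <- permutation_cluster_test(fit, n_perm = 100, seed = 9,
                                 direction = "pos",
                                 observed_sizes = c(27L))
  p2 <- permutation_cluster_test(fit, n_perm = 100, seed = 9,
                                 direction = "pos",
                                 observed_sizes = c(27L))
  expect_identical(p1$null_max_sizes, p2$null_max_sizes)
  expect_equal(p1$p, p2$p)
  # observed larger than every null maximum -> (1 + 0) / (n_perm + 1)
  expect_equal(p1$p, (1 + sum(p1$null_max_sizes >= 27)) / 101)
  expect_error(permutation_cluster_test(fit, n_perm = 50, seed = 1),
               "100")
})
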