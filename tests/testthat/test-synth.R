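test_that("BOLD generation is reproducible and hits the target lag-1", {
  cfg <- synth_config(bold_shape = c(8L, 9L, 8L), gmv_shape = c(8L, 9L, 8L),
                      n_volumes = 60L)
  geom <- synth_geometry(cfg)
  a <- generate_bold(cfg, 3, "patient", 11, geom)
  b <- generate_bold(cfg, 3, "patient", 11, geom)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(cbind(a$motion$trans, a$motion$rot),
                   cbind(b$motion$trans, b$motion$rot))
  c <- generate_bold(cfg, 4, "patient", 11, geom)
  expect_false(identical(a$bold$data, c$bold$data))

  # long-run lag-1 autocorrelation of an effect-region patient voxel
  # (phi 0.65 - 0.2 = 0.45)
  cfg2 <- synth_config(bold_shape = c(8L, 9L, 8L),
                       gmv_shape = c(8L, 9L, 8L), n_volumes = 10000L,
                       drift_amplitude = 0)
  geom2 <- synth_geometry(cfg2)
  sb <- generate_bold(cfg2, 1, "patient", 13, geom2)
  vox <- which(geom2$int_rois$A & geom2$bold_mask$data)[1]
  ijk <- arrayInd(vox, cfg2$bold_shape)
  x <- sb$bold$data[ijk[1], ijk[2], ijk[3], ]
  expect_lt(abs(acf_biased(x, 1)$rho[2] - 0.45), 0.02)
})

test_that("zero-phi cohorts give timescales near TR", {
  cfg <- synth_config(bold_shape = c(8L, 9L, 8L), gmv_shape = c(8L, 9L, 8L),
                      n_volumes = 500L, phi_sensory = 0, phi_association = 0,
                      phi_roi = 0, phi_delta = 0, drift_amplitude = 0)
  geom <- synth_geometry(cfg)
  sb <- generate_bold(cfg, 1, "control", 17, geom)
  m <- compute_int_map(sb$bold, geom$bold_mask)
  expect_lt(abs(mean(m$data[geom$bold_mask$data]) - cfg$tr), 0.1 * cfg$tr)
})

test_that("motion traces stay below the exclusion limits", {
  cfg <- synth_config(bold_shape = c(8L, 9L, 8L), gmv_shape = c(8L, 9L, 8L),
                      n_volumes = 200L)
  geom <- synth_geometry(cfg)
  for (i in 1:5) {
    sb <- generate_bold(cfg, i, "control", 19, geom)
    expect_false(motion_exclusion(sb$motion)$exclude)
  }
})

test_that("gray-matter maps are clipped and carry the planted shift", {
  cfg <- synth_config(gmv_shape = c(24L, 28L, 24L),
                      bold_shape = c(8L, 9L, 8L))
  geom <- synth_geometry(cfg)
  g <- generate_gmv(cfg, 1, "patient", 23, geom)
  expect_true(all(g$data >= 0 & g$data <= 1))
  expect_identical(g$data, generate_gmv(cfg, 1, "patient", 23, geom)$data)

  # with the default shift, the region-mean two-sample t is strongly
  # negative in nearly every seed; with no shift it stays modest
  roi_t <- function(config, seed) {
    geo <- synth_geometry(config)
    n <- 36 + 30
    grp <- rep(c("patient", "control"), c(36, 30))
    roi <- geo$gmv_rois$A & geo$gmv_mask$data
    mns <- vapply(seq_len(n), function(i)
      mean(generate_gmv(config, i, grp[i], seed, geo)$data[roi]),
      numeric(1))
    unname(t.test(mns[grp == "patient"], mns[grp == "control"],
                  var.equal = TRUE)$statistic)
  }
  t_eff <- vapply(1:4, function(s) roi_t(cfg, s), numeric(1))
  expect_gte(sum(t_eff < -5), 3)
  cfg0 <- null_config(cfg)
  t_null <- vapply(1:4, function(s) roi_t(cfg0, s), numeric(1))
  expect_gte(sum(abs(t_null) < 3), 3)
})

test_that("covariate tables respect ranges, groups and couplings", {
  cfg <- synth_config()
  tab <- generate_tables(cfg, seed = 29)
  expect_equal(nrow(tab), 66)
  expect_true(all(tab$age_years >= 5 & tab$age_years <= 14))
  expect_true(all(tab$steroid_months[tab$group == "control"] == 0))
  expect_true(all(tab$steroid_months[tab$group == "patient"] > 0))
  wisc <- c("fsiq", "vci", "pri", "wmi", "psi")
  expect_true(all(as.matrix(tab[, wisc]) >= 40 &
                    as.matrix(tab[, wisc]) <= 160))

  # planted slopes are detected; uncoupled cognition is not
  hits <- 0; null_hits <- 0
  for (s in 1:10) {
    tb <- generate_tables(cfg, seed = 300 + s)
    tr <- fit_group_age_trend(tb, c("tiv_ml", "gm_ml", "wm_ml", "csf_ml"))
    if (tr$q[tr$measure == "tiv_ml"] < 0.05) hits <- hits + 1
    tb0 <- generate_tables(null_config(cfg), seed = 400 + s)
    scr <- spearman_screen(
      data.frame(A = rnorm(66, sd = 0.02), B = rnorm(66, sd = 0.02)),
      tb0[, wisc])
    if (!any(!is.na(scr$q) & scr$q < 0.05)) null_hits <- null_hits + 1
  }
  expect_gte(hits, 9)
  expect_gte(null_hits, 8)
})

test_that("matched null configuration removes every planted effect", {
  cfg <- synth_config()
  cfg0 <- null_config(cfg)
  expect_equal(cfg0$phi_delta, 0)
  expect_equal(cfg0$gmv_delta, 0)
  expect_equal(cfg0$wmi_coupling, 0)
  expect_equal(cfg0$pri_coupling, 0)
  for (m in names(cfg0$vol_params))
    expect_equal(cfg0$vol_params[[m]]$pat[2], cfg0$vol_params[[m]]$ctl[2])
  geom <- synth_geometry(cfg0)
  expect_identical(geom$phi_patient, geom$phi_control)
})

test_that("region timescales approach the closed form as runs lengthen", {
  cfg_T <- function(T) synth_config(bold_shape = c(8L, 9L, 8L),
                                    gmv_shape = c(8L, 9L, 8L),
                                    n_volumes = T, drift_amplitude = 0)
  truth <- 2 * (1 + 0.65 / (1 - 0.65))
  roi_mean <- function(T, subjects) {
    cfg <- cfg_T(T)
    geom <- synth_geometry(cfg)
    roi <- geom$int_rois$A & geom$bold_mask$data
    mean(vapply(subjects, function(s) {
      sb <- generate_bold(cfg, s, "control", 31, geom)
      mean(compute_int_map(sb$bold, geom$bold_mask)$data[roi])
    }, numeric(1)))
  }
  short <- roi_mean(100L, 1:3)
  long <- roi_mean(4000L, 1L)
  expect_lt(abs(long - truth) / truth, 0.05)
  expect_lt(short, long)        # truncation shortens short runs
})

test_that("child seeds are stable and within the integer range", {
  expect_identical(child_seed(7, 3, 1), child_seed(7, 3, 1))
  expect_false(child_seed(7, 3, 1) == child_seed(7, 4, 1))
  expect_false(child_seed(7, 3, 1) == child_seed(8, 3, 1))
  s <- vapply(1:100, function(i) child_seed(123456, i, 2), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_equal(length(unique(s)), 100)
})
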