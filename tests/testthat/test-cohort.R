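test_that("summary t-tests reproduce the published volumetric statistics", {
  # printed group summaries (mean, SD, n): patients then controls
  tiv <- t_from_summary(1580.12, 112.04, 36, 1468.19, 110.20, 30, "pooled")
  gm <- t_from_summary(804.78, 68.39, 36, 786.23, 49.14, 30, "pooled")
  wm <- t_from_summary(508.33, 45.22, 36, 468.83, 46.35, 30, "pooled")
  csf <- t_from_summary(270.53, 68.73, 36, 213.13, 35.55, 30, "welch")
  expect_equal(tiv$t, 4.071, tolerance = 0.002)
  expect_equal(gm$t, 1.241, tolerance = 0.002)
  expect_equal(wm$t, 3.494, tolerance = 0.002)
  expect_equal(csf$t, 4.360, tolerance = 0.002)
  expect_equal(tiv$df, 64)
  expect_lt(csf$df, 64)          # Satterthwaite df below pooled
  # equal means -> t = 0, p = 1
  z <- t_from_summary(5, 1, 10, 5, 1, 12)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
})

test_that("summary t equals the textbook statistic on raw samples", {
  set.seed(41)
  x <- rnorm(14, 3, 2); y <- rnorm(11, 2, 2)
  ts <- t_from_summary(mean(x), sd(x), 14, mean(y), sd(y), 11, "pooled")
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(ts$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ts$p, tt$p.value, tolerance = 1e-10)
  tw <- t_from_summary(mean(x), sd(x), 14, mean(y), sd(y), 11, "welch")
  tt2 <- t.test(x, y)
  expect_equal(tw$t, unname(tt2$statistic), tolerance = 1e-10)
  expect_equal(tw$df, unname(tt2$parameter), tolerance = 1e-10)
})

test_that("the Levene gate picks pooled vs Welch appropriately", {
  set.seed(42)
  x <- rnorm(30); y <- rnorm(25)
  r <- levene_gated_t(x, y)
  expect_equal(r$variant, "pooled")
  rs <- t_from_summary(mean(x), sd(x), 30, mean(y), sd(y), 25, "pooled")
  expect_equal(r$t, rs$t, tolerance = 1e-10)
  # inflate one variance tenfold: the gate switches to Welch
  y10 <- y * sqrt(10)
  r10 <- levene_gated_t(x, y10)
  expect_equal(r10$variant, "welch")
  expect_lt(r10$levene_p, 0.05)
  # antisymmetry under group swap
  rba <- levene_gated_t(y10, x)
  expect_equal(rba$t, -r10$t, tolerance = 1e-10)
  expect_equal(rba$p, r10$p, tolerance = 1e-10)
  expect_error(levene_gated_t(rep(1, 5), y), "degenerate")
})

test_that("noiseless group trends give the exact interaction", {
  age <- rep(seq(6, 14, by = 1), 2)
  grp <- rep(c("control", "patient"), each = 9)
  val <- ifelse(grp == "control", 100 + 5 * age, 300 - 3 * age)
  rec <- data.frame(group = grp, age_years = age, vol = val)
  # perfect fit triggers an lm summary note; the exact estimate is the point
  tr <- suppressWarnings(fit_group_age_trend(rec, "vol"))
  expect_equal(tr$interaction, -8.0, tolerance = 1e-10)
  expect_equal(tr$slope_control, 5, tolerance = 1e-10)
  expect_equal(tr$slope_patient, -3, tolerance = 1e-10)
})

test_that("interaction test holds its type-I error under the null", {
  set.seed(43)
  rejections <- 0
  for (b in 1:200) {
    age <- runif(66, 5, 14)
    grp <- rep(c("patient", "control"), c(36, 30))
    val <- 1000 + 7 * age + rnorm(66, sd = 40)   # identical slopes
    rec <- data.frame(group = grp, age_years = age, vol = val)
    tr <- fit_group_age_trend(rec, "vol")
    if (tr$interaction_p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 200, 0.02)
  expect_lte(rejections / 200, 0.09)
})

test_that("BH adjustment matches the definitional oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      j <- which(o == i)    # rank of p[i]
      q[i] <- min(1, min(m * p[o[j:m]] / (j:m)))
    }
    q
  }
  set.seed(44)
  for (rep in 1:20) {
    p <- runif(sample(3:12, 1))^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone: ordering of q follows ordering of p
  p <- runif(8)
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1 & q >= p))
})

test_that("Spearman screen matches the rank-then-Pearson oracle", {
  x <- c(1, 4, 2, 2, 7, 9, 9, 3)       # ties on purpose
  y <- c(2, 3, 3, 5, 8, 1, 4, 4)
  out <- spearman_screen(data.frame(r1 = x), data.frame(i1 = y))
  oracle <- cor(rank(x), rank(y))       # average ranks, then Pearson
  expect_equal(out$rho, oracle, tolerance = 1e-12)
  n <- length(x)
  toracle <- oracle * sqrt((n - 2) / (1 - oracle^2))
  expect_equal(out$p, 2 * pt(-abs(toracle), n - 2), tolerance = 1e-12)
  # perfect monotone pairs
  up <- spearman_screen(data.frame(r = 1:10), data.frame(i = (1:10)^3))
  expect_equal(up$rho, 1)
  dn <- spearman_screen(data.frame(r = 1:10), data.frame(i = -(1:10)^3))
  expect_equal(dn$rho, -1)
})

test_that("Spearman screen handles missing data and degenerate columns", {
  set.seed(45)
  cm <- data.frame(r1 = rnorm(12), r2 = rnorm(12))
  sc <- data.frame(i1 = rnorm(12), i2 = rep(3, 12))
  sc$i1[1:3] <- NA
  out <- spearman_screen(cm, sc)
  expect_equal(nrow(out), 4)           # full region x index family
  expect_equal(out$n[out$index == "i1"], c(9L, 9L))
  expect_true(all(is.na(out$rho[out$index == "i2"])))  # constant index
  expect_true(all(is.na(out$q[out$index == "i2"])))
  # q over the family never drops below p
  ok <- !is.na(out$p)
  expect_true(all(out$q[ok] >= out$p[ok] - 1e-15))
})

test_that("cohort table reports the gated test per measure", {
  cfg <- synth_config(n_patient = 20, n_control = 18)
  rec <- generate_tables(cfg, seed = 8)
  tab <- cohort_table(rec, c("tiv_ml", "fsiq"))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$variant %in% c("pooled", "welch")))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  # t sign follows patient minus control
  expect_equal(sign(tab$t[tab$measure == "tiv_ml"]),
               sign(tab$patient_mean[1] - tab$control_mean[1]))
})
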