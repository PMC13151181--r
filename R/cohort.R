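#' Two-sample t statistic from summary data
#'
#' Reconstructs the two-sample t-test from printed means, SDs and group
#' sizes. Pooled: `sp2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`,
#' `t = (m1-m2) / (sp sqrt(1/n1 + 1/n2))`, df = n1+n2-2. Welch:
#' `t = (m1-m2) / sqrt(s1^2/n1 + s2^2/n2)` with Satterthwaite df.
#' Two-tailed p from the t distribution.
#'
#' @param mean1,sd1,n1 first group summary (e.g. patients).
#' @param mean2,sd2,n2 second group summary.
#' @param variant `"pooled"` or `"welch"`.
#' @return A `t_test_result`: list with `t`, `df`, `p`, `variant`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 variant = variant, levene_p = NA_real_),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("two-sample t (%s): t = %.3f, df = %.2f, p = %.4g\n",
              x$variant, x$t, x$df, x$p))
  if (is.finite(x$levene_p))
    cat(sprintf("  Levene p = %.4g (gate)\n", x$levene_p))
  invisible(x)
}

#' Levene-gated two-sample t-test
#'
#' Reproduces the SPSS reporting convention: Levene's test for equality
#' of variances (on absolute deviations from the group means) decides
#' between the pooled test (Levene p > `alpha_levene`) and the Welch
#' test (otherwise).
#'
#' @param sample1,sample2 numeric vectors (each n >= 2, nonzero
#'   variance).
#' @param alpha_levene gate level (default 0.05).
#' @return A `t_test_result` with the gate's `levene_p` filled in.
#' @export
levene_gated_t <- function(sample1, sample2, alpha_levene = 0.05) {
  x <- as.numeric(sample1)
  y <- as.numeric(sample2)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) sample")
  vals <- c(x, y)
  grp <- factor(rep(c("a", "b"), c(length(x), length(y))))
  lev <- car::leveneTest(vals, grp, center = mean)
  lev_p <- lev[["Pr(>F)"]][1]
  variant <- if (lev_p > alpha_levene) "pooled" else "welch"
  tt <- stats::t.test(x, y, var.equal = variant == "pooled")
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, variant = variant, levene_p = lev_p),
            class = "t_test_result")
}

#' Group x age interaction models for global volumetrics
#'
#' Fits, per measure, the OLS model `value ~ group + age + group:age`
#' (control is the reference level) and tests the interaction
#' coefficient two-tailed; interaction p-values are
#' Benjamini-Hochberg-adjusted across the measure family. Optionally a
#' quadratic pre-step first fits `value ~ group*age + age^2 +
#' group:age^2`; if every quadratic term in every measure has p >
#' `quad_alpha` the quadratic terms are dropped (the default model),
#' otherwise they are retained and flagged.
#'
#' @param records data.frame with columns `group` (factor control /
#'   patient), `age_years`, and the measure columns.
#' @param measures character vector of measure column names (the BH
#'   family; 4 in the intended use: TIV, GM, WM, CSF).
#' @param quadratic_screen run the quadratic pre-step (default FALSE;
#'   the reported model is the linear one).
#' @param quad_alpha removal threshold for the quadratic terms.
#' @return A `trend_result` data.frame: per measure the interaction
#'   estimate, p, BH q, per-group slopes, and whether quadratic terms
#'   were retained.
#' @export
fit_group_age_trend <- function(records, measures,
                                quadratic_screen = FALSE,
                                quad_alpha = 0.05) {
  records$group <- factor(records$group, levels = c("control", "patient"))
  for (g in levels(records$group))
    if (length(unique(records$age_years[records$group == g])) < 3L)
      stop("each group must span at least 3 distinct ages")
  quad_kept <- FALSE
  if (quadratic_screen) {
    qp <- unlist(lapply(measures, function(m) {
      f <- stats::as.formula(paste(m,
        "~ group * age_years + I(age_years^2) + group:I(age_years^2)"))
      cf <- summary(stats::lm(f, data = records))$coefficients
      rows <- grep("age_years\\^2", rownames(cf))
      cf[rows, "Pr(>|t|)"]
    }))
    quad_kept <- any(qp <= quad_alpha)
  }
  rows <- lapply(measures, function(m) {
    f <- if (quad_kept)
      stats::as.formula(paste(m,
        "~ group * age_years + I(age_years^2) + group:I(age_years^2)"))
    else stats::as.formula(paste(m, "~ group * age_years"))
    fit <- stats::lm(f, data = records)
    cf <- summary(fit)$coefficients
    irow <- "grouppatient:age_years"
    data.frame(measure = m,
               interaction = cf[irow, "Estimate"],
               interaction_p = cf[irow, "Pr(>|t|)"],
               slope_control = cf["age_years", "Estimate"],
               slope_patient = cf["age_years", "Estimate"] +
                 cf[irow, "Estimate"],
               quadratic = quad_kept,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$interaction_p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("trend_result", class(out))
  out
}

#' Spearman structure-cognition screen
#'
#' Computes average-rank Spearman correlations between every region
#' (cluster-mean) column and every cognitive index column, with p-values
#' from the t approximation `t = rho sqrt((n-2) / (1-rho^2))` on n-2 df,
#' and BH-FDR adjustment over the whole (region x index) family.
#' Pairs are handled pairwise-complete; cells with fewer than `min_n`
#' complete pairs, or with a constant vector, are reported with NA rho.
#'
#' @param cluster_means data.frame/matrix, subjects x regions.
#' @param scores data.frame/matrix, subjects x cognitive indices
#'   (same subject order).
#' @param min_n minimum complete pairs per cell (default 5).
#' @return A `correlation_result` data.frame: region, index, n, rho, p,
#'   q.
#' @export
spearman_screen <- function(cluster_means, scores, min_n = 5L) {
  cm <- as.data.frame(cluster_means)
  sc <- as.data.frame(scores)
  if (nrow(cm) != nrow(sc))
    stop("cluster_means and scores must have the same subjects")
  grid <- expand.grid(region = colnames(cm), index = colnames(sc),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- cm[[grid$region[i]]]
    y <- sc[[grid$index[i]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(region = grid$region[i], index = grid$index[i],
                        n = n, rho = NA_real_, p = NA_real_))
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    p <- if (abs(rho) >= 1) 0 else {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(t), n - 2)
    }
    data.frame(region = grid$region[i], index = grid$index[i],
               n = n, rho = rho, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  rownames(out) <- NULL
  class(out) <- c("correlation_result", class(out))
  out
}

#' Table-1-style cohort comparison
#'
#' Runs [levene_gated_t()] patient-vs-control for each requested
#' measure and returns a summary table with group means/SDs and the
#' gated test.
#'
#' @param records covariate data.frame (see [read_covariates()]).
#' @param measures measure column names.
#' @param alpha_levene Levene gate level.
#' @return data.frame: measure, group means/SDs, t, df, p, variant.
#' @export
cohort_table <- function(records, measures, alpha_levene = 0.05) {
  pat <- records[records$group == "patient", , drop = FALSE]
  ctl <- records[records$group == "control", , drop = FALSE]
  rows <- lapply(measures, function(m) {
    x <- pat[[m]]
    y <- ctl[[m]]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    tt <- levene_gated_t(x, y, alpha_levene)
    data.frame(measure = m,
               patient_mean = mean(x), patient_sd = stats::sd(x),
               control_mean = mean(y), control_sd = stats::sd(y),
               t = tt$t, df = tt$df, p = tt$p, variant = tt$variant,
               levene_p = tt$levene_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
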