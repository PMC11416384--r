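# Heterogeneity and pleiotropy diagnostics gating reported associations.

#' Cochran's Q heterogeneity test
#'
#' Q = sum_j w_j (beta_j - beta_IVW)^2 over the per-SNP Wald ratios with
#' inverse-variance weights; under homogeneity Q ~ chi-square with J - 1
#' degrees of freedom. P-values above 0.05 are conventionally read as no
#' heterogeneity.
#'
#' By default the weights use the second-order Wald-ratio variance
#' (propagating uncertainty in the SNP-exposure effects as well as the
#' SNP-outcome effects). With first-order weights Q is systematically
#' inflated whenever the causal effect is non-negligible -- the expected
#' Q/(J-1) is about 1 + beta^2 sigma_X^2/sigma_Y^2 even without any
#' heterogeneity -- so a first-order Q gate would spuriously discard
#' strong true effects; second-order weights restore E\[Q/(J-1)\] = 1 on
#' homogeneous data. Set `second_order = FALSE` for the plain first-order
#' statistic.
#'
#' @param pair a [harmonize()]d pair with >= 2 SNPs.
#' @param beta_ivw optional pooled estimate; defaults to the fixed-effect
#'   IVW mean of the ratios (under the same weights).
#' @param second_order use second-order Wald-ratio variances (default).
#' @return List with `q_stat`, `df`, `pval`.
#' @export
cochran_q <- function(pair, beta_ivw = NULL, second_order = TRUE) {
  wr <- pair_ratios(pair, second_order = second_order)
  J <- nrow(wr)
  if (J < 2L) stop("Cochran's Q requires at least 2 SNPs", call. = FALSE)
  w <- 1 / wr$se^2
  if (is.null(beta_ivw)) beta_ivw <- sum(w * wr$estimate) / sum(w)
  q <- sum(w * (wr$estimate - beta_ivw)^2)
  df <- J - 1L
  list(q_stat = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept component of [mr_egger()] exposed as a gate: a nonzero
#' intercept estimates the average direct (pleiotropic) effect of the
#' instruments on the outcome.
#'
#' @param pair a [harmonize()]d pair with >= 3 SNPs.
#' @return List with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(pair) {
  fit <- mr_egger(pair)
  list(intercept = fit$intercept, se = fit$intercept_se,
       pval = fit$intercept_pval)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect J times, each time excluding one SNP, to
#' expose single variants that drive the pooled estimate.
#'
#' @param pair a [harmonize()]d pair with >= 3 SNPs.
#' @param variant IVW variant for the re-estimates (see [mr_ivw()]).
#' @return data.frame with one row per excluded SNP: `excluded_rsid`,
#'   `beta`, `se`, `pval`.
#' @export
leave_one_out <- function(pair, variant = "mre") {
  d <- pair$data
  J <- nrow(d)
  if (J < 3L) stop("leave-one-out requires at least 3 SNPs", call. = FALSE)
  rows <- lapply(seq_len(J), function(j) {
    sub <- pair
    sub$data <- d[-j, , drop = FALSE]
    est <- mr_ivw(sub, variant)
    data.frame(excluded_rsid = d$rsid[j], beta = est$beta, se = est$se,
               pval = est$pval)
  })
  do.call(rbind, rows)
}

# IVW (origin-constrained WLS) slope with weights 1/sy^2 from raw arrays.
ivw_slope <- function(g, G, sy2) sum(g * G / sy2) / sum(g^2 / sy2)

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of horizontal pleiotropy. The observed
#' residual sum of squares uses leave-one-out IVW slopes:
#' RSS_obs = sum_j w_j (Gamma_j - beta_(-j) gamma_j)^2 with
#' w_j = 1/sigma_Yj^2. A parametric null redraws both effect arrays from
#' their sampling distributions around the leave-one-out fitted values;
#' the global p-value is the plus-one empirical tail probability
#' (1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1), so its smallest reportable
#' value is 1/(n_sim + 1). Per-SNP outlier p-values compare each SNP's
#' observed residual contribution with its simulated distribution and are
#' Bonferroni-adjusted over J; SNPs below `outlier_alpha` are outliers.
#' When outliers exist, a distortion test compares the outlier-removed
#' slope with the all-SNP slope against the distribution obtained by
#' removing equally many SNPs at random, and an outlier-corrected IVW
#' estimate is returned.
#'
#' @param pair a [harmonize()]d pair with >= 4 SNPs.
#' @param n_sim simulated null datasets (>= 100; default 1000).
#' @param seed RNG seed.
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   outlier test (default 0.05).
#' @return List of class `mr_presso` with `global_pval`, `rss_obs`,
#'   `outlier_ids`, `outlier_pvals` (adjusted, named by rsid),
#'   `distortion_pval`, and `corrected` (an `mr_estimate`, or `NULL` when
#'   no outliers are found).
#' @export
mr_presso <- function(pair, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  d <- pair$data
  J <- nrow(d)
  if (J < 4L) stop("MR-PRESSO requires at least 4 SNPs", call. = FALSE)
  if (n_sim < 100) stop("`n_sim` must be >= 100", call. = FALSE)
  g <- d$gamma_hat; sx <- d$sigma_x
  G <- d$Gamma_hat; sy <- d$sigma_y
  sy2 <- sy^2
  w <- 1 / sy2

  # leave-one-out IVW slopes via totals
  s1 <- sum(g * G / sy2); s2 <- sum(g^2 / sy2)
  beta_loo <- (s1 - g * G / sy2) / (s2 - g^2 / sy2)
  rss_j <- w * (G - beta_loo * g)^2
  rss_obs <- sum(rss_j)

  with_seed(seed, {
    Gs <- matrix(stats::rnorm(n_sim * J, rep(beta_loo * g, each = n_sim),
                              rep(sy, each = n_sim)), n_sim, J)
    gs <- matrix(stats::rnorm(n_sim * J, rep(g, each = n_sim),
                              rep(sx, each = n_sim)), n_sim, J)
    W <- matrix(w, n_sim, J, byrow = TRUE)
    S1 <- (gs * Gs) %*% w
    S2 <- (gs^2) %*% w
    beta_loo_sim <- (as.vector(S1) - t(t(gs * Gs) * w)) /
      (as.vector(S2) - t(t(gs^2) * w))
    rss_sim_j <- W * (Gs - beta_loo_sim * gs)^2
    rss_sim <- rowSums(rss_sim_j)

    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

    # per-SNP outlier test: plain empirical fraction (no plus-one), so a
    # Bonferroni-adjusted zero count can still reject at feasible n_sim
    p_out <- colMeans(rss_sim_j >= rep(rss_j, each = n_sim))
    p_adj <- pmin(1, p_out * J)
    names(p_adj) <- d$rsid
    outliers <- d$rsid[p_adj < outlier_alpha]

    distortion_pval <- NA_real_
    corrected <- NULL
    if (length(outliers) > 0 && length(outliers) < J - 1L) {
      keep <- !(d$rsid %in% outliers)
      beta_all <- ivw_slope(g, G, sy2)
      beta_out <- ivw_slope(g[keep], G[keep], sy2[keep])
      d_obs <- beta_out - beta_all
      n_o <- sum(!keep)
      d_sim <- vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(J, n_o)
        ivw_slope(g[-drop], G[-drop], sy2[-drop]) - beta_all
      }, numeric(1))
      distortion_pval <- mean(abs(d_sim) >= abs(d_obs))
      sub <- pair
      sub$data <- d[keep, , drop = FALSE]
      corrected <- mr_ivw(sub, "mre")
    }

    structure(
      list(global_pval = global_pval, rss_obs = rss_obs,
           outlier_ids = outliers, outlier_pvals = p_adj,
           distortion_pval = distortion_pval, corrected = corrected,
           n_sim = n_sim),
      class = "mr_presso")
  })
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> global p=%.4g; %d outlier(s)%s\n",
              x$global_pval, length(x$outlier_ids),
              if (length(x$outlier_ids))
                sprintf(" [%s]; distortion p=%.3g",
                        paste(x$outlier_ids, collapse = ", "),
                        x$distortion_pval) else ""))
  invisible(x)
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, MR-PRESSO and the
#' leave-one-out table, with the gating flags used by the screening rules:
#' `heterogeneous` when the Q p-value is below `alpha`, `pleiotropic` when
#' the Egger-intercept or MR-PRESSO global p-value is.
#'
#' @param pair a [harmonize()]d pair with >= 4 SNPs.
#' @param n_sim MR-PRESSO null simulations.
#' @param seed RNG seed.
#' @param alpha gate threshold (default 0.05).
#' @return List of class `sensitivity_report`.
#' @export
sensitivity_report <- function(pair, n_sim = 1000, seed = 1, alpha = 0.05) {
  q <- cochran_q(pair)
  eg <- egger_intercept_test(pair)
  pr <- mr_presso(pair, n_sim = n_sim, seed = seed, outlier_alpha = alpha)
  loo <- leave_one_out(pair)
  structure(
    list(q_stat = q$q_stat, q_df = q$df, q_pval = q$pval,
         egger_intercept = eg$intercept, egger_intercept_se = eg$se,
         egger_intercept_pval = eg$pval,
         presso_global_pval = pr$global_pval,
         presso_outlier_ids = pr$outlier_ids,
         presso_distortion_pval = pr$distortion_pval,
         loo_table = loo,
         heterogeneous = q$pval < alpha,
         pleiotropic = eg$pval < alpha || pr$global_pval < alpha,
         alpha = alpha),
    class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_report> Q=%.2f (df=%d, p=%.3g); Egger intercept=%.4f (p=%.3g); PRESSO global p=%.3g; %s%s\n",
    x$q_stat, x$q_df, x$q_pval, x$egger_intercept, x$egger_intercept_pval,
    x$presso_global_pval,
    if (x$heterogeneous) "HETEROGENEOUS " else "",
    if (x$pleiotropic) "PLEIOTROPIC" else "clean"))
  invisible(x)
}
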