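# Point estimators of the causal effect from harmonized summary data.

new_mr_estimate <- function(method, beta, se, pval, n_snp, extra = list()) {
  or <- to_odds_ratio(beta, se)
  structure(
    c(list(method = method, beta = beta, se = se, pval = pval,
           n_snp = as.integer(n_snp),
           or_value = or$or_value, ci_low = or$ci_low, ci_high = or$ci_high),
      extra),
    class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta=%.4f se=%.4f p=%.3g OR=%.3f [%.3f, %.3f] (%d SNPs)\n",
              x$method, x$beta, x$se, x$pval, x$or_value, x$ci_low, x$ci_high,
              x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snp, beta = x$beta, se = x$se,
             pval = x$pval, or = x$or_value, ci_low = x$ci_low,
             ci_high = x$ci_high)
}

#' Convert a log odds ratio and SE to an odds ratio with 95% CI
#'
#' @param beta causal estimate on the log-odds scale.
#' @param se its standard error (> 0).
#' @return List with `or_value`, `ci_low`, `ci_high` where
#'   `or = exp(beta)` and the CI is `exp(beta -/+ 1.959964 * se)`.
#' @export
to_odds_ratio <- function(beta, se) {
  if (any(se <= 0)) stop("`se` must be > 0", call. = FALSE)
  list(or_value = exp(beta), ci_low = exp(beta - Z975 * se),
       ci_high = exp(beta + Z975 * se))
}

#' Per-SNP Wald ratio estimates
#'
#' The single-instrument causal estimate: SNP-outcome effect divided by
#' SNP-exposure effect, with the first-order delta-method standard error
#' sigma_Y / |gamma_hat|. `second_order = TRUE` adds the term propagating
#' uncertainty in the SNP-exposure effect:
#' sqrt(sigma_Y^2/gamma^2 + Gamma^2 sigma_X^2 / gamma^4).
#'
#' @param gamma_hat SNP-exposure effect(s); must be nonzero.
#' @param sigma_x SNP-exposure standard error(s).
#' @param Gamma_hat SNP-outcome effect(s).
#' @param sigma_y SNP-outcome standard error(s).
#' @param second_order use the second-order SE approximation.
#' @return data.frame with columns `estimate` and `se`.
#' @export
wald_ratio <- function(gamma_hat, sigma_x, Gamma_hat, sigma_y,
                       second_order = FALSE) {
  if (any(gamma_hat == 0)) {
    stop("Wald ratio undefined: `gamma_hat` contains zero", call. = FALSE)
  }
  est <- Gamma_hat / gamma_hat
  se <- if (second_order) {
    sqrt(sigma_y^2 / gamma_hat^2 + Gamma_hat^2 * sigma_x^2 / gamma_hat^4)
  } else {
    sigma_y / abs(gamma_hat)
  }
  data.frame(estimate = est, se = se)
}

# Wald ratios of a harmonized pair (internal).
pair_ratios <- function(pair, second_order = FALSE) {
  with(pair$data,
       wald_ratio(gamma_hat, sigma_x, Gamma_hat, sigma_y, second_order))
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analysis of the per-SNP Wald ratios with weights 1/se^2,
#' algebraically identical to weighted least squares of the SNP-outcome on
#' the SNP-exposure effects through the origin with weights 1/sigma_Y^2.
#' The multiplicative-random-effects variant (the common package default,
#' reported here as the headline) scales the fixed-effect standard error by
#' sqrt(max(1, Q/(J-1))), where Q is Cochran's heterogeneity statistic.
#'
#' @param pair a [harmonize()]d pair with >= 2 SNPs.
#' @param variant `"mre"` (multiplicative random effects) or `"fe"`
#'   (fixed effect).
#' @return An `mr_estimate` (method `ivw_mre` or `ivw_fe`) with the
#'   heterogeneity statistic in `$q_stat`.
#' @export
mr_ivw <- function(pair, variant = c("mre", "fe")) {
  variant <- match.arg(variant)
  wr <- pair_ratios(pair)
  J <- nrow(wr)
  if (J < 2L) stop("IVW requires at least 2 SNPs", call. = FALSE)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$estimate) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  q <- sum(w * (wr$estimate - beta)^2)
  se <- if (variant == "mre") se_fe * sqrt(max(1, q / (J - 1))) else se_fe
  new_mr_estimate(paste0("ivw_", variant), beta, se, pval_z(beta, se), J,
                  extra = list(q_stat = q, se_fe = se_fe))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome effects on the
#' SNP-exposure effects with a free intercept and weights 1/sigma_Y^2,
#' after orienting all SNP-exposure effects to be non-negative (required
#' for the intercept to estimate average directional pleiotropy). The
#' slope is the causal estimate; standard errors carry a multiplicative
#' overdispersion factor floored at 1, and p-values use the t distribution
#' with J - 2 degrees of freedom.
#'
#' @param pair a [harmonize()]d pair with >= 3 SNPs.
#' @return An `mr_estimate` (method `egger`) with `$intercept`,
#'   `$intercept_se`, `$intercept_pval`.
#' @export
mr_egger <- function(pair) {
  d <- pair$data
  J <- nrow(d)
  if (J < 3L) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  flip <- sign(d$gamma_hat)
  flip[flip == 0] <- 1
  g <- d$gamma_hat * flip
  G <- d$Gamma_hat * flip
  if (stats::var(g) == 0) {
    stop("MR-Egger undefined: no variation in SNP-exposure effects",
         call. = FALSE)
  }
  fit <- stats::lm(G ~ g, weights = 1 / d$sigma_y^2)
  sm <- summary(fit)
  sigma <- sm$sigma
  # lm SEs already include sigma; rescale so the dispersion factor is
  # max(1, sigma): under-dispersion never shrinks the SEs.
  scale <- max(1, sigma) / sigma
  co <- sm$coefficients
  slope <- co["g", "Estimate"]
  slope_se <- co["g", "Std. Error"] * scale
  inter <- co["(Intercept)", "Estimate"]
  inter_se <- co["(Intercept)", "Std. Error"] * scale
  df <- J - 2L
  new_mr_estimate(
    "egger", slope, slope_se,
    2 * stats::pt(-abs(slope / slope_se), df), J,
    extra = list(intercept = inter, intercept_se = inter_se,
                 intercept_pval = 2 * stats::pt(-abs(inter / inter_se), df),
                 df = df))
}

# Weighted median of values x with weights w: orders x, forms cumulative
# weight midpoints s_j = cumsum(w)_j - w_j/2 (w normalized), and linearly
# interpolates the value at s = 1/2.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(x[1L])
  if (0.5 >= s[length(s)]) return(x[length(s)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Consistent when SNPs carrying at least half of the inverse-variance
#' weight are valid instruments. The point estimate interpolates the
#' weighted median of the Wald ratios; the standard error comes from a
#' parametric bootstrap that redraws the SNP-exposure and SNP-outcome
#' effects from their sampling distributions.
#'
#' @param pair a [harmonize()]d pair with >= 2 SNPs.
#' @param n_boot bootstrap resamples for the SE (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate` (method `weighted_median`).
#' @export
mr_weighted_median <- function(pair, n_boot = 1000, seed = 1) {
  d <- pair$data
  J <- nrow(d)
  if (J < 2L) stop("weighted median requires at least 2 SNPs", call. = FALSE)
  wr <- pair_ratios(pair)
  w <- 1 / wr$se^2
  beta <- weighted_median_point(wr$estimate, w)
  se <- with_seed(seed, {
    boot <- vapply(seq_len(n_boot), function(i) {
      g <- stats::rnorm(J, d$gamma_hat, d$sigma_x)
      G <- stats::rnorm(J, d$Gamma_hat, d$sigma_y)
      g[g == 0] <- .Machine$double.eps
      r <- G / g
      weighted_median_point(r, g^2 / d$sigma_y^2)
    }, numeric(1))
    stats::sd(boot)
  })
  new_mr_estimate("weighted_median", beta, se, pval_z(beta, se), J)
}

# Gaussian-kernel mode of ratios with weights, modified-Silverman
# bandwidth h = phi * 0.9 * min(sd, mad) * J^(-1/5), argmax on a grid of
# `grid_n` points spanning range(r) +/- 3h.
kernel_mode_point <- function(r, w, phi, grid_n = 512L) {
  s <- stats::sd(r)
  m <- stats::mad(r)
  spread <- min(s, if (m > 0) m else s)
  if (!is.finite(spread) || spread == 0) return(r[1L])
  h <- phi * 0.9 * spread * length(r)^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = grid_n)
  dens <- colSums((w / sum(w)) * stats::dnorm(outer(r, grid, "-") / h))
  grid[which.max(dens)]
}

#' Simple- and weighted-mode causal estimates
#'
#' Mode-based estimation: the causal effect is taken as the mode of the
#' smoothed empirical density of the Wald ratios, unweighted (simple mode)
#' or inverse-variance weighted (weighted mode). Consistent when the
#' largest cluster of SNPs is valid. Bandwidth is `phi` times the modified
#' Silverman rule; standard errors by parametric bootstrap.
#'
#' @param pair a [harmonize()]d pair with >= 3 SNPs.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param grid_n density-grid resolution (default 512).
#' @return List with elements `simple_mode` and `weighted_mode`, each an
#'   `mr_estimate`.
#' @export
mr_modes <- function(pair, phi = 1, n_boot = 1000, seed = 1, grid_n = 512L) {
  d <- pair$data
  J <- nrow(d)
  if (J < 3L) stop("mode estimators require at least 3 SNPs", call. = FALSE)
  wr <- pair_ratios(pair)
  w <- 1 / wr$se^2
  beta_s <- kernel_mode_point(wr$estimate, rep(1, J), phi, grid_n)
  beta_w <- kernel_mode_point(wr$estimate, w, phi, grid_n)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      g <- stats::rnorm(J, d$gamma_hat, d$sigma_x)
      G <- stats::rnorm(J, d$Gamma_hat, d$sigma_y)
      g[g == 0] <- .Machine$double.eps
      r <- G / g
      wb <- g^2 / d$sigma_y^2
      c(kernel_mode_point(r, rep(1, J), phi, grid_n),
        kernel_mode_point(r, wb, phi, grid_n))
    }, numeric(2))
  })
  se_s <- stats::sd(boots[1L, ])
  se_w <- stats::sd(boots[2L, ])
  list(
    simple_mode = new_mr_estimate("simple_mode", beta_s, se_s,
                                  pval_z(beta_s, se_s), J),
    weighted_mode = new_mr_estimate("weighted_mode", beta_w, se_w,
                                    pval_z(beta_w, se_w), J))
}

#' Run the full estimator suite on one harmonized pair
#'
#' Computes multiplicative-random-effects and fixed-effect IVW, MR-Egger,
#' weighted median, simple and weighted mode, and the Bayesian weighted
#' estimator, and returns them as a tidy table (one row per method) --
#' the machine-readable analogue of a forest-plot block.
#'
#' @param pair a [harmonize()]d pair.
#' @param n_boot bootstrap resamples for median/mode SEs.
#' @param seed RNG seed for bootstraps.
#' @param phi mode bandwidth multiplier.
#' @return data.frame with columns exposure, outcome, method, nsnp, beta,
#'   se, pval, or, ci_low, ci_high.
#' @export
mr_all_methods <- function(pair, n_boot = 1000, seed = 1, phi = 1) {
  ests <- list(mr_ivw(pair, "mre"), mr_ivw(pair, "fe"))
  J <- nrow(pair$data)
  if (J >= 3L) {
    modes <- mr_modes(pair, phi = phi, n_boot = n_boot, seed = seed)
    ests <- c(ests, list(
      mr_egger(pair),
      mr_weighted_median(pair, n_boot = n_boot, seed = seed),
      modes$simple_mode, modes$weighted_mode,
      fit_bwmr(pair)))
  } else {
    ests <- c(ests, list(mr_weighted_median(pair, n_boot = n_boot, seed = seed)))
  }
  tab <- do.call(rbind, lapply(ests, as.data.frame))
  cbind(exposure = pair$exposure_id, outcome = pair$outcome_id, tab)
}
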