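# Two-step MR mediation: product-of-coefficients decomposition with
# delta-method uncertainty.

#' Product-method indirect effect
#'
#' The indirect (mediated) effect of two-step MR: the product of the
#' exposure-to-mediator effect `a` and the mediator-to-outcome effect `b`.
#'
#' @param a,b path coefficients.
#' @return `a * b`.
#' @export
product_effect <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  a * b
}

#' Delta-method standard error of a product of estimates
#'
#' First-order: sqrt(a^2 se_b^2 + b^2 se_a^2). The second-order variant
#' adds se_a^2 se_b^2 under the root (always at least as large).
#'
#' @param a,se_a first estimate and its SE (se_a >= 0).
#' @param b,se_b second estimate and its SE (se_b >= 0).
#' @param order `"first"` (default) or `"second"`.
#' @return Standard error of `a * b`.
#' @export
delta_se_product <- function(a, se_a, b, se_b, order = c("first", "second")) {
  order <- match.arg(order)
  if (se_a < 0 || se_b < 0) stop("standard errors must be >= 0", call. = FALSE)
  v <- a^2 * se_b^2 + b^2 * se_a^2
  if (order == "second") v <- v + se_a^2 * se_b^2
  sqrt(v)
}

# Coerce an mr_estimate or a list(beta=, se=) to c(beta, se).
as_beta_se <- function(x, leg) {
  if (inherits(x, "mr_estimate")) return(c(x$beta, x$se))
  if (is.list(x) && all(c("beta", "se") %in% names(x))) {
    return(c(x$beta, x$se))
  }
  if (is.numeric(x) && length(x) == 2L) return(x)
  stop(sprintf("leg '%s' must be an mr_estimate or list(beta=, se=)", leg),
       call. = FALSE)
}

#' Decompose a total causal effect into indirect and direct components
#'
#' Two-step MR mediation: with `a` the exposure-to-mediator effect, `b`
#' the mediator-to-outcome effect and `c` the total exposure-to-outcome
#' effect, the indirect effect is `a*b`, the direct effect is
#' `c' = c - a*b` (so direct + indirect = c exactly), and the proportion
#' mediated is `(a*b)/c`. The 95% CI of the indirect effect uses the
#' delta-method SE of the product; the proportion CI uses the delta method
#' on the ratio `(a*b)/c` treating the three estimates as independent (the
#' two-sample, non-overlapping-cohort setting).
#'
#' When the indirect and total effects have opposite signs the proportion
#' is flagged as inconsistent mediation (reported, but not interpretable
#' as a share of the total effect); when `c = 0` the proportion is
#' undefined and set to `NA` while the decomposition is still returned.
#'
#' @param a_est,b_est,c_est the three leg estimates: `mr_estimate`s,
#'   `list(beta=, se=)`, or length-2 numeric `c(beta, se)`.
#' @param order delta-method order for the product SE
#'   (see [delta_se_product()]).
#' @return Object of class `mediation_estimate`: a, se_a, b, se_b, c,
#'   se_c, indirect, se_indirect, ci_indirect, direct, proportion,
#'   proportion_pct, se_proportion, ci_proportion, flags
#'   `proportion_defined` and `consistent`.
#' @export
mediate_decompose <- function(a_est, b_est, c_est,
                              order = c("first", "second")) {
  order <- match.arg(order)
  a <- as_beta_se(a_est, "a"); b <- as_beta_se(b_est, "b")
  cc <- as_beta_se(c_est, "c")
  indirect <- product_effect(a[1], b[1])
  se_ind <- delta_se_product(a[1], a[2], b[1], b[2], order = order)
  direct <- cc[1] - indirect
  defined <- cc[1] != 0
  consistent <- defined && (indirect == 0 || sign(indirect) == sign(cc[1]))
  if (defined) {
    prop <- indirect / cc[1]
    # delta method on (a*b)/c with independent legs
    se_prop <- sqrt((b[1] / cc[1])^2 * a[2]^2 +
                    (a[1] / cc[1])^2 * b[2]^2 +
                    (indirect / cc[1]^2)^2 * cc[2]^2)
  } else {
    prop <- NA_real_
    se_prop <- NA_real_
  }
  structure(
    list(a = a[1], se_a = a[2], b = b[1], se_b = b[2], c = cc[1],
         se_c = cc[2],
         indirect = indirect, se_indirect = se_ind,
         ci_indirect = c(indirect - Z975 * se_ind, indirect + Z975 * se_ind),
         direct = direct,
         proportion = prop, proportion_pct = 100 * prop,
         se_proportion = se_prop,
         ci_proportion = if (defined)
           c(prop - Z975 * se_prop, prop + Z975 * se_prop)
         else c(NA_real_, NA_real_),
         proportion_defined = defined, consistent = consistent,
         delta_order = order),
    class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat(sprintf("<mediation_estimate> a=%.3f b=%.3f c=%.3f\n", x$a, x$b, x$c))
  cat(sprintf("  indirect (a*b) = %.4f [%.4f, %.4f]; direct (c') = %.4f\n",
              x$indirect, x$ci_indirect[1], x$ci_indirect[2], x$direct))
  if (!x$proportion_defined) {
    cat("  proportion mediated: undefined (total effect is zero)\n")
  } else if (!x$consistent) {
    cat(sprintf("  proportion mediated: %.2f%% -- inconsistent mediation (indirect and total effects have opposite signs; not interpretable)\n",
                x$proportion_pct))
  } else {
    cat(sprintf("  proportion mediated: %.2f%% [%.2f%%, %.2f%%]\n",
                x$proportion_pct, 100 * x$ci_proportion[1],
                100 * x$ci_proportion[2]))
  }
  invisible(x)
}

#' @export
as.data.frame.mediation_estimate <- function(x, ...) {
  data.frame(a = x$a, se_a = x$se_a, b = x$b, se_b = x$se_b,
             c = x$c, se_c = x$se_c,
             indirect = x$indirect, se_indirect = x$se_indirect,
             indirect_ci_low = x$ci_indirect[1],
             indirect_ci_high = x$ci_indirect[2],
             direct = x$direct, proportion_pct = x$proportion_pct,
             proportion_ci_low_pct = 100 * x$ci_proportion[1],
             proportion_ci_high_pct = 100 * x$ci_proportion[2],
             consistent = x$consistent)
}

#' Run the full two-step MR mediation pipeline on three traits
#'
#' Estimates the three legs by univariable two-sample MR -- exposure to
#' mediator (a), mediator to outcome (b), exposure to outcome (c) -- each
#' via instrument selection, harmonization and the configured estimator
#' (default multiplicative-random-effects IVW), then decomposes the total
#' effect with [mediate_decompose()]. Instruments for the a and c legs are
#' selected from the exposure GWAS, for the b leg from the mediator GWAS.
#'
#' @param exposure,mediator,outcome [summary_stats()] objects.
#' @param ld optional `ld_matrix` for clumping.
#' @param config list of settings; see [mr_config()].
#' @return A `mediation_estimate` with the per-leg `mr_estimate`s attached
#'   as attribute `legs`.
#' @export
mediation_pipeline <- function(exposure, mediator, outcome, ld = NULL,
                               config = mr_config()) {
  cfg <- utils::modifyList(mr_config(), config)
  leg <- function(exp_stats, out_stats, label) {
    inst <- tryCatch(
      select_instruments(exp_stats, ld = ld, p_threshold = cfg$p_threshold,
                         r2_threshold = cfg$r2_threshold,
                         window_kb = cfg$window_kb, f_min = cfg$f_min,
                         f_literal = cfg$f_literal),
      error = function(e) stop(sprintf("leg '%s': %s", label,
                                       conditionMessage(e)), call. = FALSE))
    pair <- tryCatch(harmonize(inst, out_stats),
                     error = function(e) stop(sprintf("leg '%s': %s", label,
                                                      conditionMessage(e)),
                                              call. = FALSE))
    mr_ivw(pair, variant = cfg$ivw_variant)
  }
  a_est <- leg(exposure, mediator, "exposure->mediator (a)")
  b_est <- leg(mediator, outcome, "mediator->outcome (b)")
  c_est <- leg(exposure, outcome, "exposure->outcome (c)")
  med <- mediate_decompose(a_est, b_est, c_est, order = cfg$delta_order)
  attr(med, "legs") <- list(a = a_est, b = b_est, c = c_est)
  med
}

#' Bundled example mediation path coefficients
#'
#' Published path-coefficient estimates from a two-step MR study of gut
#' microbiota features, immune-cell phenotypes and neuropathic-pain
#' outcomes (post-herpetic neuralgia, trigeminal neuralgia, painful
#' diabetic peripheral neuropathy): one row per exposure-mediator-outcome
#' triplet with the exposure-to-mediator effect `a`, mediator-to-outcome
#' effect `b` and total effect `c`, all on the log-odds scale. Useful for
#' demonstrating [mediate_decompose()] on real reported numbers.
#'
#' @return data.frame with columns `exposure`, `mediator`, `outcome`,
#'   `a`, `b`, `c`.
#' @export
example_mediation_paths <- function() {
  path <- system.file("extdata", "mediation_paths.tsv", package = "mrmediate",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
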