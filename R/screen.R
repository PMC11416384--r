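# Batch screening: forward MR over many exposures, reverse-MR exclusion,
# sensitivity gating and mediation-candidate selection.

#' Default pipeline configuration
#'
#' Central defaults used by the screening and mediation pipelines:
#' instrument selection at p < 1e-5 with greedy clumping (r^2 < 0.001,
#' 10,000 kb window) and F >= 10; nominal significance 0.05 for both the
#' causal tests and the sensitivity gates; 1000 MR-PRESSO null
#' simulations; 1000 bootstrap resamples for median/mode SEs; first-order
#' delta method; multiplicative-random-effects IVW as the headline
#' estimator; "confirming" methods required at p < 0.05 (set
#' `confirm_p = FALSE` to require directional consistency only).
#'
#' @param ... named overrides of any default.
#' @return Named list of settings.
#' @export
mr_config <- function(...) {
  cfg <- list(p_threshold = 1e-5, r2_threshold = 0.001, window_kb = 10000,
              f_min = 10, f_literal = FALSE, alpha = 0.05,
              n_sim_presso = 1000, n_boot = 1000,
              delta_order = "first", ivw_variant = "mre",
              confirm_p = TRUE, seed = 1)
  utils::modifyList(cfg, list(...))
}

# Methods that count towards multi-method concordance (fixed-effect IVW is
# a variant of IVW, not an independent method).
CONCORDANCE_METHODS <- c("ivw_mre", "egger", "weighted_median",
                         "simple_mode", "weighted_mode", "bwmr")

#' Classify one exposure-outcome association
#'
#' Applies the evidence rule of the screening workflow: an association is
#' `significant` when both the IVW and the Bayesian weighted estimates
#' have p < `alpha` with concordant signs; sensitivity gates override the
#' verdict to `excluded_pleiotropy` (Egger-intercept or MR-PRESSO global
#' p < `alpha`) or `excluded_heterogeneity` (Cochran's Q p < `alpha`).
#' Also counts, among IVW (multiplicative random effects), MR-Egger,
#' weighted median, the two modes and the Bayesian weighted estimator, how
#' many are individually significant with the IVW sign
#' (`n_methods_concordant`) and how many merely share the IVW sign
#' (`n_methods_directional`).
#'
#' @param estimates tidy estimate table from [mr_all_methods()] (columns
#'   `method`, `beta`, `pval`).
#' @param sensitivity a [sensitivity_report()], or `NULL` to skip gating.
#' @param alpha significance threshold (default 0.05).
#' @return List with `verdict`, `n_methods_concordant`,
#'   `n_methods_directional`, `ivw`, `bwmr` (each beta/pval).
#' @export
classify_significance <- function(estimates, sensitivity = NULL,
                                  alpha = 0.05) {
  est <- as.data.frame(estimates)
  need <- c("ivw_mre", "bwmr")
  if (!all(need %in% est$method)) {
    stop(sprintf("classification requires estimates for: %s",
                 paste(setdiff(need, est$method), collapse = ", ")),
         call. = FALSE)
  }
  row <- function(m) est[est$method == m, , drop = FALSE][1L, ]
  ivw <- row("ivw_mre"); bw <- row("bwmr")
  meth <- est[est$method %in% CONCORDANCE_METHODS, , drop = FALSE]
  same_sign <- sign(meth$beta) == sign(ivw$beta)
  n_conc <- sum(meth$pval < alpha & same_sign)
  n_dir <- sum(same_sign)
  verdict <- if (!is.null(sensitivity) &&
                 (sensitivity$egger_intercept_pval < alpha ||
                  sensitivity$presso_global_pval < alpha)) {
    "excluded_pleiotropy"
  } else if (!is.null(sensitivity) && sensitivity$q_pval < alpha) {
    "excluded_heterogeneity"
  } else if (ivw$pval < alpha && bw$pval < alpha &&
             sign(ivw$beta) == sign(bw$beta)) {
    "significant"
  } else {
    "not_significant"
  }
  list(verdict = verdict, n_methods_concordant = n_conc,
       n_methods_directional = n_dir,
       ivw = list(beta = ivw$beta, pval = ivw$pval),
       bwmr = list(beta = bw$beta, pval = bw$pval))
}

screen_row_template <- function(exposure_id, outcome_id) {
  data.frame(exposure = exposure_id, outcome = outcome_id,
             verdict = "skipped", reason = NA_character_,
             nsnp = NA_integer_, beta_ivw = NA_real_, se_ivw = NA_real_,
             pval_ivw = NA_real_, beta_bwmr = NA_real_, pval_bwmr = NA_real_,
             n_methods_concordant = NA_integer_,
             n_methods_directional = NA_integer_,
             q_pval = NA_real_, egger_intercept_pval = NA_real_,
             presso_global_pval = NA_real_)
}

#' Forward MR screen over many exposures against one outcome
#'
#' For each exposure: instrument selection, harmonization, the full
#' estimator suite, the full sensitivity report, and classification.
#' Per-exposure failures (e.g. no surviving instruments) are recorded as
#' `skipped` rows with their reason and never abort the batch; the output
#' always has one row per input exposure.
#'
#' @param exposures list of [summary_stats()] objects.
#' @param outcome a [summary_stats()] object.
#' @param ld optional `ld_matrix`.
#' @param config see [mr_config()].
#' @return data.frame with one row per exposure (verdict, headline
#'   estimates, concordance counts, gate p-values); the per-exposure
#'   estimate tables and sensitivity reports are attached as attribute
#'   `details` (a named list).
#' @export
run_forward_screen <- function(exposures, outcome, ld = NULL,
                               config = mr_config()) {
  cfg <- utils::modifyList(mr_config(), config)
  stopifnot(length(exposures) >= 1L)
  details <- list()
  rows <- lapply(exposures, function(exp_stats) {
    out_row <- screen_row_template(exp_stats$trait_id, outcome$trait_id)
    res <- tryCatch({
      inst <- select_instruments(exp_stats, ld = ld,
                                 p_threshold = cfg$p_threshold,
                                 r2_threshold = cfg$r2_threshold,
                                 window_kb = cfg$window_kb,
                                 f_min = cfg$f_min, f_literal = cfg$f_literal)
      pair <- harmonize(inst, outcome)
      est <- mr_all_methods(pair, n_boot = cfg$n_boot, seed = cfg$seed)
      sens <- sensitivity_report(pair, n_sim = cfg$n_sim_presso,
                                 seed = cfg$seed, alpha = cfg$alpha)
      cls <- classify_significance(est, sens, alpha = cfg$alpha)
      details[[exp_stats$trait_id]] <<- list(estimates = est,
                                             sensitivity = sens)
      out_row$verdict <- cls$verdict
      out_row$nsnp <- nrow(pair$data)
      out_row$beta_ivw <- cls$ivw$beta
      out_row$se_ivw <- est$se[est$method == "ivw_mre"][1L]
      out_row$pval_ivw <- cls$ivw$pval
      out_row$beta_bwmr <- cls$bwmr$beta
      out_row$pval_bwmr <- cls$bwmr$pval
      out_row$n_methods_concordant <- cls$n_methods_concordant
      out_row$n_methods_directional <- cls$n_methods_directional
      out_row$q_pval <- sens$q_pval
      out_row$egger_intercept_pval <- sens$egger_intercept_pval
      out_row$presso_global_pval <- sens$presso_global_pval
      out_row
    }, error = function(e) {
      out_row$reason <- conditionMessage(e)
      out_row
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Reverse MR screen: outcome as exposure
#'
#' Swaps the roles: instruments are selected from the outcome trait's GWAS
#' and IVW is run against each original exposure, flagging nominally
#' significant reverse effects (reverse IVW p < `alpha`). By construction
#' the forward and reverse screens of a pair use disjoint instrument
#' sets (each trait's own top SNPs).
#'
#' @param outcome the outcome [summary_stats()] (now the instrument
#'   source).
#' @param exposures list of [summary_stats()] (now outcomes).
#' @param ld optional `ld_matrix`.
#' @param config see [mr_config()].
#' @return data.frame: exposure, outcome, nsnp, beta_reverse, se_reverse,
#'   pval_reverse, reverse_significant, reason.
#' @export
run_reverse_screen <- function(outcome, exposures, ld = NULL,
                               config = mr_config()) {
  cfg <- utils::modifyList(mr_config(), config)
  inst <- tryCatch(
    select_instruments(outcome, ld = ld, p_threshold = cfg$p_threshold,
                       r2_threshold = cfg$r2_threshold,
                       window_kb = cfg$window_kb, f_min = cfg$f_min,
                       f_literal = cfg$f_literal),
    error = function(e) NULL)
  rows <- lapply(exposures, function(exp_stats) {
    row <- data.frame(exposure = exp_stats$trait_id,
                      outcome = outcome$trait_id, nsnp = NA_integer_,
                      beta_reverse = NA_real_, se_reverse = NA_real_,
                      pval_reverse = NA_real_, reverse_significant = FALSE,
                      reason = NA_character_)
    if (is.null(inst)) {
      row$reason <- "no instruments for outcome trait"
      return(row)
    }
    tryCatch({
      pair <- harmonize(inst, exp_stats)
      est <- mr_ivw(pair, variant = cfg$ivw_variant)
      row$nsnp <- est$n_snp
      row$beta_reverse <- est$beta
      row$se_reverse <- est$se
      row$pval_reverse <- est$pval
      row$reverse_significant <- est$pval < cfg$alpha
      row
    }, error = function(e) {
      row$reason <- conditionMessage(e)
      row
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select exposure-mediator-outcome triplets eligible for mediation
#'
#' Implements the candidate rules of the screening workflow. A triplet is
#' a candidate iff:
#' \itemize{
#'   \item the exposure-to-outcome association passes the multi-method
#'     rule: `significant` verdict (IVW + Bayesian weighted concordant,
#'     clean diagnostics) and at least three concordant methods in total
#'     (i.e. at least one of MR-Egger/median/modes confirming, at p <
#'     alpha when `confirm_p`, by sign otherwise);
#'   \item the exposure is not flagged in the reverse screen;
#'   \item the exposure-to-mediator and mediator-to-outcome associations
#'     each have a `significant` verdict (IVW + Bayesian weighted, clean
#'     diagnostics);
#'   \item the implied indirect effect `a*b` has the sign of the total
#'     effect `c` (consistent mediation).
#' }
#'
#' @param gm_outcome forward-screen table for exposure -> outcome
#'   ([run_forward_screen()] output).
#' @param gm_cell forward-screen table for exposure -> mediator; its
#'   `outcome` column names the mediator.
#' @param cell_outcome forward-screen table for mediator -> outcome.
#' @param reverse_flags optional [run_reverse_screen()] table for the
#'   outcome against the exposures.
#' @param confirm_p require the confirming third method at p < alpha
#'   (default) rather than sign-only.
#' @param alpha significance threshold.
#' @return data.frame of all evaluated triplets: exposure, mediator,
#'   outcome, a, b, c, candidate (logical), reason.
#' @export
select_mediation_candidates <- function(gm_outcome, gm_cell, cell_outcome,
                                        reverse_flags = NULL,
                                        confirm_p = TRUE, alpha = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(gm_cell))) {
    e_id <- gm_cell$exposure[i]
    m_id <- gm_cell$outcome[i]
    go <- gm_outcome[gm_outcome$exposure == e_id, , drop = FALSE]
    co <- cell_outcome[cell_outcome$exposure == m_id, , drop = FALSE]
    if (nrow(go) == 0L || nrow(co) == 0L) next
    go <- go[1L, ]; co <- co[1L, ]
    a <- gm_cell$beta_ivw[i]; b <- co$beta_ivw; cc <- go$beta_ivw
    n_third <- if (confirm_p) go$n_methods_concordant else
      go$n_methods_directional
    reversed <- FALSE
    if (!is.null(reverse_flags)) {
      rf <- reverse_flags[reverse_flags$exposure == e_id, , drop = FALSE]
      reversed <- nrow(rf) > 0 && isTRUE(rf$reverse_significant[1L])
    }
    reason <- if (reversed) {
      "excluded_reverse"
    } else if (go$verdict %in% c("excluded_pleiotropy",
                                 "excluded_heterogeneity")) {
      go$verdict
    } else if (!identical(go$verdict, "significant")) {
      "total_effect_not_significant"
    } else if (is.na(n_third) || n_third < 3L) {
      "fewer_than_three_concordant_methods"
    } else if (!identical(gm_cell$verdict[i], "significant")) {
      "exposure_mediator_leg_not_significant"
    } else if (!identical(co$verdict, "significant")) {
      "mediator_outcome_leg_not_significant"
    } else if (is.na(a) || is.na(b) || is.na(cc) ||
               sign(a * b) != sign(cc)) {
      "inconsistent_mediation_sign"
    } else {
      "candidate"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      exposure = e_id, mediator = m_id, outcome = go$outcome,
      a = a, b = b, c = cc,
      candidate = identical(reason, "candidate"), reason = reason)
  }
  if (!length(rows)) {
    return(data.frame(exposure = character(), mediator = character(),
                      outcome = character(), a = numeric(), b = numeric(),
                      c = numeric(), candidate = logical(),
                      reason = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
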