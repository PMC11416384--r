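clean_sens <- list(q_pval = 0.5, egger_intercept_pval = 0.5,
                   presso_global_pval = 0.5)

fake_estimates <- function(p_ivw, p_bwmr, beta_ivw = 0.3, beta_bwmr = 0.3,
                           others_p = 0.5, others_beta = 0.3) {
  data.frame(
    method = c("ivw_mre", "ivw_fe", "egger", "weighted_median",
               "simple_mode", "weighted_mode", "bwmr"),
    beta = c(beta_ivw, beta_ivw, rep_len(others_beta, 4), beta_bwmr),
    pval = c(p_ivw, p_ivw, rep_len(others_p, 4), p_bwmr))
}

test_that("significance rule requires concordant IVW and Bayesian results", {
  # the printed evidence pattern of a reported taxon: IVW p = 0.041,
  # Bayesian weighted p = 0.039, same direction, clean diagnostics
  est <- fake_estimates(0.041, 0.039, beta_ivw = log(1.339),
                        beta_bwmr = log(1.30), others_beta = log(1.2))
  cls <- classify_significance(est, clean_sens)
  expect_equal(cls$verdict, "significant")

  expect_equal(classify_significance(
    fake_estimates(0.004, 0.30), clean_sens)$verdict, "not_significant")
  expect_equal(classify_significance(
    fake_estimates(0.01, 0.01, beta_bwmr = -0.3), clean_sens)$verdict,
    "not_significant")
  expect_error(classify_significance(
    data.frame(method = "ivw_mre", beta = 1, pval = 0.01), clean_sens),
    "bwmr")
})

test_that("sensitivity gates take precedence over significance", {
  est <- fake_estimates(0.01, 0.01)
  het <- clean_sens; het$q_pval <- 0.01
  expect_equal(classify_significance(est, het)$verdict,
               "excluded_heterogeneity")
  ple <- clean_sens; ple$egger_intercept_pval <- 0.01
  expect_equal(classify_significance(est, ple)$verdict,
               "excluded_pleiotropy")
  ple2 <- clean_sens; ple2$presso_global_pval <- 0.01
  expect_equal(classify_significance(est, ple2)$verdict,
               "excluded_pleiotropy")
})

test_that("method concordance counts significant same-sign methods", {
  est <- fake_estimates(0.01, 0.01, others_p = c(0.01, 0.2, 0.2, 0.01))
  cls <- classify_significance(est, clean_sens)
  expect_equal(cls$n_methods_concordant, 4)  # ivw, bwmr, 2 others
  expect_equal(cls$n_methods_directional, 6)
  est2 <- fake_estimates(0.01, 0.01, others_p = 0.01, others_beta = -0.3)
  expect_equal(classify_significance(est2, clean_sens)$n_methods_concordant, 2)
})

# Build a shared-outcome study: several exposures, some with true effects.
make_multi_exposure_study <- function(effects, n_snps = 40, seed = 1) {
  sims <- lapply(seq_along(effects), function(i) {
    tp <- truth_params(effect_a = 0, effect_b = 0,
                       effect_direct = effects[i],
                       n_snps = n_snps, n_snps_med = 0,
                       n_exp = 3e5, n_med = 3e5, n_out = 8000,
                       seed = seed * 1000 + i)
    sim <- simulate_triplet_gwas(tp)
    rename <- function(stats) {
      stats$records$rsid <- paste0("e", i, "_", stats$records$rsid)
      stats$trait_id <- paste0(stats$trait_id, "_", i)
      stats
    }
    list(exposure = rename(sim$exposure), outcome = rename(sim$outcome))
  })
  outcome_records <- do.call(rbind, lapply(sims, function(s) s$outcome$records))
  list(exposures = lapply(sims, `[[`, "exposure"),
       outcome = summary_stats(outcome_records, "shared_outcome", "outcome"))
}

test_that("forward screen separates true from null exposures", {
  effects <- c(-0.9, 0, 0, 0.8, 0, 0, -0.85, 0, 0, 0)
  study <- make_multi_exposure_study(effects, seed = 3)
  cfg <- mr_config(n_boot = 100, n_sim_presso = 200)
  fw <- suppressMessages(
    run_forward_screen(study$exposures, study$outcome, config = cfg))
  expect_equal(nrow(fw), 10)
  truth_sig <- effects != 0
  # no null exposure is ever declared significant
  expect_true(all(fw$verdict[!truth_sig] != "significant"))
  # true effects are detected by IVW and mostly survive the gates
  expect_true(all(fw$pval_ivw[truth_sig] < 0.05))
  expect_gte(sum(fw$verdict[truth_sig] == "significant"), 2)
})

test_that("exposures without instruments are skipped, not fatal", {
  study <- make_multi_exposure_study(c(-0.9, 0), seed = 9)
  weak <- study$exposures[[2]]
  weak$records$pval <- 0.5  # nothing passes selection
  fw <- suppressMessages(run_forward_screen(
    list(study$exposures[[1]], weak), study$outcome,
    config = mr_config(n_boot = 100, n_sim_presso = 200)))
  expect_equal(nrow(fw), 2)
  expect_equal(fw$verdict[2], "skipped")
  expect_match(fw$reason[2], "no SNP passes")
})

test_that("reverse screen flags injected reverse causation", {
  tp <- truth_params(n_snps = 60, n_snps_med = 0, n_snps_out = 80,
                     effect_reverse = 0.4, n_exp = 3e5, n_out = 8000,
                     seed = 71)
  sim <- simulate_triplet_gwas(tp)
  rev <- suppressMessages(
    run_reverse_screen(sim$outcome, list(sim$exposure)))
  expect_true(rev$reverse_significant[1])

  # without reverse causation the forward and reverse screens select
  # disjoint instrument sets (each trait's own top SNPs)
  tp0 <- truth_params(n_snps = 60, n_snps_med = 0, n_snps_out = 80,
                      effect_reverse = 0, n_exp = 3e5, n_out = 8000,
                      seed = 72)
  sim0 <- simulate_triplet_gwas(tp0)
  fwd_inst <- suppressMessages(select_instruments(sim0$exposure))
  rev_inst <- suppressMessages(select_instruments(sim0$outcome))
  roles <- sim0$snp_roles
  expect_true(all(roles$role[match(fwd_inst$records$rsid, roles$rsid)] ==
                    "exposure_instrument"))
  expect_true(all(roles$role[match(rev_inst$records$rsid, roles$rsid)] ==
                    "outcome_instrument"))
  expect_length(intersect(fwd_inst$records$rsid, rev_inst$records$rsid), 0)
})

test_that("reverse screen stays near nominal size without reverse effects", {
  flags <- vapply(1:30, function(seed) {
    tp <- truth_params(n_snps = 30, n_snps_med = 0, n_snps_out = 60,
                       effect_reverse = 0, n_exp = 3e5, n_out = 8000,
                       seed = 400 + seed)
    sim <- simulate_triplet_gwas(tp)
    rev <- suppressMessages(run_reverse_screen(sim$outcome,
                                               list(sim$exposure)))
    isTRUE(rev$reverse_significant[1])
  }, logical(1))
  expect_lte(mean(flags), 0.17)
})

test_that("candidate selection applies the triplet rules in order", {
  gm_out <- screen_row <- data.frame(
    exposure = "gm", outcome = "np", verdict = "significant",
    reason = NA, nsnp = 50, beta_ivw = -0.9, se_ivw = 0.1,
    pval_ivw = 1e-5, beta_bwmr = -0.85, pval_bwmr = 1e-4,
    n_methods_concordant = 3L, n_methods_directional = 5L,
    q_pval = 0.5, egger_intercept_pval = 0.5, presso_global_pval = 0.5)
  gm_cell <- transform(screen_row, outcome = "cell", beta_ivw = 0.3)
  cell_out <- transform(screen_row, exposure = "cell", beta_ivw = -0.25)
  rev_ok <- data.frame(exposure = "gm", reverse_significant = FALSE)

  cand <- select_mediation_candidates(gm_out, gm_cell, cell_out, rev_ok)
  expect_true(cand$candidate)
  expect_equal(cand$reason, "candidate")
  expect_equal(cand$a * cand$b > 0, cand$c > 0)

  rev_bad <- data.frame(exposure = "gm", reverse_significant = TRUE)
  expect_equal(select_mediation_candidates(gm_out, gm_cell, cell_out,
                                           rev_bad)$reason,
               "excluded_reverse")

  two_methods <- transform(gm_out, n_methods_concordant = 2L)
  expect_equal(select_mediation_candidates(two_methods, gm_cell, cell_out,
                                           rev_ok)$reason,
               "fewer_than_three_concordant_methods")
  # sign-only confirmation accepts the same triplet
  expect_true(select_mediation_candidates(two_methods, gm_cell, cell_out,
                                          rev_ok, confirm_p = FALSE)$candidate)

  bad_leg <- transform(cell_out, verdict = "not_significant")
  expect_equal(select_mediation_candidates(gm_out, gm_cell, bad_leg,
                                           rev_ok)$reason,
               "mediator_outcome_leg_not_significant")

  flipped <- transform(cell_out, beta_ivw = 0.25)
  expect_equal(select_mediation_candidates(gm_out, gm_cell, flipped,
                                           rev_ok)$reason,
               "inconsistent_mediation_sign")

  het <- transform(gm_out, verdict = "excluded_heterogeneity")
  expect_equal(select_mediation_candidates(het, gm_cell, cell_out,
                                           rev_ok)$reason,
               "excluded_heterogeneity")
})
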