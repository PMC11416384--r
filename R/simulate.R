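#' Ground-truth parameters for a synthetic three-trait GWAS study
#'
#' Defines the causal structure exposure -> mediator -> outcome used by
#' [simulate_triplet_gwas()]. The mediation decomposition follows the
#' standard two-step convention: `a` is the exposure-to-mediator effect,
#' `b` the mediator-to-outcome effect, `effect_direct` (c') the outcome
#' effect not through the mediator, and the total effect satisfies
#' c = c' + a*b exactly by construction.
#'
#' Instrument strength is parameterised by the expected chi-square
#' (equivalently the expected single-SNP F statistic) of a true instrument
#' in its own GWAS; defaults (60 for the exposure, 100 for the mediator-
#' and outcome-specific sets) are typical of variants surviving genome-wide
#' selection at p < 1e-5 in the sample sizes used here.
#'
#' @param effect_a exposure -> mediator effect (path a).
#' @param effect_b mediator -> outcome effect (path b).
#' @param effect_direct direct exposure -> outcome effect (c'). Exactly one
#'   of `effect_direct` and `beta_total` must be supplied; the other is
#'   derived through c = c' + a*b.
#' @param beta_total total exposure -> outcome effect (c).
#' @param pleio_fraction proportion of exposure instruments with a direct
#'   (pleiotropic) outcome effect, in \[0, 1\].
#' @param pleio_mean mean of the pleiotropic effects (0 = balanced
#'   pleiotropy; nonzero = directional).
#' @param pleio_sd standard deviation of the pleiotropic effects (>= 0).
#' @param n_snps number of exposure instruments J.
#' @param n_snps_med number of mediator-specific instruments (the mediator's
#'   own genetic architecture; required for the b leg of two-step MR to be
#'   identified).
#' @param n_snps_out number of outcome-specific instruments (used for
#'   reverse-MR experiments; 0 by default).
#' @param effect_reverse reverse outcome -> exposure effect carried by the
#'   outcome-specific instruments (0 = no reverse causation).
#' @param n_exp,n_med,n_out GWAS sample sizes for the three traits.
#' @param maf_range interval within (0, 0.5] from which effect-allele
#'   frequencies are drawn uniformly.
#' @param strength_exp,strength_med,strength_out expected instrument
#'   chi-square for each trait's specific instruments.
#' @param seed RNG seed; identical parameters (including seed) give
#'   identical output.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(effect_a = 0.24, effect_b = -0.27,
                         effect_direct = NULL, beta_total = NULL,
                         pleio_fraction = 0, pleio_mean = 0, pleio_sd = 0,
                         n_snps = 150, n_snps_med = 150, n_snps_out = 0,
                         effect_reverse = 0,
                         n_exp = 300000, n_med = 300000, n_out = 300000,
                         maf_range = c(0.05, 0.5),
                         strength_exp = 60, strength_med = 100,
                         strength_out = 100, seed = 1) {
  if (is.null(effect_direct) && is.null(beta_total)) effect_direct <- -0.90
  if (!is.null(effect_direct) && !is.null(beta_total)) {
    if (abs(beta_total - (effect_direct + effect_a * effect_b)) > 1e-12) {
      stop("supply either `effect_direct` or `beta_total`; both given and inconsistent with c = c' + a*b",
           call. = FALSE)
    }
  }
  if (is.null(effect_direct)) effect_direct <- beta_total - effect_a * effect_b
  beta_total <- effect_direct + effect_a * effect_b
  for (nm in c("effect_a", "effect_b", "effect_direct", "pleio_fraction",
               "pleio_mean", "pleio_sd", "effect_reverse")) {
    stopifnot_scalar(get(nm), nm)
  }
  if (pleio_fraction < 0 || pleio_fraction > 1) {
    stop("`pleio_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (pleio_sd < 0) stop("`pleio_sd` must be >= 0", call. = FALSE)
  if (n_snps < 1) stop("need at least one exposure instrument", call. = FALSE)
  if (any(c(n_exp, n_med, n_out) < 2)) {
    stop("all GWAS sample sizes must be >= 2", call. = FALSE)
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an interval within (0, 0.5]", call. = FALSE)
  }
  structure(
    list(effect_a = effect_a, effect_b = effect_b,
         effect_direct = effect_direct, beta_total = beta_total,
         pleio_fraction = pleio_fraction, pleio_mean = pleio_mean,
         pleio_sd = pleio_sd,
         n_snps = as.integer(n_snps), n_snps_med = as.integer(n_snps_med),
         n_snps_out = as.integer(n_snps_out),
         effect_reverse = effect_reverse,
         n_exp = as.integer(n_exp), n_med = as.integer(n_med),
         n_out = as.integer(n_out),
         maf_range = as.numeric(maf_range),
         strength_exp = strength_exp, strength_med = strength_med,
         strength_out = strength_out, seed = as.integer(seed)),
    class = "truth_params"
  )
}

#' @export
print.truth_params <- function(x, ...) {
  cat(sprintf(
    "<truth_params> a=%.3g b=%.3g c'=%.3g (c=%.3g); J=%d (+%d med, +%d out); pleiotropy pi=%.2g mu=%.2g tau=%.2g; seed=%d\n",
    x$effect_a, x$effect_b, x$effect_direct, x$beta_total,
    x$n_snps, x$n_snps_med, x$n_snps_out,
    x$pleio_fraction, x$pleio_mean, x$pleio_sd, x$seed))
  invisible(x)
}

#' Block-diagonal AR(1) linkage-disequilibrium matrix
#'
#' Builds a synthetic LD correlation matrix with independent blocks and
#' AR(1) decay within each block: r_ij = rho^|i-j| inside a block, 0
#' across blocks. Variants are laid out with strictly increasing positions
#' within each chromosome; a new block never straddles a chromosome
#' boundary when `positions_per_chrom` is a multiple of `block_size`.
#'
#' @param n_snps total number of variants.
#' @param block_size variants per LD block.
#' @param rho within-block adjacent correlation, in \[0, 1).
#' @param positions_per_chrom variants placed per chromosome.
#' @param spacing_bp base pairs between adjacent variants on a chromosome.
#' @param rsids optional variant ids (default `rs1..rsN`).
#' @return An object of class `ld_matrix`: list with `rsids`, correlation
#'   matrix `r` (dimnames = rsids) and a `variants` data.frame
#'   (rsid, chrom, pos).
#' @export
simulate_ld_blocks <- function(n_snps, block_size = 10, rho = 0,
                               positions_per_chrom = 50, spacing_bp = 50000,
                               rsids = NULL) {
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  if (n_snps < 1 || block_size < 1) {
    stop("`n_snps` and `block_size` must be positive", call. = FALSE)
  }
  rsids <- rsids %||% paste0("rs", seq_len(n_snps))
  stopifnot(length(rsids) == n_snps)
  idx <- seq_len(n_snps) - 1L
  block <- idx %/% block_size
  within <- idx %% block_size
  r <- rho ^ abs(outer(within, within, "-"))
  r[outer(block, block, "!=")] <- 0
  dimnames(r) <- list(rsids, rsids)
  chrom <- (idx %/% positions_per_chrom) + 1L
  pos <- (idx %% positions_per_chrom) * spacing_bp + 1L
  structure(
    list(rsids = rsids, r = r,
         variants = data.frame(rsid = rsids, chrom = as.character(chrom),
                               pos = as.integer(pos))),
    class = "ld_matrix"
  )
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d variants\n", length(x$rsids)))
  invisible(x)
}

#' Write / read an LD matrix as dense tab-separated text
#'
#' The format has a header row of variant ids and a leading id column.
#'
#' @param ld an `ld_matrix` object.
#' @param path file path.
#' @return `write_ld_matrix()` returns `path` invisibly; `read_ld_matrix()`
#'   returns an `ld_matrix` (without variant positions).
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  out <- data.frame(rsid = ld$rsids, ld$r, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  rsids <- as.character(dt[[1L]])
  r <- as.matrix(dt[, -1L, drop = FALSE])
  dimnames(r) <- list(rsids, rsids)
  structure(list(rsids = rsids, r = r, variants = NULL), class = "ld_matrix")
}

# Non-palindromic ordered allele pairs used by the generator.
NONPALINDROMIC_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "G", "A",
  "C", "T", "T", "C", "G", "T", "T", "G"), ncol = 2L, byrow = TRUE)

# Draw one trait's observed summary statistics from its true effects.
sample_trait <- function(rsid, chrom, pos, ea, oa, eaf, true_beta, n) {
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
  beta <- true_beta + stats::rnorm(length(true_beta), 0, se)
  data.frame(rsid = rsid, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se,
             pval = pmax(pval_z(beta, se), .Machine$double.xmin),
             n = n)
}

#' Simulate a three-trait GWAS with known mediation structure
#'
#' Generates summary statistics for an exposure, a mediator and an outcome
#' under the causal chain exposure -> mediator -> outcome plus a direct
#' exposure -> outcome path, entirely on the summary-statistic scale.
#'
#' The variant set is the union of three disjoint instrument groups:
#' \itemize{
#'   \item `n_snps` exposure instruments with effects
#'     gamma_j ~ N(0, strength_exp * se_xj^2) (so the expected single-SNP
#'     chi-square is about `strength_exp` + 1, comfortably above the weak-
#'     instrument threshold of 10). Their mediator effect is `a * gamma_j`
#'     and their outcome effect `(c' + a*b) * gamma_j + alpha_j`, where
#'     `alpha_j` is 0 with probability 1 - `pleio_fraction` and otherwise
#'     drawn from N(`pleio_mean`, `pleio_sd`^2), expressed per
#'     exposure-increasing allele (so `pleio_mean` != 0 is directional
#'     pleiotropy as the Egger intercept defines it).
#'   \item `n_snps_med` mediator-specific instruments with effects
#'     delta_j ~ N(0, strength_med * se_mj^2), outcome effect `b * delta_j`,
#'     and no exposure effect.
#'   \item `n_snps_out` outcome-specific instruments, with an exposure
#'     effect `effect_reverse * zeta_j` to emulate reverse causation.
#' }
#' Observed estimates add sampling noise N(0, se^2) with
#' se = 1/sqrt(2 p (1-p) n); p-values are two-sided Gaussian. Variants are
#' spaced > 10 Mb apart (approximate linkage equilibrium). The same
#' parameters (including seed) reproduce the output exactly.
#'
#' @param truth a [truth_params()] object.
#' @return A list of class `mr_triplet_sim` with elements `exposure`,
#'   `mediator`, `outcome` ([summary_stats()] objects), the echoed `truth`,
#'   and `snp_roles` (data.frame rsid/role).
#' @export
simulate_triplet_gwas <- function(truth) {
  stopifnot(inherits(truth, "truth_params"))
  with_seed(truth$seed, {
    n_tot <- truth$n_snps + truth$n_snps_med + truth$n_snps_out
    role <- rep(c("exposure_instrument", "mediator_instrument",
                  "outcome_instrument"),
                c(truth$n_snps, truth$n_snps_med, truth$n_snps_out))
    idx <- seq_len(n_tot)
    rsid <- sprintf("rs%05d", idx)
    chrom <- as.character(((idx - 1L) %% 22L) + 1L)
    pos <- as.integer(1e6 + ((idx - 1L) %/% 22L) * 2e7)
    pair <- NONPALINDROMIC_PAIRS[
      sample.int(nrow(NONPALINDROMIC_PAIRS), n_tot, replace = TRUE), ,
      drop = FALSE]
    eaf <- stats::runif(n_tot, truth$maf_range[1], truth$maf_range[2])

    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_exp)
    se_m <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_med)
    se_o <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_out)

    is_exp <- role == "exposure_instrument"
    is_med <- role == "mediator_instrument"
    is_out <- role == "outcome_instrument"

    gamma <- delta <- zeta <- numeric(n_tot)
    gamma[is_exp] <- stats::rnorm(sum(is_exp), 0,
                                  sqrt(truth$strength_exp) * se_x[is_exp])
    delta[is_med] <- stats::rnorm(sum(is_med), 0,
                                  sqrt(truth$strength_med) * se_m[is_med])
    zeta[is_out] <- stats::rnorm(sum(is_out), 0,
                                 sqrt(truth$strength_out) * se_o[is_out])

    # Pleiotropic effects are expressed per exposure-increasing allele
    # (aligned with sign(gamma)), the orientation on which directional
    # pleiotropy and the Egger intercept are defined; balanced pleiotropy
    # (pleio_mean = 0) is unaffected by the alignment.
    alpha <- numeric(n_tot)
    if (truth$pleio_fraction > 0 && any(is_exp)) {
      hit <- is_exp & stats::runif(n_tot) < truth$pleio_fraction
      alpha[hit] <- sign(gamma[hit]) *
        stats::rnorm(sum(hit), truth$pleio_mean, truth$pleio_sd)
    }

    true_x <- gamma + truth$effect_reverse * zeta
    true_m <- truth$effect_a * gamma + delta
    true_y <- (truth$effect_direct + truth$effect_a * truth$effect_b) * gamma +
      truth$effect_b * delta + zeta + alpha

    exposure <- summary_stats(
      sample_trait(rsid, chrom, pos, pair[, 1], pair[, 2], eaf, true_x,
                   truth$n_exp),
      trait_id = "sim_exposure", trait_class = "gut_microbiota")
    mediator <- summary_stats(
      sample_trait(rsid, chrom, pos, pair[, 1], pair[, 2], eaf, true_m,
                   truth$n_med),
      trait_id = "sim_mediator", trait_class = "immune_cell")
    outcome <- summary_stats(
      sample_trait(rsid, chrom, pos, pair[, 1], pair[, 2], eaf, true_y,
                   truth$n_out),
      trait_id = "sim_outcome", trait_class = "outcome")

    structure(
      list(exposure = exposure, mediator = mediator, outcome = outcome,
           truth = truth,
           snp_roles = data.frame(rsid = rsid, role = role)),
      class = "mr_triplet_sim")
  })
}

#' @export
print.mr_triplet_sim <- function(x, ...) {
  cat(sprintf("<mr_triplet_sim> %d SNPs; truth: a=%.3g b=%.3g c=%.3g\n",
              nrow(x$exposure$records), x$truth$effect_a, x$truth$effect_b,
              x$truth$beta_total))
  invisible(x)
}

#' Inject allele-flip and palindromic artifacts into summary statistics
#'
#' Emulates the harmonization hazards of real GWAS files: a fraction of
#' records get their effect/other alleles swapped (beta negated, frequency
#' reflected to 1 - p) and a disjoint fraction get their allele pair
#' rewritten to a palindromic A/T or G/C pair. All modified variant ids are
#' recorded in the `modifications` attribute.
#'
#' @param stats a [summary_stats()] object.
#' @param frac_flipped,frac_palindromic fractions in \[0, 1\] with sum <= 1.
#' @param seed RNG seed.
#' @return A modified [summary_stats()] object with attribute
#'   `modifications` (data.frame rsid/type).
#' @export
inject_harmonization_noise <- function(stats, frac_flipped = 0,
                                       frac_palindromic = 0, seed = 1) {
  stopifnot(inherits(stats, "summary_stats"))
  if (frac_flipped < 0 || frac_palindromic < 0 ||
      frac_flipped + frac_palindromic > 1) {
    stop("fractions must be >= 0 and sum to <= 1", call. = FALSE)
  }
  rec <- stats$records
  n <- nrow(rec)
  n_flip <- round(frac_flipped * n)
  n_pal <- round(frac_palindromic * n)
  with_seed(seed, {
    chosen <- sample.int(n, n_flip + n_pal)
    flip_idx <- chosen[seq_len(n_flip)]
    pal_idx <- chosen[n_flip + seq_len(n_pal)]
    if (n_flip > 0) {
      ea <- rec$effect_allele[flip_idx]
      rec$effect_allele[flip_idx] <- rec$other_allele[flip_idx]
      rec$other_allele[flip_idx] <- ea
      rec$beta[flip_idx] <- -rec$beta[flip_idx]
      rec$eaf[flip_idx] <- 1 - rec$eaf[flip_idx]
    }
    if (n_pal > 0) {
      pal_pair <- matrix(c("A", "T", "G", "C"), ncol = 2L, byrow = TRUE)
      pick <- sample.int(2L, n_pal, replace = TRUE)
      rec$effect_allele[pal_idx] <- pal_pair[pick, 1L]
      rec$other_allele[pal_idx] <- pal_pair[pick, 2L]
    }
    out <- summary_stats(rec, stats$trait_id, stats$trait_class)
    attr(out, "modifications") <- data.frame(
      rsid = c(rec$rsid[flip_idx], rec$rsid[pal_idx]),
      type = rep(c("flipped", "palindromic"), c(n_flip, n_pal)))
    out
  })
}

#' Serialize truth parameters to a YAML sidecar
#'
#' @param truth a [truth_params()] object.
#' @param path YAML file path.
#' @return `path` invisibly; `read_truth_params()` returns the object.
#' @export
write_truth_params <- function(truth, path) {
  stopifnot(inherits(truth, "truth_params"))
  yaml::write_yaml(unclass(truth), path)
  invisible(path)
}

#' @rdname write_truth_params
#' @export
read_truth_params <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(truth_params, x[setdiff(names(x), "beta_total")])
}
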