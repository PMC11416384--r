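#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns SNP-exposure and SNP-outcome effects onto the exposure's effect
#' allele, the prerequisite of every two-sample MR estimator. For each
#' instrument:
#' \itemize{
#'   \item absent from the outcome: dropped (`dropped_missing_in_outcome`;
#'     proxy-SNP lookup is deliberately not attempted);
#'   \item palindromic allele pair (A/T or G/C) in either trait: dropped
#'     (`dropped_palindromic`) -- strand assignment is ambiguous and no
#'     frequency-based rescue is attempted;
#'   \item same alleles (directly or after strand complement): kept as is;
#'   \item swapped alleles (directly or after strand complement): outcome
#'     beta negated and its allele frequency reflected
#'     (`flipped_then_kept`);
#'   \item anything else: `dropped_ambiguous`.
#' }
#' All kept effects are expressed per copy of the exposure's effect allele;
#' harmonization never changes the magnitude of any kept effect.
#'
#' @param exposure_instruments a [summary_stats()] object of selected
#'   instruments (see [select_instruments()]).
#' @param outcome a [summary_stats()] object for the outcome trait.
#' @return An object of class `harmonized_pair`: list with `exposure_id`,
#'   `outcome_id`, `data` (data.frame rsid, gamma_hat, sigma_x, Gamma_hat,
#'   sigma_y, eaf_exposure, eaf_outcome) for the kept SNPs, and
#'   `provenance` (data.frame rsid, status) covering every input
#'   instrument.
#' @export
harmonize <- function(exposure_instruments, outcome) {
  stopifnot(inherits(exposure_instruments, "summary_stats"),
            inherits(outcome, "summary_stats"))
  ex <- exposure_instruments$records
  out <- outcome$records
  m <- match(ex$rsid, out$rsid)

  status <- character(nrow(ex))
  o_beta <- o_se <- o_eaf <- rep(NA_real_, nrow(ex))

  for (i in seq_len(nrow(ex))) {
    if (is.na(m[i])) {
      status[i] <- "dropped_missing_in_outcome"
      next
    }
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- out$effect_allele[m[i]]; o2 <- out$other_allele[m[i]]
    if (is_palindromic_pair(e1, e2) || is_palindromic_pair(o1, o2)) {
      status[i] <- "dropped_palindromic"
      next
    }
    c1 <- complement_allele(o1); c2 <- complement_allele(o2)
    if ((o1 == e1 && o2 == e2) || (c1 == e1 && c2 == e2)) {
      status[i] <- "kept"
      o_beta[i] <- out$beta[m[i]]
      o_eaf[i] <- out$eaf[m[i]]
    } else if ((o1 == e2 && o2 == e1) || (c1 == e2 && c2 == e1)) {
      status[i] <- "flipped_then_kept"
      o_beta[i] <- -out$beta[m[i]]
      o_eaf[i] <- 1 - out$eaf[m[i]]
    } else {
      status[i] <- "dropped_ambiguous"
      next
    }
    o_se[i] <- out$se[m[i]]
  }

  kept <- status %in% c("kept", "flipped_then_kept")
  if (!any(kept)) {
    stop(sprintf("harmonization of '%s' on '%s' retained zero SNPs",
                 exposure_instruments$trait_id, outcome$trait_id),
         call. = FALSE)
  }
  structure(
    list(
      exposure_id = exposure_instruments$trait_id,
      outcome_id = outcome$trait_id,
      data = data.frame(
        rsid = ex$rsid[kept],
        gamma_hat = ex$beta[kept], sigma_x = ex$se[kept],
        Gamma_hat = o_beta[kept], sigma_y = o_se[kept],
        eaf_exposure = ex$eaf[kept], eaf_outcome = o_eaf[kept]),
      provenance = data.frame(rsid = ex$rsid, status = status)),
    class = "harmonized_pair"
  )
}

#' @export
print.harmonized_pair <- function(x, ...) {
  tab <- table(x$provenance$status)
  cat(sprintf("<harmonized_pair> %s -> %s: %d SNPs kept of %d (%s)\n",
              x$exposure_id, x$outcome_id, nrow(x$data),
              nrow(x$provenance),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Build a harmonized pair directly from aligned effect arrays
#'
#' Constructor for callers who already hold allele-aligned SNP-exposure
#' and SNP-outcome effects (e.g. exported from another harmonization
#' tool, or simulated): skips file I/O and allele bookkeeping.
#'
#' @param gamma_hat,sigma_x SNP-exposure effects and SEs.
#' @param Gamma_hat,sigma_y SNP-outcome effects and SEs.
#' @param rsid optional variant ids.
#' @param exposure_id,outcome_id trait labels.
#' @return A `harmonized_pair` (all SNPs marked `kept`).
#' @export
harmonized_pair <- function(gamma_hat, sigma_x, Gamma_hat, sigma_y,
                            rsid = NULL,
                            exposure_id = "exposure",
                            outcome_id = "outcome") {
  n <- length(gamma_hat)
  stopifnot(length(sigma_x) == n, length(Gamma_hat) == n, length(sigma_y) == n,
            all(sigma_x > 0), all(sigma_y > 0))
  rsid <- rsid %||% sprintf("snp%04d", seq_len(n))
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id,
         data = data.frame(rsid = rsid, gamma_hat = gamma_hat,
                           sigma_x = sigma_x, Gamma_hat = Gamma_hat,
                           sigma_y = sigma_y,
                           eaf_exposure = NA_real_, eaf_outcome = NA_real_),
         provenance = data.frame(rsid = rsid, status = "kept")),
    class = "harmonized_pair")
}
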