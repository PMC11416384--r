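#' Single-SNP instrument-strength F statistic
#'
#' The conventional single-SNP approximation F = beta^2 / se^2; instruments
#' with F below 10 are conventionally regarded as weak. `literal = TRUE`
#' instead computes |beta| / se^2 (a non-standard reading of "ratio of the
#' effect size to the square of its standard error" occasionally seen in
#' applied reports); the default is the standard screen that the threshold
#' of 10 belongs to.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param literal use |beta|/se^2 instead of beta^2/se^2.
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se, literal = FALSE) {
  if (any(!is.finite(se) | se <= 0)) stop("`se` must be > 0", call. = FALSE)
  if (literal) abs(beta) / se^2 else (beta / se)^2
}

#' Select and clump instrumental variables
#'
#' Applies the standard instrument-selection cascade to one trait's GWAS:
#' genome-wide significance threshold, greedy LD clumping, then a weak-
#' instrument F filter. Clumping sorts candidates by ascending p-value
#' (ties broken by chromosome then position), repeatedly keeps the best
#' remaining SNP and removes every other candidate on the same chromosome
#' within `window_kb` kilobases whose squared correlation with it exceeds
#' `r2_threshold`. SNPs absent from the LD matrix are treated as
#' independent (with a message), so partial LD panels are usable.
#'
#' @param stats a [summary_stats()] object.
#' @param ld optional [simulate_ld_blocks()]-style `ld_matrix`; `NULL`
#'   treats all SNPs as independent.
#' @param p_threshold association p-value cutoff (default 1e-5).
#' @param r2_threshold squared-correlation clumping cutoff (default 0.001).
#' @param window_kb clumping window in kilobases (default 10000).
#' @param f_min minimum instrument F statistic (default 10).
#' @param f_literal see [f_statistic()].
#' @return A [summary_stats()] object containing the retained instruments,
#'   ordered by ascending p-value.
#' @export
select_instruments <- function(stats, ld = NULL, p_threshold = 1e-5,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_min = 10, f_literal = FALSE) {
  stopifnot(inherits(stats, "summary_stats"))
  rec <- stats$records
  cand <- rec[rec$pval < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop(sprintf("no instruments for trait '%s': no SNP passes p < %g",
                 stats$trait_id, p_threshold), call. = FALSE)
  }
  ord <- order(cand$pval, cand$chrom, cand$pos)
  cand <- cand[ord, , drop = FALSE]

  r2 <- NULL
  if (!is.null(ld)) {
    stopifnot(inherits(ld, "ld_matrix"))
    uncovered <- setdiff(cand$rsid, ld$rsids)
    if (length(uncovered)) {
      message(sprintf(
        "select_instruments: %d candidate SNP(s) absent from LD matrix treated as independent",
        length(uncovered)))
    }
    covered <- intersect(cand$rsid, ld$rsids)
    r2 <- ld$r[covered, covered, drop = FALSE]^2
  }

  keep <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  window_bp <- window_kb * 1000
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    if (!any(alive)) break
    j <- which(alive)
    same_chr <- cand$chrom[j] == cand$chrom[i]
    in_window <- abs(cand$pos[j] - cand$pos[i]) <= window_bp
    correlated <- rep(FALSE, length(j))
    if (!is.null(r2) && cand$rsid[i] %in% rownames(r2)) {
      jj <- match(cand$rsid[j], rownames(r2))
      correlated[!is.na(jj)] <- r2[cand$rsid[i], rownames(r2)[jj[!is.na(jj)]]] >
        r2_threshold
    }
    alive[j[same_chr & in_window & correlated]] <- FALSE
  }
  sel <- cand[keep, , drop = FALSE]

  f <- f_statistic(sel$beta, sel$se, literal = f_literal)
  weak <- f < f_min
  if (any(weak)) {
    message(sprintf("select_instruments: dropped %d weak instrument(s) (F < %g) for '%s'",
                    sum(weak), f_min, stats$trait_id))
    sel <- sel[!weak, , drop = FALSE]
  }
  if (nrow(sel) == 0L) {
    stop(sprintf("no instruments for trait '%s' survive clumping and the F >= %g filter",
                 stats$trait_id, f_min), call. = FALSE)
  }
  summary_stats(sel, stats$trait_id, stats$trait_class)
}
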