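#' GWAS summary statistics for one trait
#'
#' A `summary_stats` object holds the per-SNP association estimates of a
#' single GWAS: one row per variant with its alleles, effect-allele
#' frequency, additive effect (log-odds or SD units), standard error,
#' p-value and sample size. It is the raw material of every stage of the
#' MR pipeline.
#'
#' @param records data.frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` and `n` may be `NA`.
#' @param trait_id character label for the trait.
#' @param trait_class one of `"gut_microbiota"`, `"immune_cell"`,
#'   `"outcome"`, `"other"`.
#' @return An object of class `summary_stats` with elements `trait_id`,
#'   `trait_class` and `records`.
#' @export
summary_stats <- function(records, trait_id,
                          trait_class = c("other", "gut_microbiota",
                                          "immune_cell", "outcome")) {
  trait_class <- match.arg(trait_class)
  records <- validate_snp_records(as.data.frame(records), trait_id)
  structure(
    list(trait_id = as.character(trait_id), trait_class = trait_class,
         records = records),
    class = "summary_stats"
  )
}

MANDATORY_COLUMNS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "pval", "n")

validate_snp_records <- function(records, trait_id = "?") {
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop(sprintf("summary statistics for '%s' lack mandatory column(s): %s",
                 trait_id, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop(sprintf("summary statistics for '%s' contain no records", trait_id),
         call. = FALSE)
  }
  records$rsid <- as.character(records$rsid)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  dup <- unique(records$rsid[duplicated(records$rsid)])
  if (length(dup)) {
    stop(sprintf("duplicated rsid(s) in '%s': %s",
                 trait_id, paste(utils::head(dup, 5L), collapse = ", ")),
         call. = FALSE)
  }
  bad_alleles <- records$effect_allele == records$other_allele
  if (any(bad_alleles)) {
    stop(sprintf("identical effect/other alleles in '%s' (e.g. %s)",
                 trait_id, records$rsid[which(bad_alleles)[1L]]),
         call. = FALSE)
  }
  if (any(!is.finite(records$se) | records$se <= 0)) {
    stop(sprintf("non-positive or non-finite standard errors in '%s'",
                 trait_id), call. = FALSE)
  }
  if (any(!is.finite(records$pval) | records$pval <= 0 | records$pval > 1)) {
    stop(sprintf("p-values outside (0, 1] in '%s'", trait_id), call. = FALSE)
  }
  rownames(records) <- NULL
  records[MANDATORY_COLUMNS]
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s' (%s): %d SNPs\n",
              x$trait_id, x$trait_class, nrow(x$records)))
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads one trait's summary statistics. Rows with non-finite effect or
#' standard error, or `se <= 0`, are dropped with a message giving the
#' count. Alleles are upper-cased. Duplicated variant ids are an error.
#'
#' @param path path to a tab-separated file with a header row.
#' @param trait_id trait label; defaults to the file name.
#' @param trait_class see [summary_stats()].
#' @param column_map optional named character vector mapping the canonical
#'   column names (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval`, `n`) to the names used in the file.
#' @return A [summary_stats()] object.
#' @export
read_summary_stats <- function(path, trait_id = NULL,
                               trait_class = "other", column_map = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  trait_id <- trait_id %||% sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  if (nrow(dt) == 0L) {
    stop(sprintf("empty summary-statistics file: %s", path), call. = FALSE)
  }
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(dt)) {
        stop(sprintf("column '%s' (mapped to '%s') absent from %s",
                     src, canon, path), call. = FALSE)
      }
      names(dt)[names(dt) == src] <- canon
    }
  }
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(dt))
  if (length(missing_cols)) {
    stop(sprintf("file %s lacks mandatory column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  keep <- is.finite(dt$beta) & is.finite(dt$se) & dt$se > 0
  if (any(!keep)) {
    message(sprintf("read_summary_stats: dropped %d record(s) with invalid beta/se from '%s'",
                    sum(!keep), trait_id))
    dt <- dt[keep, , drop = FALSE]
  }
  if (nrow(dt) == 0L) {
    stop(sprintf("no usable records in %s after filtering", path), call. = FALSE)
  }
  summary_stats(dt, trait_id = trait_id, trait_class = trait_class)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Writes the canonical ten-column format read by [read_summary_stats()];
#' write-then-read round-trips all mandatory fields.
#'
#' @param stats a [summary_stats()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  data.table::fwrite(stats$records[MANDATORY_COLUMNS], path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}
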