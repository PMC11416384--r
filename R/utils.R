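# Internal helpers shared across the package.

# 97.5% normal quantile used for all 95% intervals (matches the convention
# of reporting exp(beta -/+ 1.959964 se) on the odds-ratio scale).
Z975 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a temporary RNG state so generators and bootstraps are
# reproducible without clobbering the caller's stream. seed = NULL leaves
# the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Two-sided p-value from a z statistic.
pval_z <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

stopifnot_scalar <- function(x, name, finite = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) unname(DNA_COMPLEMENT[x])

is_palindromic_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}
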