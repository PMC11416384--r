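# Shared fixtures: harmonized pairs built directly from effect arrays
# (bypassing file I/O and allele bookkeeping) and small summary-stats
# tables. Everything is generated in code under fixed seeds.

# A harmonized pair from the generative model
#   gamma_hat ~ N(gamma, sx^2),
#   Gamma_hat ~ N(beta*gamma + sign(gamma)*alpha, sy^2)
# with instrument effects gamma ~ N(0, gamma_sd^2) + gamma_floor on |gamma|.
# Pleiotropic offsets `alpha` are applied per exposure-increasing allele,
# matching the orientation on which the Egger intercept is defined.
make_pair <- function(J = 50, beta = 0.3, seed = 1, sx = 0.003, sy = 0.02,
                      gamma_sd = 0.05, gamma_floor = 0.02, alpha = 0) {
  withr::with_seed(seed, {
    gamma <- stats::rnorm(J, 0, gamma_sd)
    gamma <- gamma + sign(gamma) * gamma_floor
    sx <- rep_len(sx, J)
    sy <- rep_len(sy, J)
    alpha <- rep_len(alpha, J)
    harmonized_pair(
      gamma_hat = gamma + stats::rnorm(J, 0, sx),
      sigma_x = sx,
      Gamma_hat = beta * gamma + sign(gamma) * alpha + stats::rnorm(J, 0, sy),
      sigma_y = sy)
  })
}

# A pair with fixed Wald ratios: gamma_hat = 1 with negligible
# SNP-exposure noise, so ratio_j = Gamma_hat_j and ratio SE = sy_j.
make_ratio_pair <- function(ratios, sy = rep(1, length(ratios))) {
  J <- length(ratios)
  harmonized_pair(gamma_hat = rep(1, J), sigma_x = rep(1e-9, J),
                  Gamma_hat = ratios, sigma_y = sy)
}

# A minimal well-formed summary-stats record table.
make_records <- function(n = 3, rsid = sprintf("rs%d", seq_len(n)),
                         chrom = "1", pos = seq_len(n) * 1e6,
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, beta = 0.1, se = 0.01,
                         pval = 1e-8, nn = 10000) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = nn)
}

# Independent brute-force weighted-median oracle: explicit bracketing and
# linear interpolation, no shared code with the implementation.
oracle_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  s <- numeric(length(x))
  acc <- 0
  for (i in seq_along(x)) {
    s[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (s[1] >= 0.5) return(x[1])
  for (i in 2:length(x)) {
    if (s[i] >= 0.5) {
      return(x[i - 1] + (x[i] - x[i - 1]) * (0.5 - s[i - 1]) / (s[i] - s[i - 1]))
    }
  }
  x[length(x)]
}
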