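test_that("Wald ratios match their closed form and symmetries", {
  wr <- wald_ratio(0.1, 0.01, 0.2, 0.05)
  expect_equal(wr$estimate, 2.0)
  expect_equal(wr$se, 0.5)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.05)$estimate, 0)
  expect_equal(wald_ratio(-0.1, 0.01, -0.2, 0.05)$estimate, 2.0)
  so <- wald_ratio(0.1, 0.01, 0.2, 0.05, second_order = TRUE)
  expect_gte(so$se, 0.5)
  expect_equal(so$se, sqrt(0.05^2 / 0.1^2 + 0.2^2 * 0.01^2 / 0.1^4))
  expect_error(wald_ratio(0, 0.01, 0.2, 0.05), "zero")
})

test_that("IVW equals the closed-form weighted mean of Wald ratios", {
  pair <- make_ratio_pair(c(0.5, 0.3), sy = c(0.1, 0.2))
  fe <- mr_ivw(pair, "fe")
  expect_equal(fe$beta, 0.46, tolerance = 1e-9)
  expect_equal(fe$se, 1 / sqrt(125), tolerance = 1e-9)
  # Q/(J-1) = 0.8 < 1, so the multiplicative-random SE hits the floor
  mre <- mr_ivw(pair, "mre")
  expect_equal(mre$q_stat, 0.8, tolerance = 1e-9)
  expect_equal(mre$se, fe$se)
  expect_error(mr_ivw(make_ratio_pair(1)), "2 SNPs")
})

test_that("IVW agrees with an origin-constrained WLS oracle", {
  for (seed in 1:50) {
    pair <- make_pair(J = 20, beta = runif(1, -1, 1), seed = seed,
                      sy = runif(20, 0.01, 0.1))
    d <- pair$data
    oracle <- stats::coef(stats::lm(Gamma_hat ~ 0 + gamma_hat, data = d,
                                    weights = 1 / d$sigma_y^2))[[1]]
    expect_equal(mr_ivw(pair, "fe")$beta, oracle, tolerance = 1e-10)
  }
})

test_that("all estimators return the common value on homogeneous ratios", {
  pair <- make_ratio_pair(rep(0.7, 6))
  expect_equal(mr_ivw(pair, "fe")$beta, 0.7)
  expect_equal(mr_ivw(pair, "mre")$beta, 0.7)
  expect_equal(mr_ivw(pair, "mre")$q_stat, 0, tolerance = 1e-18)
  expect_equal(mr_weighted_median(pair, n_boot = 50)$beta, 0.7)
  modes <- mr_modes(pair, n_boot = 50)
  expect_equal(modes$simple_mode$beta, 0.7)
  expect_equal(modes$weighted_mode$beta, 0.7)
})

test_that("MR-Egger recovers an exact affine relationship", {
  g <- seq(0.05, 0.5, length.out = 10)
  pair <- harmonized_pair(g, rep(1e-6, 10), 0.1 + 0.5 * g, rep(0.05, 10))
  fit <- mr_egger(pair)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_error(mr_egger(make_ratio_pair(c(1, 2))), "3 SNPs")
})

test_that("Egger pre-orientation makes the fit sign-consistent", {
  # flipping the sign of individual SNP pairs must not change the fit
  g <- c(-0.3, 0.2, -0.1, 0.4, 0.25)
  pair1 <- harmonized_pair(g, rep(1e-6, 5), 0.4 * g + 0.05 * sign(g),
                           rep(0.03, 5))
  pair2 <- pair1
  pair2$data$gamma_hat <- -pair2$data$gamma_hat
  pair2$data$Gamma_hat <- -pair2$data$Gamma_hat
  f1 <- mr_egger(pair1)
  f2 <- mr_egger(pair2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)
})

test_that("weighted median interpolates the weighted ratio distribution", {
  pair <- make_ratio_pair(c(1, 2, 3, 4, 5))
  expect_equal(mr_weighted_median(pair, n_boot = 50)$beta, 3)
  # brute-force oracle over random weight configurations
  withr::with_seed(99, {
    for (i in 1:50) {
      J <- sample(3:12, 1)
      ratios <- rnorm(J)
      sy <- runif(J, 0.2, 2)
      pair <- make_ratio_pair(ratios, sy = sy)
      est <- mr_weighted_median(pair, n_boot = 2)
      expect_equal(est$beta, oracle_weighted_median(ratios, 1 / sy^2),
                   tolerance = 1e-10)
    }
  })
})

test_that("weighted median resists a minority pleiotropic cluster", {
  # 40% of SNPs (the weaker instruments, carrying ~12% of the weight)
  # share a large common offset: the weighted median stays within 2 SE of
  # truth while IVW is pulled many SEs away
  res <- vapply(1:40, function(seed) {
    gamma <- seq(0.05, 0.3, length.out = 20)
    alpha <- c(rep(0.1, 8), rep(0, 12))  # contaminate the weak 40%
    withr::with_seed(seed, {
      pair <- harmonized_pair(
        gamma_hat = gamma + rnorm(20, 0, 0.003), sigma_x = rep(0.003, 20),
        Gamma_hat = 0.3 * gamma + alpha + rnorm(20, 0, 0.01),
        sigma_y = rep(0.01, 20))
    })
    med <- mr_weighted_median(pair, n_boot = 100, seed = seed)
    ivw <- mr_ivw(pair, "fe")
    c(med_ok = abs(med$beta - 0.3) < 2 * med$se,
      ivw_off = abs(ivw$beta - 0.3) > 2 * ivw$se,
      med_dev = abs(med$beta - 0.3),
      ivw_dev = abs(ivw$beta - 0.3))
  }, numeric(4))
  expect_gte(mean(res["med_ok", ]), 0.9)
  expect_gte(mean(res["ivw_off", ]), 0.9)
  expect_lt(mean(res["med_dev", ]), mean(res["ivw_dev", ]))
})

test_that("mode estimators find the dominant ratio cluster", {
  pair <- make_ratio_pair(c(2, 2, 2, 9))
  modes <- mr_modes(pair, n_boot = 20)
  expect_lt(abs(modes$simple_mode$beta - 2), 0.1)
  # equal weights: the two mode variants coincide
  expect_equal(modes$simple_mode$beta, modes$weighted_mode$beta)
  # bandwidth scaling keeps the estimate inside the ratio range (up to
  # one step of the 512-point density grid)
  for (phi in c(0.5, 1, 2, 4)) {
    m <- mr_modes(pair, phi = phi, n_boot = 2)
    expect_gte(m$simple_mode$beta, 2 - 0.05)
    expect_lte(m$simple_mode$beta, 9 + 0.05)
  }
  expect_error(mr_modes(make_ratio_pair(c(1, 2))), "3 SNPs")
})

test_that("estimators are exactly sign-equivariant in the outcome", {
  pair <- make_pair(J = 30, beta = 0.4, seed = 8)
  neg <- pair
  neg$data$Gamma_hat <- -neg$data$Gamma_hat
  expect_equal(mr_ivw(neg)$beta, -mr_ivw(pair)$beta)
  expect_equal(mr_egger(neg)$beta, -mr_egger(pair)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(neg)$intercept, -mr_egger(pair)$intercept,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(neg, n_boot = 2)$beta,
               -mr_weighted_median(pair, n_boot = 2)$beta)
  expect_equal(mr_modes(neg, n_boot = 2)$weighted_mode$beta,
               -mr_modes(pair, n_boot = 2)$weighted_mode$beta,
               tolerance = 1e-12)
  expect_equal(fit_bwmr(neg)$beta, -fit_bwmr(pair)$beta, tolerance = 1e-10)
})

test_that("odds-ratio conversion matches the log-normal interval", {
  expect_equal(round(to_odds_ratio(-0.966, 0.1)$or_value, 3), 0.381)
  or0 <- to_odds_ratio(0, 0.2)
  expect_equal(or0$or_value, 1)
  expect_equal(or0$ci_low * or0$ci_high, 1, tolerance = 1e-12)
  or <- to_odds_ratio(0.2, 0.1)
  expect_equal(or$ci_low, exp(0.2 - 1.959964 * 0.1))
  expect_equal(or$ci_high, exp(0.2 + 1.959964 * 0.1))
  expect_error(to_odds_ratio(0.1, 0), "se")
})

test_that("estimators recover the causal effect on clean simulations", {
  methods <- c("ivw", "egger", "median", "simple_mode", "weighted_mode",
               "bwmr")
  hits <- matrix(0, 120, length(methods),
                 dimnames = list(NULL, methods))
  for (i in seq_len(120)) {
    beta_true <- withr::with_seed(1000 + i, runif(1, -0.8, 0.8))
    pair <- make_pair(J = 60, beta = beta_true, seed = i, sy = 0.015)
    within2 <- function(e) abs(e$beta - beta_true) < 2 * e$se
    modes <- mr_modes(pair, n_boot = 80, seed = i)
    hits[i, ] <- c(within2(mr_ivw(pair)),
                   within2(mr_egger(pair)),
                   within2(mr_weighted_median(pair, n_boot = 80, seed = i)),
                   within2(modes$simple_mode),
                   within2(modes$weighted_mode),
                   within2(fit_bwmr(pair)))
  }
  for (m in methods) expect_gte(mean(hits[, m]), 0.93)
})

test_that("the tidy estimate table carries one row per method", {
  pair <- make_pair(J = 25, beta = 0.2, seed = 4)
  tab <- mr_all_methods(pair, n_boot = 50)
  expect_setequal(tab$method, c("ivw_mre", "ivw_fe", "egger",
                                "weighted_median", "simple_mode",
                                "weighted_mode", "bwmr"))
  expect_true(all(tab$or == exp(tab$beta)))
  expect_true(all(tab$ci_low <= tab$or & tab$or <= tab$ci_high))
  expect_true(all(tab$nsnp == 25))
})
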