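test_that("composite likelihoods match brute-force per-SNP mixture densities", {
  set.seed(20)
  m <- 500
  ld <- simulate_ld_blocks(m, 5, 0.7)
  arch <- architecture_params(m, pi_a = 0.02, pi_b = 0.03, pi_ab = 0.02,
                              rho_shared = 0.6, seed = 22)
  sim <- simulate_bivariate_sumstats(arch, ld)
  z1 <- sim$sumstats_a$z
  z2 <- sim$sumstats_b$z

  # univariate: grouped composite likelihood vs direct per-SNP evaluation
  grp <- crosstraitr:::ld_groups(z1, ld$ld_score)
  ll_pkg <- crosstraitr:::uni_loglik(0.04, 1e-4, 1.02, 1e5, grp)
  ll_ref <- brute_uni_loglik(z1, ld$ld_score, 0.04, 1e-4, 1.02, 1e5)
  expect_equal(ll_pkg, ll_ref, tolerance = 1e-10)

  # bivariate 4-component likelihood vs triple-loop evaluation
  grp2 <- crosstraitr:::biv_groups(z1, z2, ld$ld_score)
  fx <- list(s2a = 1e-4, s2b = 2e-4, s0a = 1.0, s0b = 1.05,
             n_a = 1e5, n_b = 8e4)
  ll_pkg2 <- crosstraitr:::biv_loglik(0.02, 0.03, 0.015, 0.5, 0.1, fx, grp2)
  ll_ref2 <- brute_biv_loglik(z1, z2, ld$ld_score, 0.02, 0.03, 0.015, 0.5,
                              0.1, fx$s2a, fx$s2b, fx$s0a, fx$s0b,
                              fx$n_a, fx$n_b)
  expect_equal(ll_pkg2, ll_ref2, tolerance = 1e-8)
})

test_that("univariate fit recovers polygenicity and inflation on simulated data", {
  m <- 100000
  ld <- simulate_ld_blocks(m, 1, 0)
  arch <- architecture_params(m, pi_a = 0.003, sigma2_a = 1e-4, seed = 23)
  sim <- simulate_bivariate_sumstats(arch, ld)
  fit <- fit_univariate(sim$sumstats_a, seed = 1)
  expect_gt(fit$pi, 0.003 / 2)
  expect_lt(fit$pi, 0.003 * 2)
  expect_lt(abs(fit$sigma0 - 1), 0.05)
  expect_equal(fit$aic, 6 - 2 * fit$loglik)
  expect_lte(fit$n_causal, fit$m)

  # pure-null data: no causal variants and no likelihood gain over pi = 0
  # (the pi/sigma2 product itself is unidentified on the boundary ridge)
  sim0 <- simulate_bivariate_sumstats(architecture_params(m, seed = 24), ld)
  fit0 <- fit_univariate(sim0$sumstats_a, seed = 1)
  expect_lt(fit0$n_causal, 1)
  ll_null <- univariate_loglik(fit0, pi = 1e-30)
  expect_lt(fit0$loglik - ll_null, 3)

  # the full model beats a near-zero-polygenicity submodel by AIC
  ll_constrained <- univariate_loglik(fit, pi = 1e-7)
  expect_lt(fit$aic, 2 * 3 - 2 * ll_constrained)
})

test_that("bivariate fit separates unique and shared architectures", {
  m <- 50000
  ld <- simulate_ld_blocks(m, 1, 0)

  fit_for <- function(arch) {
    sim <- simulate_bivariate_sumstats(arch, ld)
    pair <- harmonize_pair(sim$sumstats_a, sim$sumstats_b)
    tabs <- pair_tables(pair)
    fa <- fit_univariate(tabs$a, seed = 1)
    fb <- fit_univariate(tabs$b, seed = 2)
    fit_bivariate(pair, fa, fb, seed = 3, n_boot = 0, n_starts = 4)
  }

  # disjoint architectures: negligible Dice
  disjoint <- fit_for(architecture_params(m, pi_a = 0.004, pi_b = 0.004,
                                          seed = 25))
  expect_lte(disjoint$dice, 0.02)

  # fully shared architecture: Dice near 1
  shared <- fit_for(architecture_params(m, pi_ab = 0.004, rho_shared = 0.9,
                                        seed = 26))
  expect_gte(shared$dice, 0.9)
  expect_lt(shared$aic, shared$aic_no_overlap)

  # count conservation: unique + shared = total causal proportion times M
  expect_equal(shared$n_a_only + shared$n_shared,
               (shared$pi_a + shared$pi_ab) * shared$m, tolerance = 1e-9)
})

test_that("overlap summaries implement the Dice and shared-fraction arithmetic", {
  expect_equal(dice_coefficient(500, 300, 4900), 0.1)
  expect_equal(dice_coefficient(0, 7, 0), 1)
  expect_error(dice_coefficient(-1, 1, 1), class = "crosstraitr_invalid_parameter")

  s <- derive_overlap_summary(c(n_a_only = 500, n_shared = 300,
                                n_b_only = 4900))
  expect_equal(s$shared_fraction_a, 37.5)
  expect_equal(s$dice, 0.1)
  expect_equal(s$venn_thousands, c(0.5, 0.3, 4.9))

  td <- tidy(s)
  expect_equal(td$estimate[td$term == "shared_fraction_a"], 37.5)
})

test_that("likelihood surface over the shared proportion peaks near the estimate", {
  m <- 20000
  ld <- simulate_ld_blocks(m, 1, 0)
  sim <- simulate_bivariate_sumstats(
    architecture_params(m, pi_ab = 0.005, rho_shared = 0.8, seed = 27), ld)
  pair <- harmonize_pair(sim$sumstats_a, sim$sumstats_b)
  tabs <- pair_tables(pair)
  fit <- fit_bivariate(pair, fit_univariate(tabs$a, seed = 1),
                       fit_univariate(tabs$b, seed = 2),
                       seed = 3, n_boot = 2, n_starts = 3)
  s <- derive_overlap_summary(fit)
  surf <- s$loglik_surface
  expect_equal(nrow(surf), 21L)
  best_grid <- surf$pi_ab[which.max(surf$loglik)]
  expect_lt(abs(best_grid - fit$pi_ab), diff(range(surf$pi_ab)) / 4)
  expect_true(is.finite(fit$dice_se) && fit$dice_se >= 0)
})
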