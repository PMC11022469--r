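test_that("propensity scores reduce to analytic values in degenerate designs", {
  # constant covariates: every score equals the exposure prevalence
  cohort <- tibble::tibble(id = 1:200, x = 1,
                           exposure = rep(c(1, 0), c(60, 140)))
  scored <- estimate_propensity(cohort, "x")
  expect_equal(scored$pscore, rep(0.3, 200), tolerance = 1e-6)

  # single binary covariate: scores reproduce stratum prevalences
  set.seed(33)
  cohort2 <- tibble::tibble(id = 1:1000, x = rep(0:1, each = 500))
  cohort2$exposure <- rbinom(1000, 1, ifelse(cohort2$x == 1, 0.4, 0.1))
  scored2 <- estimate_propensity(cohort2, "x")
  expect_equal(length(unique(round(scored2$pscore, 10))), 2L)
  strat <- tapply(scored2$exposure, cohort2$x, mean)
  expect_equal(sort(unique(round(scored2$pscore, 6))),
               sort(round(as.numeric(strat), 6)), tolerance = 1e-6)

  # known-model coefficient recovery at n = 50,000
  cohort3 <- simulate_epi_cohort(cohort_params(50000, seed = 34))
  p <- cohort_params(50000, seed = 34)
  scored3 <- estimate_propensity(cohort3, names(p$beta_exposure))
  coefs <- attr(scored3, "ps_coefficients")[names(p$beta_exposure)]
  expect_true(all(abs(coefs - p$beta_exposure) < 0.1))

  # separation raises a class-tagged error advising the penalized fallback
  sep <- tibble::tibble(id = 1:50, x = rep(0:1, each = 25),
                        exposure = rep(0:1, each = 25))
  expect_error(estimate_propensity(sep, "x"), class = "crosstraitr_separation")
  scored_pen <- estimate_propensity(sep, "x", penalized = TRUE)
  expect_true(all(scored_pen$pscore > 0 & scored_pen$pscore < 1))
})

test_that("nearest-neighbour matching honours the caliper and is canonical", {
  base <- tibble::tibble(
    id = 1:3, exposure = c(1, 0, 0),
    pscore = plogis(c(0, 0.05, 2)), lps = c(0, 0.05, 2)
  )
  attr(base, "ps_covariates") <- character(0)
  m <- match_1to1(base, caliper = Inf, seed = 1)
  expect_equal(m$pairs$control_id, 2L)          # nearest neighbour

  # control beyond the caliper leaves that exposed subject unmatched
  far <- tibble::tibble(id = 1:4, exposure = c(1, 1, 0, 0),
                        pscore = 0.5, lps = c(0, 5, 0.2, 5.01))
  attr(far, "ps_covariates") <- character(0)
  m2 <- match_1to1(far, caliper = 0.01, seed = 1)
  expect_equal(nrow(m2$pairs), 1L)
  expect_equal(m2$pairs$exposed_id, 2L)
  expect_equal(m2$n_unmatched_exposed, 1L)
  expect_true(all(m2$pairs$distance <= m2$caliper_logit))

  # no pairs at all is a hard error
  none <- tibble::tibble(id = 1:2, exposure = c(1, 0),
                         pscore = 0.5, lps = c(-10, 10))
  attr(none, "ps_covariates") <- character(0)
  expect_error(match_1to1(none, caliper = 0.1, seed = 1),
               class = "crosstraitr_no_pairs")

  # deterministic under seed, invariant to row permutation
  cohort <- simulate_epi_cohort(cohort_params(4000, seed = 35))
  scored <- estimate_propensity(cohort, cohort_covariates())
  m3 <- match_1to1(scored, seed = 7)
  m4 <- match_1to1(scored[sample(nrow(scored)), ], seed = 7)
  expect_identical(m3$pairs, m4$pairs)
})

test_that("matching balances confounded cohorts and never worsens SMDs", {
  cohort <- simulate_epi_cohort(cohort_params(50000, true_or = 2, seed = 36))
  scored <- estimate_propensity(cohort, cohort_covariates())
  m <- match_1to1(scored, seed = 8)
  expect_true(all(abs(m$balance$smd_after) < 0.1))

  # across seeds: post-match |SMD| <= pre-match |SMD| for confounded covariates
  for (s in 1:3) {
    co <- simulate_epi_cohort(cohort_params(8000, true_or = 2, seed = 40 + s))
    sc <- estimate_propensity(co, cohort_covariates())
    mm <- match_1to1(sc, seed = s)
    conf <- mm$balance[abs(mm$balance$smd_before) > 0.05, ]
    expect_true(all(abs(conf$smd_after) <= abs(conf$smd_before)))
  }
})

test_that("odds-ratio estimates agree with closed forms and recover truth", {
  # crude 2x2: OR = ad/bc exactly, for several tables
  for (cells in list(c(30, 70, 10, 90), c(12, 40, 9, 77), c(55, 45, 25, 75))) {
    d <- tibble::tibble(
      exposure = rep(c(1, 1, 0, 0), cells),
      outcome = rep(c(1, 0, 1, 0), cells)
    )
    est <- fit_or(d, list(label = "crude", outcome = "outcome",
                          exposure = "exposure", covariates = character(0)))
    expect_equal(est$or, (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-8)
  }

  # adjusted estimate near the true conditional OR, with collinearity report
  cohort <- simulate_epi_cohort(cohort_params(50000, true_or = 2, seed = 37))
  est2 <- fit_or(cohort, model_spec("model2"))
  expect_lt(abs(est2$or - 2), 0.2)
  cm <- attr(est2, "collinearity")
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.5))
})

test_that("interaction tests calibrate under the null and detect modification", {
  spec <- model_spec("model1")
  # null: interaction p-values approximately uniform across replicates
  ps <- vapply(1:40, function(s) {
    co <- simulate_epi_cohort(cohort_params(4000, true_or = 2, seed = 300 + s))
    interaction_test(co, spec, "gender")$p_interaction
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # strong modification (OR ratio 2 between strata) is detected at n = 50,000
  hits <- vapply(1:5, function(s) {
    co <- simulate_epi_cohort(cohort_params(50000, true_or = 2, seed = 400 + s))
    boost <- co$gender == 1 & co$exposure == 1
    pb <- mean(co$outcome[boost])
    set.seed(500 + s)
    co$outcome[boost] <- rbinom(sum(boost), 1, plogis(qlogis(pb) + log(2)))
    interaction_test(co, spec, "gender")$p_interaction < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  co1 <- simulate_epi_cohort(cohort_params(1000, seed = 38))
  co1$gender <- 1
  expect_error(interaction_test(co1, spec, "gender"), "one level")
})

test_that("sensitivity variants filter as stated and propagate hard errors", {
  cohort <- simulate_epi_cohort(cohort_params(20000, true_or = 2, seed = 39))
  primary <- run_matched_analysis(cohort, model_spec("model2"), seed = 11)

  strict <- run_sensitivity(cohort, "strict-hearing-definition",
                            model_spec("model2"), seed = 11)
  expect_gt(strict$or, primary$estimate$ci_low * 0.8)
  expect_lt(strict$or, primary$estimate$ci_high * 1.2)

  nosurg <- run_sensitivity(cohort, "exclude-surgery",
                            model_spec("model2"), seed = 11)
  prov <- attr(nosurg, "filter_provenance")
  expect_equal(prov$n_removed, sum(cohort$surgery == 1))
  expect_gt(nosurg$or, 1.5)

  # a variant with no filtered subjects reproduces the primary analysis
  cohort0 <- dplyr::mutate(cohort, surgery = 0L)
  same <- run_sensitivity(cohort0, "exclude-surgery",
                          model_spec("model2"), seed = 11)
  expect_equal(same$or, primary$estimate$or)

  # removing every exposed subject propagates a hard matching error
  all_surg <- dplyr::mutate(cohort, surgery = exposure)
  expect_error(run_sensitivity(all_surg, "exclude-surgery",
                               model_spec("model2"), seed = 11),
               class = "crosstraitr_sensitivity_error")
})
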