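#' Specify a confounded binary-cohort generative model
#'
#' Parameters for a synthetic observational cohort with a binary exposure
#' (e.g. documented cataract), a binary outcome (e.g. self-reported hearing
#' difficulty) and measured confounders. Exposure probability is logistic in
#' the confounders; outcome probability is logistic in the confounders plus
#' the exposure with log-odds `log(true_or)`, so `true_or` is the known
#' conditional odds ratio the analysis stage should recover.
#'
#' @param n_subjects Cohort size.
#' @param true_or True conditional odds ratio of exposure on outcome (> 0).
#' @param prevalence Baseline outcome prevalence at covariate means, in (0,1).
#' @param exposure_prevalence Baseline exposure prevalence at covariate means.
#' @param beta_exposure,beta_outcome Named numeric vectors of confounder
#'   effects (log-odds per unit of the standardized covariate) on exposure and
#'   outcome. Names must be a subset of the generated covariates: `age`,
#'   `gender`, `ethnicity`, `townsend`, `education`, `smoking`, `alcohol`,
#'   `obesity`, `physical_activity`, `hypertension`, `diabetes`,
#'   `hyperlipidemia`. Defaults induce confounding through age, smoking,
#'   diabetes and townsend.
#' @param seed Integer seed (mandatory).
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects,
                          true_or = 2,
                          prevalence = 0.3,
                          exposure_prevalence = 0.15,
                          beta_exposure = c(age = 0.6, smoking = 0.4,
                                            diabetes = 0.5, townsend = 0.3),
                          beta_outcome = c(age = 0.5, smoking = 0.4,
                                           diabetes = 0.4, townsend = 0.3),
                          seed) {
  assert_that(n_subjects >= 1, "`n_subjects` must be positive.")
  assert_that(true_or > 0, "`true_or` must be positive.")
  assert_prob(prevalence, "prevalence", lo_open = TRUE, hi_open = TRUE)
  assert_prob(exposure_prevalence, "exposure_prevalence",
              lo_open = TRUE, hi_open = TRUE)
  known <- cohort_covariates()
  assert_that(all(names(beta_exposure) %in% known) &&
                all(names(beta_outcome) %in% known),
              "confounder effect names must match generated covariates.")
  seed <- assert_seed(seed)
  structure(
    list(n_subjects = as.integer(n_subjects), true_or = true_or,
         prevalence = prevalence, exposure_prevalence = exposure_prevalence,
         beta_exposure = beta_exposure, beta_outcome = beta_outcome,
         seed = seed),
    class = "cohort_params"
  )
}

#' Covariates generated by the cohort simulator
#' @return Character vector of covariate column names.
#' @export
cohort_covariates <- function() {
  c("age", "gender", "ethnicity", "townsend", "education", "smoking",
    "alcohol", "obesity", "physical_activity", "hypertension", "diabetes",
    "hyperlipidemia")
}

#' Simulate a confounded exposure/outcome cohort
#'
#' Generates per-subject covariates (continuous `age` and `townsend`, the rest
#' binary), then a binary `exposure` and binary `outcome` under the logistic
#' models described in [cohort_params()]. Two auxiliary columns support
#' sensitivity analyses: `outcome_strict` (a stricter case definition that
#' thins cases at random, leaving the conditional exposure effect unchanged)
#' and `surgery` (an indicator among the exposed, used to exclude
#' surgically-treated subjects).
#'
#' @param params A [cohort_params()] object.
#' @return A tibble with one row per subject: `id`, the covariates of
#'   [cohort_covariates()] (age and townsend standardized), `exposure`,
#'   `outcome`, `outcome_strict`, `surgery`.
#' @examples
#' cohort <- simulate_epi_cohort(cohort_params(5000, true_or = 2, seed = 1))
#' mean(cohort$exposure)
#' @export
simulate_epi_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  withr::local_seed(params$seed)
  n <- params$n_subjects

  covs <- tibble::tibble(
    age = rnorm(n),                       # standardized
    gender = rbinom(n, 1, 0.54),
    ethnicity = rbinom(n, 1, 0.94),
    townsend = rnorm(n),
    education = rbinom(n, 1, 0.34),
    smoking = rbinom(n, 1, 0.45),
    alcohol = rbinom(n, 1, 0.95),
    obesity = rbinom(n, 1, 0.25),
    physical_activity = rbinom(n, 1, 0.82),
    hypertension = rbinom(n, 1, 0.73),
    diabetes = rbinom(n, 1, 0.06),
    hyperlipidemia = rbinom(n, 1, 0.46)
  )

  lp_of <- function(beta, intercept) {
    lp <- rep(intercept, n)
    for (nm in names(beta)) {
      x <- covs[[nm]]
      lp <- lp + beta[[nm]] * (x - mean(x))  # centered: intercept = baseline
    }
    lp
  }

  lp_e <- lp_of(params$beta_exposure, qlogis(params$exposure_prevalence))
  exposure <- rbinom(n, 1, plogis(lp_e))

  lp_y <- lp_of(params$beta_outcome, qlogis(params$prevalence)) +
    log(params$true_or) * exposure
  outcome <- rbinom(n, 1, plogis(lp_y))

  # strict definition: cases must also endorse a second item, independent of
  # exposure given case status -> conditional OR approximately preserved
  outcome_strict <- as.integer(outcome == 1L & rbinom(n, 1, 0.55) == 1L)
  surgery <- as.integer(exposure == 1L & rbinom(n, 1, 0.5) == 1L)

  dplyr::bind_cols(
    tibble::tibble(id = seq_len(n)), covs,
    tibble::tibble(exposure = exposure, outcome = outcome,
                   outcome_strict = outcome_strict, surgery = surgery)
  )
}
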