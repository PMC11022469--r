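#' Covariate specification for the association models
#'
#' The two standard adjustment sets: `model1` adjusts for age and gender
#' only; `model2` additionally adjusts for ethnicity, Townsend deprivation
#' index, educational attainment, smoking, alcohol consumption, obesity,
#' physical activity and history of hypertension, diabetes and
#' hyperlipidemia.
#'
#' @param label `"model1"` or `"model2"`.
#' @param outcome,exposure Column names of the outcome and exposure.
#' @return A list of class `model_spec` with `label`, `outcome`, `exposure`,
#'   `covariates`.
#' @export
model_spec <- function(label = c("model1", "model2"),
                       outcome = "outcome", exposure = "exposure") {
  label <- match.arg(label)
  covariates <- switch(
    label,
    model1 = c("age", "gender"),
    model2 = c("age", "gender", "ethnicity", "townsend", "education",
               "smoking", "alcohol", "obesity", "physical_activity",
               "hypertension", "diabetes", "hyperlipidemia")
  )
  structure(list(label = label, outcome = outcome, exposure = exposure,
                 covariates = covariates),
            class = "model_spec")
}

#' Adjusted odds ratio of exposure on outcome
#'
#' Maximum-likelihood logistic regression of the outcome on the exposure and
#' the specification's covariates; the exposure's odds ratio is reported with
#' a Wald 95% confidence interval on the log-odds scale and a two-sided
#' p-value. A pairwise correlation report of the model covariates (the
#' multicollinearity check) is attached as attribute `"collinearity"`.
#'
#' @param data Cohort or matched-cohort data tibble.
#' @param spec A [model_spec()] (or any list with `outcome`, `exposure`,
#'   `covariates`, `label`).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble of class `or_estimate`: `model`, `or`, `ci_low`,
#'   `ci_high`, `p`, `n`, `n_exposed`, `n_cases`.
#' @examples
#' cohort <- simulate_epi_cohort(cohort_params(20000, true_or = 2, seed = 4))
#' fit_or(cohort, model_spec("model2"))
#' @export
fit_or <- function(data, spec, conf_level = 0.95) {
  if (inherits(data, "matched_cohort")) data <- data$data
  vars <- c(spec$outcome, spec$exposure, spec$covariates)
  assert_that(all(vars %in% names(data)), "model columns missing from data.")
  assert_that(all(data[[spec$outcome]] %in% 0:1) &&
                all(data[[spec$exposure]] %in% 0:1),
              "outcome and exposure must be binary 0/1.")
  rhs <- paste(c(spec$exposure, spec$covariates), collapse = " + ")
  fml <- as.formula(paste(spec$outcome, "~", rhs))
  fit <- glm(fml, data = data, family = binomial(),
             control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  if (!fit$converged) {
    rlang::abort("logistic model did not converge.",
                 class = "crosstraitr_nonconvergence",
                 trace_coefficients = coef(fit))
  }
  est <- coef(fit)[[spec$exposure]]
  se <- sqrt(vcov(fit)[spec$exposure, spec$exposure])
  zc <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    model = spec$label,
    or = exp(est),
    ci_low = exp(est - zc * se),
    ci_high = exp(est + zc * se),
    p = 2 * pnorm(-abs(est / se)),
    n = nrow(data),
    n_exposed = sum(data[[spec$exposure]] == 1),
    n_cases = sum(data[[spec$outcome]] == 1)
  )
  class(out) <- c("or_estimate", class(out))
  if (length(spec$covariates) >= 2) {
    cm <- suppressWarnings(cor(data[, spec$covariates]))
    attr(out, "collinearity") <- cm
  }
  out
}

#' Likelihood-ratio test for effect modification
#'
#' Adds the exposure-by-modifier product term to the specification's model
#' and compares the two fits with a likelihood-ratio test.
#'
#' @param data Cohort tibble.
#' @param spec A [model_spec()].
#' @param modifier Column name of the (binary or categorical) effect
#'   modifier; must take at least two observed levels.
#' @return One-row tibble: `modifier`, `p_interaction`, `df`, `deviance_drop`.
#' @export
interaction_test <- function(data, spec, modifier) {
  if (inherits(data, "matched_cohort")) data <- data$data
  assert_that(modifier %in% names(data), "modifier column missing.")
  lv <- unique(data[[modifier]][!is.na(data[[modifier]])])
  if (length(lv) < 2) {
    rlang::abort("modifier has one level; no interaction is estimable.",
                 class = "crosstraitr_invalid_parameter")
  }
  covs <- setdiff(spec$covariates, modifier)
  base_rhs <- paste(c(spec$exposure, modifier, covs), collapse = " + ")
  f0 <- as.formula(paste(spec$outcome, "~", base_rhs))
  f1 <- as.formula(paste(spec$outcome, "~", base_rhs, "+",
                         spec$exposure, ":", modifier))
  fit0 <- glm(f0, data = data, family = binomial())
  fit1 <- glm(f1, data = data, family = binomial())
  lrt <- anova(fit0, fit1, test = "LRT")
  tibble::tibble(
    modifier = modifier,
    p_interaction = lrt$`Pr(>Chi)`[2],
    df = lrt$Df[2],
    deviance_drop = lrt$Deviance[2]
  )
}

#' Run the full matched analysis: propensity scores, matching, odds ratio
#'
#' Convenience wrapper chaining [estimate_propensity()], [match_1to1()] and
#' [fit_or()] on the matched sample.
#'
#' @param cohort Cohort tibble.
#' @param spec A [model_spec()].
#' @param match_covariates Covariates for the propensity model; defaults to
#'   every generated covariate present in the cohort.
#' @param caliper Caliper in SD-of-logit-PS multiples.
#' @param seed Seed for the matching order.
#' @return List with `matched` (the [match_1to1()] object) and `estimate`
#'   (the [fit_or()] row).
#' @export
run_matched_analysis <- function(cohort, spec, match_covariates = NULL,
                                 caliper = 0.2, seed) {
  match_covariates <- match_covariates %||%
    intersect(cohort_covariates(), names(cohort))
  scored <- estimate_propensity(cohort, match_covariates,
                                exposure = spec$exposure)
  matched <- match_1to1(scored, caliper = caliper,
                        exposure = spec$exposure, seed = seed)
  list(matched = matched, estimate = fit_or(matched, spec))
}

#' Sensitivity analyses of the matched association
#'
#' Re-runs the matched analysis under a modified analysis population:
#' `"strict-hearing-definition"` replaces the outcome with the stricter
#' definition column (`outcome_strict`), restricting cases to subjects
#' positive on both ascertainment items; `"exclude-surgery"` removes exposed
#' subjects with a history of the corrective procedure (`surgery == 1`).
#'
#' @param cohort Cohort tibble carrying the indicator columns the variant
#'   needs.
#' @param variant `"strict-hearing-definition"` or `"exclude-surgery"`.
#' @param spec A [model_spec()].
#' @param seed Seed for the matching order.
#' @param ... Passed to [run_matched_analysis()].
#' @return The [fit_or()] row, with `model` suffixed by the variant and an
#'   attribute `filter_provenance` describing the subjects removed.
#' @export
run_sensitivity <- function(cohort,
                            variant = c("strict-hearing-definition",
                                        "exclude-surgery"),
                            spec = model_spec("model2"), seed, ...) {
  variant <- match.arg(variant)
  n0 <- nrow(cohort)
  if (variant == "strict-hearing-definition") {
    assert_that("outcome_strict" %in% names(cohort),
                "cohort lacks the `outcome_strict` indicator.")
    cohort[[spec$outcome]] <- cohort$outcome_strict
    removed <- 0L
  } else {
    assert_that("surgery" %in% names(cohort),
                "cohort lacks the `surgery` indicator.")
    cohort <- cohort[cohort$surgery == 0L, ]
    removed <- n0 - nrow(cohort)
  }
  res <- tryCatch(
    run_matched_analysis(cohort, spec, seed = seed, ...),
    error = function(e) {
      rlang::abort(sprintf("sensitivity variant '%s' failed.", variant),
                   class = "crosstraitr_sensitivity_error", parent = e)
    }
  )
  est <- res$estimate
  est$model <- paste0(spec$label, " [", variant, "]")
  attr(est, "filter_provenance") <- list(variant = variant,
                                         n_removed = removed, n_input = n0)
  est
}
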