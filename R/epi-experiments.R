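#' Coverage experiment for the adjusted odds ratio
#'
#' Repeatedly simulates confounded cohorts with a known conditional odds
#' ratio, fits the fully adjusted logistic model, and reports how often the
#' Wald confidence interval covers the truth, together with the distribution
#' of the point estimates.
#'
#' @param n_subjects Cohort size per replicate.
#' @param true_or True conditional odds ratio.
#' @param reps Number of replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param spec Adjustment model (default [model_spec()] `"model2"`).
#' @param params_fn Optional function `(seed) -> cohort_params`; defaults to
#'   [cohort_params()] with the stated size and odds ratio.
#' @return Tibble with one row per replicate (`rep`, `or`, `ci_low`,
#'   `ci_high`, `covered`); attribute `summary` lists `coverage`, `mean_or`,
#'   `mean_abs_error`.
#' @export
epi_coverage_experiment <- function(n_subjects, true_or, reps, seed,
                                    spec = model_spec("model2"),
                                    params_fn = NULL) {
  seed <- assert_seed(seed)
  params_fn <- params_fn %||% function(s) {
    cohort_params(n_subjects, true_or = true_or, seed = s)
  }
  per_rep <- purrr::map_dfr(seq_len(reps), function(r) {
    cohort <- simulate_epi_cohort(params_fn(seed + r))
    est <- fit_or(cohort, spec)
    tibble::tibble(
      rep = r, or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
      covered = est$ci_low <= true_or & true_or <= est$ci_high
    )
  })
  attr(per_rep, "summary") <- list(
    coverage = mean(per_rep$covered),
    mean_or = mean(per_rep$or),
    mean_abs_error = mean(abs(per_rep$or - true_or)),
    true_or = true_or
  )
  per_rep
}
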