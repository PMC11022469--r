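#' Estimate propensity scores for a binary exposure
#'
#' Logistic regression of the exposure on the requested covariates by maximum
#' likelihood. Rows with missing values in the model variables are removed
#' (listwise deletion) and counted. Complete or quasi-complete separation is
#' detected and raised as an error unless `penalized = TRUE`, which refits
#' with a small ridge penalty (glmnet) to keep the scores finite.
#'
#' @param cohort Cohort tibble (one row per subject).
#' @param covariates Character vector of covariate column names.
#' @param exposure Name of the binary exposure column (default `"exposure"`).
#' @param penalized Use a ridge-penalized fit as a separation fallback.
#' @return `cohort` (complete cases only) with an added `pscore` column in
#'   (0, 1) and `lps` (logit propensity); attributes `ps_coefficients`,
#'   `ps_covariates`, `n_dropped_missing`.
#' @export
estimate_propensity <- function(cohort, covariates, exposure = "exposure",
                                penalized = FALSE) {
  assert_that(all(c(exposure, covariates) %in% names(cohort)),
              "missing exposure or covariate columns.")
  vars <- c(exposure, covariates)
  cc <- complete.cases(cohort[, vars])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "estimate_propensity: %d row(s) removed by listwise deletion.", n_dropped))
  }
  dat <- cohort[cc, ]
  fml <- as.formula(paste(exposure, "~",
                          paste(covariates, collapse = " + ")))

  if (!penalized) {
    fit <- suppressWarnings(glm(fml, data = dat, family = binomial()))
    probs <- unname(fitted(fit))
    separated <- !fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE) ||
      any(probs < 1e-8) || any(probs > 1 - 1e-8)
    if (separated) {
      rlang::abort(
        "separation detected in the propensity model; retry with `penalized = TRUE`.",
        class = "crosstraitr_separation"
      )
    }
    coefs <- coef(fit)
  } else {
    assert_that(requireNamespace("glmnet", quietly = TRUE),
                "the penalized fallback requires the glmnet package.")
    x <- stats::model.matrix(fml, dat)[, -1, drop = FALSE]
    if (ncol(x) == 1L) x <- cbind(x, `.zero` = 0)  # glmnet needs >= 2 columns
    fit <- glmnet::glmnet(x, dat[[exposure]], family = "binomial",
                          alpha = 0, lambda = 1e-3)
    probs <- as.numeric(stats::predict(fit, newx = x, type = "response"))
    coefs <- c(as.numeric(fit$a0), as.numeric(fit$beta))
  }

  dat$pscore <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  dat$lps <- qlogis(dat$pscore)
  attr(dat, "ps_coefficients") <- coefs
  attr(dat, "ps_covariates") <- covariates
  attr(dat, "n_dropped_missing") <- n_dropped
  dat
}

#' Standardized mean differences between exposure groups
#'
#' SMD = (mean in exposed - mean in unexposed) / pooled SD, the pooled SD
#' taken from the reference (pre-match) groups so before/after values share a
#' denominator. |SMD| < 0.1 is the conventional balance criterion.
#'
#' @param data Cohort tibble.
#' @param covariates Covariate columns to assess.
#' @param exposure Binary exposure column.
#' @param sd_reference Optional tibble whose groups define the pooled SD
#'   (defaults to `data` itself).
#' @return Tibble with `covariate`, `mean_exposed`, `mean_control`, `smd`.
#' @export
covariate_balance <- function(data, covariates, exposure = "exposure",
                              sd_reference = NULL) {
  if (length(covariates) == 0L) {
    return(tibble::tibble(covariate = character(), mean_exposed = numeric(),
                          mean_control = numeric(), smd = numeric()))
  }
  ref <- sd_reference %||% data
  e_ref <- ref[[exposure]] == 1
  purrr::map_dfr(covariates, function(v) {
    sd_pool <- sqrt((var(ref[[v]][e_ref]) + var(ref[[v]][!e_ref])) / 2)
    e <- data[[exposure]] == 1
    m1 <- mean(data[[v]][e]); m0 <- mean(data[[v]][!e])
    tibble::tibble(covariate = v, mean_exposed = m1, mean_control = m0,
                   smd = if (sd_pool > 0) (m1 - m0) / sd_pool else 0)
  })
}

#' 1:1 propensity-score matching without replacement
#'
#' Greedy nearest-neighbour matching on the logit propensity score: exposed
#' subjects are processed in a seeded random order and each is paired with
#' the nearest still-unmatched control within the caliper. Subjects are
#' first put in a canonical order (by `id`), so permuting the input rows with
#' the same seed produces the same pairs. The caliper is expressed in
#' multiples of the SD of the logit propensity score (0.2 by convention).
#'
#' @param scored Cohort with `pscore`/`lps`, from [estimate_propensity()].
#' @param caliper Caliper width in SD-of-logit-PS multiples; `Inf` disables.
#' @param exposure Binary exposure column.
#' @param seed Integer seed for the processing order.
#' @return An object of class `matched_cohort`: list with `data` (the matched
#'   subjects, with `pair_id`), `pairs` (exposed/control ids and distance),
#'   `caliper_logit` (absolute caliper used), `n_unmatched_exposed`, and
#'   `balance` (per-covariate SMD before/after matching).
#' @export
match_1to1 <- function(scored, caliper = 0.2, exposure = "exposure", seed) {
  seed <- assert_seed(seed)
  assert_that(all(c("lps", "id") %in% names(scored)),
              "input must come from estimate_propensity() and carry `id`.")
  scored <- dplyr::arrange(scored, .data$id)   # canonical order
  e <- scored[[exposure]] == 1
  assert_that(any(e) && any(!e), "both exposure groups must be non-empty.")

  cal <- caliper * sd(scored$lps)
  exp_idx <- which(e)
  ctl_idx <- which(!e)
  ctl_ord <- ctl_idx[order(scored$lps[ctl_idx])]
  ctl_lps <- scored$lps[ctl_ord]
  n_ctl <- length(ctl_ord)
  avail <- rep(TRUE, n_ctl)

  withr::local_seed(seed)
  exp_order <- exp_idx[sample.int(length(exp_idx))]

  pair_e <- integer(0); pair_c <- integer(0); pair_d <- numeric(0)
  for (i in exp_order) {
    x <- scored$lps[i]
    j <- findInterval(x, ctl_lps)
    # nearest available control on each side
    l <- j
    while (l >= 1 && !avail[l]) l <- l - 1L
    r <- j + 1L
    while (r <= n_ctl && !avail[r]) r <- r + 1L
    dl <- if (l >= 1) abs(x - ctl_lps[l]) else Inf
    dr <- if (r <= n_ctl) abs(x - ctl_lps[r]) else Inf
    if (min(dl, dr) > cal) next
    k <- if (dl <= dr) l else r
    avail[k] <- FALSE
    pair_e <- c(pair_e, i); pair_c <- c(pair_c, ctl_ord[k])
    pair_d <- c(pair_d, min(dl, dr))
  }
  if (length(pair_e) == 0L) {
    rlang::abort("no matched pairs could be formed.",
                 class = "crosstraitr_no_pairs")
  }

  pairs <- tibble::tibble(
    pair_id = seq_along(pair_e),
    exposed_id = scored$id[pair_e],
    control_id = scored$id[pair_c],
    distance = pair_d
  )
  matched <- dplyr::bind_rows(
    dplyr::mutate(scored[pair_e, ], pair_id = pairs$pair_id),
    dplyr::mutate(scored[pair_c, ], pair_id = pairs$pair_id)
  )

  covs <- attr(scored, "ps_covariates") %||%
    intersect(cohort_covariates(), names(scored))
  balance <- dplyr::full_join(
    covariate_balance(scored, covs, exposure) |>
      dplyr::select("covariate", smd_before = "smd"),
    covariate_balance(matched, covs, exposure, sd_reference = scored) |>
      dplyr::select("covariate", smd_after = "smd"),
    by = "covariate"
  )

  structure(
    list(data = matched, pairs = pairs, caliper_logit = cal,
         n_unmatched_exposed = length(exp_idx) - length(pair_e),
         balance = balance, seed = seed),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d pairs (%d subjects), %d exposed unmatched\n",
              nrow(x$pairs), nrow(x$data), x$n_unmatched_exposed))
  cat(sprintf("  caliper (logit scale): %.4f; max |SMD| after: %.3f\n",
              x$caliper_logit, max(abs(x$balance$smd_after))))
  invisible(x)
}

#' @describeIn match_1to1 tidy method: the balance table.
#' @param x A `matched_cohort`.
#' @param ... Unused.
#' @method tidy matched_cohort
#' @export
tidy.matched_cohort <- function(x, ...) x$balance

#' Love-style balance plot of a matched cohort
#'
#' @param x A `matched_cohort`.
#' @return A ggplot dot plot of |SMD| before/after matching with the 0.1
#'   convention line.
#' @export
plot_balance <- function(x) {
  long <- tidyr::pivot_longer(x$balance, c("smd_before", "smd_after"),
                              names_to = "stage", values_to = "smd")
  long$stage <- factor(long$stage, c("smd_before", "smd_after"),
                       c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = abs(.data$smd),
                                     y = .data$covariate,
                                     colour = .data$stage)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
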