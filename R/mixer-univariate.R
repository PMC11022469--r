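# Group SNPs by LD score for the composite likelihood: each group carries
# L = round(ld score) Bernoulli "causal partner" slots and a moment-matching
# factor h = ld_score / L so that E[z^2] is preserved exactly.
ld_groups <- function(z, ld_scores, z2 = NULL, max_groups = 200L) {
  assert_that(all(ld_scores >= 1), "LD scores must be >= 1.")
  key <- ld_scores
  if (length(unique(key)) > max_groups) {
    qs <- unique(quantile(key, seq(0, 1, length.out = max_groups + 1L)))
    bin <- cut(key, qs, include.lowest = TRUE)
    key <- stats::ave(key, bin)         # bin-mean LD score
  }
  split_idx <- split(seq_along(z), key)
  purrr::map(split_idx, function(idx) {
    ell <- ld_scores[idx][1]
    L <- max(1L, as.integer(round(ell)))
    list(L = L, h = ell / L, z = z[idx], idx = idx)
  })
}

# composite log-likelihood of the two-component scale mixture:
# z_j | k ~ N(0, sigma0^2 + n sigma2 h k),  k ~ Binomial(L_j, pi)
uni_loglik <- function(pi, sigma2, sigma0, n, groups) {
  ll <- 0
  for (g in groups) {
    k <- 0:g$L
    w <- stats::dbinom(k, g$L, pi)
    v <- sigma0^2 + n * sigma2 * g$h * k
    dens <- numeric(length(g$z))
    for (j in seq_along(k)) {
      if (w[j] < 1e-14) next
      dens <- dens + w[j] * dnorm(g$z, 0, sqrt(v[j]))
    }
    ll <- ll + sum(log(pmax(dens, 1e-300)))
  }
  ll
}

# deterministic Latin-hypercube multistart designs in the unit cube
multistart_design <- function(n_starts, dims, seed) {
  withr::local_seed(seed)
  lhs::randomLHS(n_starts, dims)
}

#' Fit the univariate causal-mixture model to one trait's summary statistics
#'
#' Models each z-score as a scale mixture driven by the number of causal
#' variants the SNP tags: with causal proportion `pi`, a SNP with LD score
#' `l` has `k ~ Binomial(round(l), pi)` causal partners and
#' `z | k ~ N(0, sigma0^2 + n * sigma2 * (l / round(l)) * k)`. This
#' moment-matched binomial-mixture approximation to the full LD convolution
#' preserves `E[z^2]` exactly and is evaluated as a per-SNP composite
#' likelihood. Optimization runs in unconstrained space (logit `pi`,
#' log `sigma2`, log `sigma0`) from a deterministic Latin-hypercube set of
#' starting points; the best start is returned.
#'
#' @param table Summary-statistics tibble (needs `z`; `n` used unless
#'   overridden).
#' @param ld_scores Per-SNP LD scores (>= 1); default 1 (no LD).
#' @param n GWAS sample size; defaults to the median of `table$n`.
#' @param n_starts Number of multistart points (>= 1; default 5).
#' @param seed Seed for the multistart design.
#' @return An object of class `univariate_mixfit`: list with `pi`, `sigma2`,
#'   `sigma0`, `n_causal` (`pi * M`), `m`, `n`, `loglik`, `aic`
#'   (`2k - 2 loglik`, k = 3), `starts` (per-start tibble) and `best_start`.
#' @examples
#' \donttest{
#' ld <- simulate_ld_blocks(20000, 1, 0)
#' sim <- simulate_bivariate_sumstats(
#'   architecture_params(20000, pi_a = 0.003, seed = 11), ld)
#' fit <- fit_univariate(sim$sumstats_a, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_univariate <- function(table, ld_scores = NULL, n = NULL,
                           n_starts = 5L, seed = 1L) {
  z <- table$z
  m <- length(z)
  assert_that(m >= 100, "too few SNPs to fit the mixture model.")
  if (is.null(ld_scores)) ld_scores <- rep(1, m)
  assert_that(length(ld_scores) == m, "`ld_scores` must align with `table`.")
  if (is.null(n)) n <- stats::median(table$n, na.rm = TRUE)
  assert_that(is.finite(n) && n > 0, "a positive sample size is required.")

  groups <- ld_groups(z, ld_scores)

  nll <- function(par) {
    pi <- plogis(par[1]); s2 <- exp(par[2]); s0 <- exp(par[3])
    -uni_loglik(pi, s2, s0, n, groups)
  }

  # unconstrained box the Latin hypercube is mapped into
  lo <- c(qlogis(1e-5), log(1e-6), log(0.8))
  hi <- c(qlogis(0.3),  log(1e-2), log(1.5))
  design <- multistart_design(n_starts, 3L, seed)
  starts <- t(lo + t(design) * (hi - lo))

  runs <- purrr::map(seq_len(n_starts), function(s) {
    fit <- optim(starts[s, ], nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    list(par = fit$par, value = fit$value, convergence = fit$convergence,
         iterations = fit$counts[["function"]])
  })
  conv <- purrr::map_int(runs, "convergence") == 0L
  if (!any(conv)) {
    rlang::abort(
      "no multistart converged; per-start traces attached.",
      class = "crosstraitr_nonconvergence",
      traces = purrr::map(runs, function(r) r[c("par", "value", "convergence")])
    )
  }
  values <- purrr::map_dbl(runs, "value")
  values[!conv] <- Inf
  best <- which.min(values)
  par <- runs[[best]]$par
  loglik <- -runs[[best]]$value

  start_tbl <- tibble::tibble(
    start = seq_len(n_starts),
    loglik = -purrr::map_dbl(runs, "value"),
    converged = purrr::map_int(runs, "convergence") == 0L,
    iterations = purrr::map_int(runs, "iterations")
  )

  structure(
    list(
      pi = plogis(par[1]), sigma2 = exp(par[2]), sigma0 = exp(par[3]),
      n_causal = plogis(par[1]) * m, m = m, n = n,
      loglik = loglik, aic = 2 * 3 - 2 * loglik,
      starts = start_tbl, best_start = best,
      groups = groups
    ),
    class = "univariate_mixfit"
  )
}

#' Composite log-likelihood of a univariate fit at arbitrary parameters
#'
#' Re-evaluates the fitted model's likelihood at user-supplied parameters
#' (e.g. for profile curves or constrained-model AIC comparisons).
#'
#' @param fit A `univariate_mixfit`.
#' @param pi,sigma2,sigma0 Parameter values; default to the fitted estimates.
#' @return Log-likelihood value.
#' @export
univariate_loglik <- function(fit, pi = fit$pi, sigma2 = fit$sigma2,
                              sigma0 = fit$sigma0) {
  stopifnot(inherits(fit, "univariate_mixfit"))
  uni_loglik(pi, sigma2, sigma0, fit$n, fit$groups)
}

#' @export
print.univariate_mixfit <- function(x, ...) {
  cat(sprintf(
    "<univariate_mixfit> pi = %.3g (n_causal = %.0f of %d), sigma2 = %.3g, sigma0 = %.3f\n",
    x$pi, x$n_causal, x$m, x$sigma2, x$sigma0))
  cat(sprintf("  loglik = %.2f, AIC = %.2f (best of %d starts)\n",
              x$loglik, x$aic, nrow(x$starts)))
  invisible(x)
}

#' @describeIn fit_univariate tidy method: one row per parameter.
#' @param x A `univariate_mixfit`.
#' @param ... Unused.
#' @method tidy univariate_mixfit
#' @export
tidy.univariate_mixfit <- function(x, ...) {
  tibble::tibble(
    term = c("pi", "sigma2", "sigma0", "n_causal"),
    estimate = c(x$pi, x$sigma2, x$sigma0, x$n_causal)
  )
}

#' @describeIn fit_univariate glance method: one-row model summary.
#' @method glance univariate_mixfit
#' @export
glance.univariate_mixfit <- function(x, ...) {
  tibble::tibble(
    m = x$m, n = x$n, logLik = x$loglik, AIC = x$aic,
    best_start = x$best_start, n_starts = nrow(x$starts)
  )
}
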