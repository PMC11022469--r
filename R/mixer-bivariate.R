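# combos of (ka, kb, kc) causal-partner counts for the three non-null
# components among L slots; k0 = L - ka - kb - kc
biv_combos <- function(L) {
  g <- expand.grid(ka = 0:L, kb = 0:L, kc = 0:L)
  g <- g[g$ka + g$kb + g$kc <= L, , drop = FALSE]
  g$k0 <- L - g$ka - g$kb - g$kc
  g$lcoef <- lgamma(L + 1) - lgamma(g$ka + 1) - lgamma(g$kb + 1) -
    lgamma(g$kc + 1) - lgamma(g$k0 + 1)
  g
}

# vectorized bivariate normal log-density with per-call scalar covariance
bvn_dens <- function(z1, z2, v1, v2, cv) {
  cap <- 0.999 * sqrt(v1 * v2)
  cv <- pmin(pmax(cv, -cap), cap)
  det <- v1 * v2 - cv^2
  q <- (v2 * z1^2 - 2 * cv * z1 * z2 + v1 * z2^2) / det
  exp(-log(2 * pi) - 0.5 * log(det) - 0.5 * q)
}

biv_groups <- function(z1, z2, ld_scores) {
  grp <- ld_groups(z1, ld_scores)
  purrr::map(grp, function(g) {
    g$z2 <- z2[g$idx]
    g$combos <- biv_combos(g$L)
    g
  })
}

# composite log-likelihood of the 4-component bivariate causal mixture:
# each of a SNP's L tagged slots is independently null / A-only / B-only /
# shared; given slot counts (ka, kb, kc) the z pair is bivariate normal.
biv_loglik <- function(pi_a, pi_b, pi_ab, rho_shared, rho0, fx, groups) {
  p0 <- 1 - pi_a - pi_b - pi_ab
  if (p0 < 0) return(-Inf)
  lp <- log(pmax(c(p0, pi_a, pi_b, pi_ab), 1e-300))
  ll <- 0
  for (g in groups) {
    cb <- g$combos
    lw <- cb$lcoef + cb$k0 * lp[1] + cb$ka * lp[2] + cb$kb * lp[3] +
      cb$kc * lp[4]
    keep <- lw > log(1e-12)
    dens <- numeric(length(g$z))
    for (j in which(keep)) {
      v1 <- fx$s0a^2 + fx$n_a * fx$s2a * g$h * (cb$ka[j] + cb$kc[j])
      v2 <- fx$s0b^2 + fx$n_b * fx$s2b * g$h * (cb$kb[j] + cb$kc[j])
      cv <- rho0 * fx$s0a * fx$s0b +
        rho_shared * sqrt(fx$n_a * fx$n_b * fx$s2a * fx$s2b) * g$h * cb$kc[j]
      dens <- dens + exp(lw[j]) * bvn_dens(g$z, g$z2, v1, v2, cv)
    }
    ll <- ll + sum(log(pmax(dens, 1e-300)))
  }
  ll
}

#' Fit the bivariate 4-component causal-mixture model
#'
#' Estimates the architecture of cross-trait sharing from a harmonized pair
#' of summary statistics: the proportions of SNPs causal for trait A only
#' (`pi_a`), trait B only (`pi_b`) and both (`pi_ab`), the effect correlation
#' within the shared component (`rho_shared`) and a residual z-score
#' correlation (`rho0`, e.g. sample overlap). Per-trait effect variances and
#' inflation are held at the univariate estimates (two-stage fitting); pass
#' `joint = TRUE` to polish all nine parameters jointly from the two-stage
#' solution. From the fitted proportions the shared/unique variant counts,
#' their Dice coefficient and per-trait shared fractions are derived, and the
#' constrained `pi_ab = 0` submodel is refitted for an AIC comparison of the
#' evidence for any overlap.
#'
#' @param pair Harmonized-pair tibble (`z1`, `z2`, `n1`, `n2`).
#' @param fit_a,fit_b Converged [fit_univariate()] results for the two traits.
#' @param ld_scores Per-SNP LD scores aligned with `pair`; default 1.
#' @param n_starts Multistart points for the 5-parameter optimization.
#' @param seed Seed for the multistart design and bootstrap.
#' @param n_boot Parametric-bootstrap refits for the Dice standard error
#'   (0 disables; each refit simulates data at the point estimate and refits
#'   from a single start).
#' @param boot_ld Optional `ld_structure` used by the bootstrap simulations;
#'   defaults to an LD-free panel of the same size.
#' @param joint If `TRUE`, refine sigma parameters jointly after the
#'   two-stage fit.
#' @return An object of class `bivariate_mixfit` with the mixture proportions,
#'   variant counts (`n_a_only`, `n_b_only`, `n_shared`), `dice`, `dice_se`,
#'   `shared_fraction_a`/`_b` (percent), `rho_shared`, `rho0`, log-likelihood
#'   and AIC of the full and no-overlap models, convergence metadata, and a
#'   `no_overlap` flag set when the shared count collapses to zero.
#' @export
fit_bivariate <- function(pair, fit_a, fit_b, ld_scores = NULL,
                          n_starts = 5L, seed = 1L, n_boot = 20L,
                          boot_ld = NULL, joint = FALSE) {
  stopifnot(inherits(fit_a, "univariate_mixfit"),
            inherits(fit_b, "univariate_mixfit"))
  m <- nrow(pair)
  assert_that(m >= 100, "too few SNPs to fit the bivariate mixture.")
  if (is.null(ld_scores)) ld_scores <- rep(1, m)

  fx <- list(
    s2a = fit_a$sigma2, s2b = fit_b$sigma2,
    s0a = fit_a$sigma0, s0b = fit_b$sigma0,
    n_a = fit_a$n, n_b = fit_b$n
  )
  groups <- biv_groups(pair$z1, pair$z2, ld_scores)

  # multinomial-logit for the proportions, tanh for the correlations
  unpack <- function(par) {
    e <- exp(par[1:3])
    s <- 1 + sum(e)
    list(pi_a = e[1] / s, pi_b = e[2] / s, pi_ab = e[3] / s,
         rho_shared = tanh(par[4]), rho0 = tanh(par[5]))
  }
  nll <- function(par) {
    p <- unpack(par)
    -biv_loglik(p$pi_a, p$pi_b, p$pi_ab, p$rho_shared, p$rho0, fx, groups)
  }

  # starts: split each trait's univariate polygenicity between its unique and
  # shared components at Latin-hypercube fractions
  design <- multistart_design(n_starts, 5L, seed)
  pit_a <- max(fit_a$pi, 1e-5)
  pit_b <- max(fit_b$pi, 1e-5)
  starts <- t(apply(design, 1, function(u) {
    f <- 0.05 + 0.9 * u[1]                  # shared fraction of the smaller trait
    pi_ab0 <- f * min(pit_a, pit_b)
    pi_a0 <- max(pit_a - pi_ab0, 1e-6)
    pi_b0 <- max(pit_b - pi_ab0, 1e-6)
    p00 <- max(1 - pi_a0 - pi_b0 - pi_ab0, 1e-3)
    c(log(pi_a0 / p00), log(pi_b0 / p00), log(pi_ab0 / p00),
      atanh(-0.9 + 1.8 * u[2]), atanh(-0.3 + 0.6 * u[3]))
  }))

  runs <- purrr::map(seq_len(n_starts), function(s) {
    optim(starts[s, ], nll, method = "Nelder-Mead",
          control = list(maxit = 3000, reltol = 1e-10))
  })
  conv <- purrr::map_int(runs, "convergence") == 0L
  if (!any(conv)) {
    rlang::abort("no multistart of the bivariate fit converged.",
                 class = "crosstraitr_nonconvergence",
                 traces = purrr::map(runs, function(r) r[c("par", "value", "convergence")]))
  }
  values <- purrr::map_dbl(runs, "value")
  values[!conv] <- Inf
  best <- which.min(values)
  par <- runs[[best]]$par
  loglik <- -runs[[best]]$value

  if (isTRUE(joint)) {
    nll9 <- function(q) {
      fx2 <- fx
      fx2$s2a <- exp(q[6]); fx2$s2b <- exp(q[7])
      fx2$s0a <- exp(q[8]); fx2$s0b <- exp(q[9])
      p <- unpack(q[1:5])
      -biv_loglik(p$pi_a, p$pi_b, p$pi_ab, p$rho_shared, p$rho0, fx2, groups)
    }
    q0 <- c(par, log(fx$s2a), log(fx$s2b), log(fx$s0a), log(fx$s0b))
    ref <- optim(q0, nll9, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-10))
    if (ref$convergence == 0L && -ref$value > loglik) {
      par <- ref$par[1:5]
      fx$s2a <- exp(ref$par[6]); fx$s2b <- exp(ref$par[7])
      fx$s0a <- exp(ref$par[8]); fx$s0b <- exp(ref$par[9])
      loglik <- -ref$value
    }
  }

  est <- unpack(par)

  # no-overlap submodel (pi_ab = 0, rho_shared dropped): k = 3
  nll0 <- function(par3) {
    e <- exp(par3[1:2]); s <- 1 + sum(e)
    -biv_loglik(e[1] / s, e[2] / s, 0, 0, tanh(par3[3]), fx, groups)
  }
  run0 <- optim(c(par[1], par[2], par[5]), nll0, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-10))
  loglik0 <- -run0$value

  n_a_only <- est$pi_a * m
  n_b_only <- est$pi_b * m
  n_shared <- est$pi_ab * m

  fit <- structure(
    list(
      pi_a = est$pi_a, pi_b = est$pi_b, pi_ab = est$pi_ab,
      rho_shared = est$rho_shared, rho0 = est$rho0,
      sigma2_a = fx$s2a, sigma2_b = fx$s2b,
      sigma0_a = fx$s0a, sigma0_b = fx$s0b,
      n_a = fx$n_a, n_b = fx$n_b, m = m,
      n_a_only = n_a_only, n_b_only = n_b_only, n_shared = n_shared,
      dice = dice_coefficient(n_a_only, n_shared, n_b_only),
      dice_se = NA_real_,
      shared_fraction_a = 100 * n_shared / (n_a_only + n_shared),
      shared_fraction_b = 100 * n_shared / (n_b_only + n_shared),
      loglik = loglik, aic = 2 * 5 - 2 * loglik,
      loglik_no_overlap = loglik0, aic_no_overlap = 2 * 3 - 2 * loglik0,
      no_overlap = n_shared < 0.5,
      best_start = best,
      starts = tibble::tibble(start = seq_len(n_starts),
                              loglik = -purrr::map_dbl(runs, "value"),
                              converged = conv),
      par = par, fx = fx, groups = groups
    ),
    class = "bivariate_mixfit"
  )

  if (n_boot > 0) {
    fit$dice_se <- boot_dice_se(fit, n_boot, seed + 1000L, boot_ld)
  }
  fit
}

# parametric bootstrap of the Dice coefficient: simulate at the point
# estimate, refit the 5-parameter model from a single start at the truth
boot_dice_se <- function(fit, n_boot, seed, boot_ld = NULL) {
  if (is.null(boot_ld)) boot_ld <- simulate_ld_blocks(fit$m, 1L, 0)
  dice_b <- purrr::map_dbl(seq_len(n_boot), function(b) {
    arch <- architecture_params(
      fit$m, pi_a = fit$pi_a, pi_b = fit$pi_b, pi_ab = max(fit$pi_ab, 1e-8),
      sigma2_a = fit$sigma2_a, sigma2_b = fit$sigma2_b,
      rho_shared = fit$rho_shared,
      sigma0_a = fit$sigma0_a, sigma0_b = fit$sigma0_b,
      n_a = fit$n_a, n_b = fit$n_b, seed = seed + b
    )
    sim <- simulate_bivariate_sumstats(arch, boot_ld)
    groups_b <- biv_groups(sim$sumstats_a$z, sim$sumstats_b$z, boot_ld$ld_score)
    nll_b <- function(par) {
      e <- exp(par[1:3]); s <- 1 + sum(e)
      -biv_loglik(e[1] / s, e[2] / s, e[3] / s, tanh(par[4]), tanh(par[5]),
                  fit$fx, groups_b)
    }
    run <- optim(fit$par, nll_b, method = "Nelder-Mead",
                 control = list(maxit = 1500, reltol = 1e-8))
    e <- exp(run$par[1:3]); s <- 1 + sum(e)
    dice_coefficient(e[1] / s * fit$m, e[3] / s * fit$m, e[2] / s * fit$m)
  })
  sd(dice_b)
}

#' Composite log-likelihood of a bivariate fit at arbitrary proportions
#'
#' @param fit A `bivariate_mixfit`.
#' @param pi_a,pi_b,pi_ab,rho_shared,rho0 Parameter values; default to the
#'   fitted estimates.
#' @return Log-likelihood value.
#' @export
bivariate_loglik <- function(fit, pi_a = fit$pi_a, pi_b = fit$pi_b,
                             pi_ab = fit$pi_ab, rho_shared = fit$rho_shared,
                             rho0 = fit$rho0) {
  stopifnot(inherits(fit, "bivariate_mixfit"))
  biv_loglik(pi_a, pi_b, pi_ab, rho_shared, rho0, fit$fx, fit$groups)
}

#' @export
print.bivariate_mixfit <- function(x, ...) {
  cat("<bivariate_mixfit>\n")
  cat(sprintf("  variants: %.0f A-only | %.0f shared | %.0f B-only (of %d SNPs)\n",
              x$n_a_only, x$n_shared, x$n_b_only, x$m))
  cat(sprintf("  Dice = %.3f%s, shared fraction A = %.1f%%, B = %.1f%%\n",
              x$dice,
              if (is.na(x$dice_se)) "" else sprintf(" (SE %.3f)", x$dice_se),
              x$shared_fraction_a, x$shared_fraction_b))
  cat(sprintf("  rho_shared = %.2f, rho0 = %.2f\n", x$rho_shared, x$rho0))
  cat(sprintf("  AIC full = %.1f vs no-overlap = %.1f%s\n",
              x$aic, x$aic_no_overlap,
              if (x$no_overlap) " [no detectable overlap]" else ""))
  invisible(x)
}

#' @describeIn fit_bivariate tidy method: one row per parameter/count.
#' @param x A `bivariate_mixfit`.
#' @param ... Unused.
#' @method tidy bivariate_mixfit
#' @export
tidy.bivariate_mixfit <- function(x, ...) {
  tibble::tibble(
    term = c("pi_a", "pi_b", "pi_ab", "rho_shared", "rho0",
             "n_a_only", "n_b_only", "n_shared", "dice",
             "shared_fraction_a", "shared_fraction_b"),
    estimate = c(x$pi_a, x$pi_b, x$pi_ab, x$rho_shared, x$rho0,
                 x$n_a_only, x$n_b_only, x$n_shared, x$dice,
                 x$shared_fraction_a, x$shared_fraction_b)
  )
}

#' @describeIn fit_bivariate glance method: one-row model summary.
#' @method glance bivariate_mixfit
#' @export
glance.bivariate_mixfit <- function(x, ...) {
  tibble::tibble(
    m = x$m, logLik = x$loglik, AIC = x$aic,
    logLik_no_overlap = x$loglik_no_overlap, AIC_no_overlap = x$aic_no_overlap,
    dice = x$dice, dice_se = x$dice_se, no_overlap = x$no_overlap
  )
}
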