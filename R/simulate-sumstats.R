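#' Specify a bivariate causal-mixture architecture
#'
#' Parameters of the four-component generative model for paired GWAS
#' summary statistics: each SNP is (i) null for both traits, (ii) causal for
#' trait A only, (iii) causal for trait B only, or (iv) causal for both, with
#' probabilities `1 - pi_a - pi_b - pi_ab`, `pi_a`, `pi_b` and `pi_ab`.
#' Causal effects are zero-mean Gaussian with per-variant variance `sigma2_a`
#' / `sigma2_b`; within the shared component the two traits' effects are
#' correlated with coefficient `rho_shared`. Observed z-scores add residual
#' noise with standard deviation `sigma0_a` / `sigma0_b` (1 = no inflation).
#'
#' @param m_snps Number of SNPs in the reference panel.
#' @param pi_a,pi_b,pi_ab Mixture proportions of the unique-A, unique-B and
#'   shared causal components; must satisfy `pi_a + pi_b + pi_ab <= 1`.
#' @param sigma2_a,sigma2_b Per-causal-variant effect variance for each trait.
#' @param rho_shared Effect correlation within the shared component, in
#'   `[-1, 1]`.
#' @param sigma0_a,sigma0_b Residual inflation of null z-scores.
#' @param n_a,n_b GWAS sample sizes.
#' @param seed Integer seed; mandatory (reproducibility contract).
#' @return A list of class `architecture_params`.
#' @examples
#' arch <- architecture_params(1e4, pi_ab = 0.01, seed = 1)
#' @export
architecture_params <- function(m_snps,
                                pi_a = 0, pi_b = 0, pi_ab = 0,
                                sigma2_a = 1e-4, sigma2_b = 1e-4,
                                rho_shared = 0,
                                sigma0_a = 1, sigma0_b = 1,
                                n_a = 1e5, n_b = 1e5,
                                seed) {
  assert_that(m_snps >= 1, "`m_snps` must be positive.")
  assert_prob(c(pi_a, pi_b, pi_ab), "pi components")
  assert_that(pi_a + pi_b + pi_ab <= 1, "mixture proportions must sum to at most 1.")
  assert_that(sigma2_a > 0 && sigma2_b > 0, "effect variances must be positive.")
  assert_that(abs(rho_shared) <= 1, "`rho_shared` must lie in [-1, 1].")
  assert_that(sigma0_a > 0 && sigma0_b > 0, "inflation parameters must be positive.")
  assert_that(n_a > 0 && n_b > 0, "sample sizes must be positive.")
  seed <- assert_seed(seed)
  structure(
    list(
      m_snps = as.integer(m_snps),
      pi_a = pi_a, pi_b = pi_b, pi_ab = pi_ab,
      sigma2_a = sigma2_a, sigma2_b = sigma2_b,
      rho_shared = rho_shared,
      sigma0_a = sigma0_a, sigma0_b = sigma0_b,
      n_a = n_a, n_b = n_b, seed = seed
    ),
    class = "architecture_params"
  )
}

# deterministic SNP map: blocks cycle over chr1-22, positions every 5 kb
snp_map <- function(ld) {
  n_blocks <- nrow(ld$blocks)
  chr_of_block <- as.character(((seq_len(n_blocks) - 1L) %% 22L) + 1L)
  chr <- chr_of_block[ld$block_of]
  pos_in_chr <- stats::ave(seq_len(ld$m), chr, FUN = seq_along)
  tibble::tibble(
    snp = sprintf("rs%07d", seq_len(ld$m)),
    chr = chr,
    bp = as.integer(pos_in_chr * 5000L)
  )
}

#' Simulate paired GWAS summary statistics under a causal mixture with block LD
#'
#' Each SNP is assigned a mixture component, causal effects are drawn from the
#' component's Gaussian (bivariate with correlation `rho_shared` in the shared
#' component), and the observed z-score of trait t is
#' `sqrt(n_t) * sum_k r_jk beta_k + e`, where `r_jk` is the LD correlation and
#' `e` is `N(0, sigma0_t^2)` noise. Two-sided p-values follow from the normal
#' tail. Component labels are returned as a ground-truth sidecar, never in the
#' summary-statistics tables themselves.
#'
#' @param arch An [architecture_params()] object (carries the seed).
#' @param ld An [simulate_ld_blocks()] structure covering `arch$m_snps` SNPs.
#' @param perturb_b If `TRUE`, inject harmonization challenges into trait B's
#'   table: a fraction of records with swapped alleles (and flipped z), a
#'   fraction strand-complemented, and a fraction rewritten as palindromic
#'   A/T / C/G variants. Defaults to `FALSE` (tables share orientation).
#' @return A list with tibbles `sumstats_a`, `sumstats_b` (columns `snp, chr,
#'   bp, a1, a2, z, p, n, frq`) and `truth` (`snp, component, beta_a, beta_b`,
#'   plus `block`).
#' @examples
#' ld <- simulate_ld_blocks(2000, 10, 0.8)
#' sim <- simulate_bivariate_sumstats(
#'   architecture_params(2000, pi_ab = 0.01, rho_shared = 0.9, seed = 7), ld)
#' dplyr::count(sim$truth, component)
#' @export
simulate_bivariate_sumstats <- function(arch, ld, perturb_b = FALSE) {
  stopifnot(inherits(arch, "architecture_params"), inherits(ld, "ld_structure"))
  assert_that(ld$m == arch$m_snps, "`ld` must cover exactly `m_snps` SNPs.")
  seed <- assert_seed(arch$seed)
  withr::local_seed(seed)

  m <- arch$m_snps
  comp <- sample(
    c("null", "a_only", "b_only", "shared"), m, replace = TRUE,
    prob = c(1 - arch$pi_a - arch$pi_b - arch$pi_ab,
             arch$pi_a, arch$pi_b, arch$pi_ab)
  )

  beta_a <- numeric(m)
  beta_b <- numeric(m)
  ia <- comp == "a_only"; ib <- comp == "b_only"; is <- comp == "shared"
  beta_a[ia] <- rnorm(sum(ia), 0, sqrt(arch$sigma2_a))
  beta_b[ib] <- rnorm(sum(ib), 0, sqrt(arch$sigma2_b))
  if (any(is)) {
    # correlated bivariate draw via conditional normal
    u <- rnorm(sum(is))
    v <- arch$rho_shared * u + sqrt(1 - arch$rho_shared^2) * rnorm(sum(is))
    beta_a[is] <- u * sqrt(arch$sigma2_a)
    beta_b[is] <- v * sqrt(arch$sigma2_b)
  }

  # LD-weighted causal signal: within an exchangeable block,
  # sum_k r_jk beta_k = beta_j + rho * (block sum - beta_j)
  rho_b <- ld$blocks$rho[ld$block_of]
  sum_a <- stats::ave(beta_a, ld$block_of, FUN = sum)
  sum_b <- stats::ave(beta_b, ld$block_of, FUN = sum)
  sig_a <- beta_a + rho_b * (sum_a - beta_a)
  sig_b <- beta_b + rho_b * (sum_b - beta_b)

  z_a <- sqrt(arch$n_a) * sig_a + rnorm(m, 0, arch$sigma0_a)
  z_b <- sqrt(arch$n_b) * sig_b + rnorm(m, 0, arch$sigma0_b)

  map <- snp_map(ld)
  pair_idx <- sample(nrow(NONPALINDROMIC_PAIRS), m, replace = TRUE)
  a1 <- NONPALINDROMIC_PAIRS[pair_idx, 1]
  a2 <- NONPALINDROMIC_PAIRS[pair_idx, 2]
  frq <- runif(m, 0.05, 0.95)

  mk <- function(z, n) {
    tibble::tibble(
      snp = map$snp, chr = map$chr, bp = map$bp,
      a1 = a1, a2 = a2,
      z = z, p = pmax(z_to_p(z), .Machine$double.xmin),
      n = as.integer(n), frq = frq
    )
  }
  sumstats_a <- mk(z_a, arch$n_a)
  sumstats_b <- mk(z_b, arch$n_b)

  if (isTRUE(perturb_b)) {
    sumstats_b <- perturb_orientation(sumstats_b)
  }

  truth <- tibble::tibble(
    snp = map$snp, block = ld$block_of,
    component = comp, beta_a = beta_a, beta_b = beta_b
  )
  list(sumstats_a = sumstats_a, sumstats_b = sumstats_b, truth = truth)
}

# rewrite a fraction of records with swapped alleles (+z flip), a fraction
# strand-complemented, and a fraction turned palindromic; exercises
# harmonize_pair() — uses the RNG stream of the caller
perturb_orientation <- function(tab, frac_swap = 0.1, frac_flip = 0.1,
                                frac_palindromic = 0.02) {
  m <- nrow(tab)
  grp <- sample(c("keep", "swap", "flip", "pal"), m, replace = TRUE,
                prob = c(1 - frac_swap - frac_flip - frac_palindromic,
                         frac_swap, frac_flip, frac_palindromic))
  sw <- grp == "swap"
  tmp <- tab$a1[sw]; tab$a1[sw] <- tab$a2[sw]; tab$a2[sw] <- tmp
  tab$z[sw] <- -tab$z[sw]
  tab$frq[sw] <- 1 - tab$frq[sw]
  fl <- grp == "flip"
  tab$a1[fl] <- complement_allele(tab$a1[fl])
  tab$a2[fl] <- complement_allele(tab$a2[fl])
  pl <- grp == "pal"
  tab$a1[pl] <- sample(c("A", "C"), sum(pl), replace = TRUE)
  tab$a2[pl] <- ifelse(tab$a1[pl] == "A", "T", "G")
  tab
}
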