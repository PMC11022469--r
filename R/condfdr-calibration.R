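#' Monte-Carlo calibration of conjunctional-FDR discoveries
#'
#' Repeatedly simulates paired summary statistics with known ground truth,
#' runs the full condFDR machinery (both directions, LD-pruned empirical
#' grids), and measures the empirical false-discovery proportion (FDP) among
#' SNPs called at `conjfdr < conj_threshold`. A discovery counts as false
#' when its LD block contains no shared-component causal variant — LD proxies
#' of a shared causal SNP are genuine discoveries at locus resolution.
#'
#' @param arch An [architecture_params()] object; its seed is the base seed
#'   and replicate r uses `seed + r`.
#' @param ld LD structure shared by all replicates.
#' @param reps Number of replicates.
#' @param conj_threshold Discovery threshold on the conjunctional FDR.
#' @param n_prunings Pruning iterations per grid.
#' @return A tibble with one row per replicate (`rep`, `n_discoveries`,
#'   `n_false`, `fdp`) plus attribute `summary`: a list with `mean_fdp`
#'   (over replicates with at least one discovery), `fdp_mc_se` (binomial
#'   Monte-Carlo standard error of the pooled FDP), `mean_discoveries`.
#' @examples
#' \donttest{
#' ld <- simulate_ld_blocks(20000, 10, 0.8)
#' arch <- architecture_params(20000, pi_ab = 0.002, rho_shared = 0.8, seed = 5)
#' cal <- fdr_calibration_experiment(arch, ld, reps = 2)
#' attr(cal, "summary")$mean_fdp
#' }
#' @export
fdr_calibration_experiment <- function(arch, ld, reps,
                                       conj_threshold = 0.05,
                                       n_prunings = 100L) {
  stopifnot(inherits(arch, "architecture_params"), inherits(ld, "ld_structure"))
  assert_that(reps >= 1, "`reps` must be at least 1.")

  per_rep <- purrr::map_dfr(seq_len(reps), function(r) {
    arch_r <- arch
    arch_r$seed <- arch$seed + r
    sim <- simulate_bivariate_sumstats(arch_r, ld)
    pair <- harmonize_pair(sim$sumstats_a, sim$sumstats_b)

    grid_ab <- empirical_cdf_grid(pair, "A|B", ld = ld,
                                  n_prunings = n_prunings,
                                  seed = arch_r$seed + 10000L)
    grid_ba <- empirical_cdf_grid(pair, "B|A", ld = ld,
                                  n_prunings = n_prunings,
                                  seed = arch_r$seed + 20000L)
    snp_fdr <- assign_condfdr(pair, grid_ab, grid_ba,
                              conj_threshold = conj_threshold)

    disc <- snp_fdr$snp[snp_fdr$conjfdr < conj_threshold]
    shared_blocks <- unique(sim$truth$block[sim$truth$component == "shared"])
    disc_blocks <- sim$truth$block[match(disc, sim$truth$snp)]
    n_false <- sum(!(disc_blocks %in% shared_blocks))
    tibble::tibble(
      rep = r,
      n_discoveries = length(disc),
      n_false = n_false,
      fdp = if (length(disc) > 0) n_false / length(disc) else NA_real_
    )
  })

  tot_disc <- sum(per_rep$n_discoveries)
  pooled <- if (tot_disc > 0) sum(per_rep$n_false) / tot_disc else 0
  attr(per_rep, "summary") <- list(
    mean_fdp = mean(per_rep$fdp, na.rm = TRUE),
    pooled_fdp = pooled,
    fdp_mc_se = if (tot_disc > 0) sqrt(pooled * (1 - pooled) / tot_disc) else NA_real_,
    mean_discoveries = mean(per_rep$n_discoveries),
    conj_threshold = conj_threshold
  )
  per_rep
}
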