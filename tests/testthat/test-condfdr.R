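test_that("grid cells reproduce the count-ratio definition on the worked table", {
  p1 <- c(0.001, 0.01, 0.02, 0.5, 0.9)
  p2 <- c(0.005, 0.02, 0.5, 0.03, 0.9)
  # replicate the 5-point pattern to satisfy the minimum-size contract
  pair <- toy_pair(rep(p1, 30), rep(p2, 30))
  g <- empirical_cdf_grid(pair, "A|B",
                          p1_cut = sort(unique(p1)), p2_cut = sort(unique(p2)))
  # cell (u = 0.001, v = 0.005): 30 SNPs with p2 <= v, 30 with both
  expect_equal(g$fdr[1, 1], 0.001)
  # normalization at the coarsest cell
  g_full <- empirical_cdf_grid(pair, "A|B")
  expect_equal(g_full$fdr[101, 101], 1)
  expect_error(empirical_cdf_grid(toy_pair(runif(50), runif(50)), "A|B"),
               "fewer than 100")
})

test_that("per-SNP condFDR equals the brute-force oracle on exact-cutpoint grids", {
  set.seed(15)
  for (rep in 1:4) {
    n <- sample(100:200, 1)
    p1 <- runif(n)^sample(1:3, 1)
    p2 <- runif(n)^sample(1:3, 1)
    pair <- toy_pair(p1, p2)
    gab <- empirical_cdf_grid(pair, "A|B", p1_cut = sort(unique(p1)),
                              p2_cut = sort(unique(p2)))
    gba <- empirical_cdf_grid(pair, "B|A", p1_cut = sort(unique(p2)),
                              p2_cut = sort(unique(p1)))
    res <- assign_condfdr(pair, gab, gba)
    expect_equal(res$condfdr_ab, brute_condfdr(p1, p2), tolerance = 1e-12)
    expect_equal(res$condfdr_ba, brute_condfdr(p2, p1), tolerance = 1e-12)
    # conjunction is exactly the maximum of the two directions
    expect_identical(res$conjfdr, pmax(res$condfdr_ab, res$condfdr_ba))
    expect_true(all(res$conjfdr >= res$condfdr_ab))
    expect_true(all(res$conjfdr >= res$condfdr_ba))
  }
})

test_that("conditioning on v = 1 degenerates to the unconditional BH-style ratio", {
  set.seed(16)
  m <- 20000
  pair <- toy_pair(runif(m), runif(m))
  g <- empirical_cdf_grid(pair, "A|B")
  u <- g$p1_cut
  cnt <- vapply(u, function(ui) sum(pair$p1 <= ui), numeric(1))
  pop <- cnt > 0
  bh <- cummax(pmin(1, (u * m / pmax(cnt, 1))[pop]))
  expect_equal(g$fdr[pop, 101], bh, tolerance = 1e-12)
})

test_that("grid estimation is monotone, flag thresholds honoured, pruning seeded", {
  ld <- simulate_ld_blocks(20000, 10, 0.8)
  sim <- simulate_bivariate_sumstats(
    architecture_params(20000, pi_ab = 0.005, rho_shared = 0.8, seed = 17), ld)
  pair <- harmonize_pair(sim$sumstats_a, sim$sumstats_b)
  g1 <- empirical_cdf_grid(pair, "A|B", ld = ld, n_prunings = 10, seed = 1)
  g2 <- empirical_cdf_grid(pair, "A|B", ld = ld, n_prunings = 10, seed = 1)
  expect_identical(g1$fdr, g2$fdr)

  # monotone non-decreasing in p1 along every conditioning column
  expect_true(all(apply(g1$fdr, 2, function(col) all(diff(col) >= 0))))

  # stronger conditioning cannot worsen the estimate at fixed p1: across the
  # conditioning columns of a strict p1 row the trend is non-decreasing in v,
  # up to pruning noise
  strict <- g1$fdr[40, ]                # p1 cutpoint ~ 1e-7.3
  expect_gt(cor(seq_along(strict), strict, method = "spearman"), 0.9)
  expect_true(all(diff(strict) >= -1e-6))

  snp_fdr <- assign_condfdr(pair, g1,
                            empirical_cdf_grid(pair, "B|A", ld = ld,
                                               n_prunings = 10, seed = 2))
  expect_identical(snp_fdr$flag_conj, snp_fdr$conjfdr < 0.05)
  expect_identical(snp_fdr$flag_cond_ab, snp_fdr$condfdr_ab < 0.01)
  expect_true(all(snp_fdr$conjfdr > 0))
})

test_that("calibration experiment is deterministic and controls block-level FDP", {
  ld <- simulate_ld_blocks(20000, 10, 0.8)
  arch <- architecture_params(20000, pi_ab = 0.002, rho_shared = 0.8, seed = 18)
  cal1 <- fdr_calibration_experiment(arch, ld, reps = 1, n_prunings = 20)
  cal2 <- fdr_calibration_experiment(arch, ld, reps = 1, n_prunings = 20)
  expect_identical(cal1, cal2)
  expect_lte(attr(cal1, "summary")$mean_fdp, 0.10)

  # pure null: essentially no conjunctional discoveries
  cal0 <- fdr_calibration_experiment(architecture_params(20000, seed = 19),
                                     ld, reps = 2, n_prunings = 20)
  expect_lt(attr(cal0, "summary")$mean_discoveries, 1)
})

test_that("per-SNP FDR table writes in the canonical layout", {
  pair <- toy_pair(runif(300), runif(300))
  g_ab <- empirical_cdf_grid(pair, "A|B")
  g_ba <- empirical_cdf_grid(pair, "B|A")
  res <- assign_condfdr(pair, g_ab, g_ba)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_condfdr(res, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(back, c("SNP", "CHR", "BP", "condfdr_ab", "condfdr_ba",
                       "conjfdr", "flag_cond_ab", "flag_cond_ba", "flag_conj"))
  expect_equal(back$conjfdr, res$conjfdr, tolerance = 1e-12)
})
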