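write_tmp_sumstats <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_sumstats validates records and reports drop reasons", {
  z <- 1.5
  p <- 2 * pnorm(-abs(z))
  good <- sprintf("s%d\t1\t%d\tA\tG\t%.10f\t%.10g\t1000\t0.3", 1:3, 1:3, z, p)
  path <- write_tmp_sumstats(c("SNP\tCHR\tBP\tA1\tA2\tZ\tP\tN\tFRQ", good))
  tab <- read_sumstats(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$z, rep(1.5, 3))

  # p = 0 and inconsistent z/p rows are dropped with counts
  bad <- c(sprintf("b1\t1\t10\tA\tG\t%.10f\t0\t1000\t0.3", z),
           "b2\t1\t11\tA\tG\t1.96\t0.5\t1000\t0.3")
  path2 <- write_tmp_sumstats(c("SNP\tCHR\tBP\tA1\tA2\tZ\tP\tN\tFRQ", good, bad))
  tab2 <- suppressMessages(read_sumstats(path2))
  expect_equal(nrow(tab2), 3L)
  dl <- attr(tab2, "drop_log")
  expect_equal(unname(dl["bad_p"]), 1L)
  expect_equal(unname(dl["inconsistent_zp"]), 1L)

  # duplicates keep the record with the largest n
  dup <- c(sprintf("d1\t1\t20\tA\tG\t%.10f\t%.10g\t500\t0.3", z, p),
           sprintf("d1\t1\t20\tA\tG\t%.10f\t%.10g\t2000\t0.3", z, p))
  path3 <- write_tmp_sumstats(c("SNP\tCHR\tBP\tA1\tA2\tZ\tP\tN\tFRQ", dup))
  tab3 <- suppressMessages(read_sumstats(path3))
  expect_equal(tab3$n, 2000)

  # schema and empty-file errors
  path4 <- write_tmp_sumstats(c("SNP\tCHR\tBP\tA1\tZ\tP", "x\t1\t1\tA\t1\t0.5"))
  expect_error(read_sumstats(path4), class = "crosstraitr_schema_error")
  path5 <- write_tmp_sumstats("SNP\tCHR\tBP\tA1\tA2\tZ\tP\tN\tFRQ")
  expect_error(read_sumstats(path5), class = "crosstraitr_empty_input")
})

test_that("z is reconstructed from p and effect direction when absent", {
  p <- 0.04
  lines <- c("SNP\tCHR\tBP\tA1\tA2\tBETA\tP\tN",
             sprintf("s1\t1\t1\tA\tG\t-0.2\t%.10g\t1000", p),
             sprintf("s2\t1\t2\tA\tG\t0.3\t%.10g\t1000", p))
  path <- write_tmp_sumstats(lines)
  tab <- read_sumstats(path)
  expect_equal(tab$z, c(-1, 1) * qnorm(p / 2, lower.tail = FALSE))
})

test_that("harmonize_pair aligns swapped, flipped and palindromic records", {
  z <- 1.5
  a <- toy_sumstats(rep(z, 3))
  a$a1 <- c("A", "A", "A"); a$a2 <- c("G", "G", "T")
  b <- toy_sumstats(c(-z, z, z))
  b$a1 <- c("G", "T", "A"); b$a2 <- c("A", "C", "T")
  pair <- harmonize_pair(a, b)
  # swapped alleles: sign restored; strand complement: sign unchanged
  expect_equal(pair$snp, c("s001", "s002"))
  expect_equal(pair$z2, c(z, z))
  log <- attr(pair, "harmonize_log")
  expect_equal(unname(log["swapped"]), 1L)
  expect_equal(unname(log["strand_flipped"]), 1L)
  expect_equal(unname(log["dropped_palindromic"]), 1L)

  # irreconcilable allele pairs are dropped; empty intersection errors
  b2 <- b
  b2$a1 <- "C"; b2$a2 <- "A"
  pair2 <- harmonize_pair(a[1, ], b2[1, ])
  expect_equal(nrow(pair2), 0L)
  expect_equal(unname(attr(pair2, "harmonize_log")["dropped_irreconcilable"]), 1L)
  b3 <- b
  b3$snp <- paste0("other_", b3$snp)
  expect_error(harmonize_pair(a, b3),
               class = "crosstraitr_empty_intersection")
})

test_that("harmonization is idempotent and symmetric under orientation flips", {
  ld <- simulate_ld_blocks(500, 5, 0.6)
  sim <- simulate_bivariate_sumstats(
    architecture_params(500, pi_ab = 0.02, seed = 8), ld, perturb_b = TRUE)
  pair <- harmonize_pair(sim$sumstats_a, sim$sumstats_b)
  tabs <- pair_tables(pair)
  pair2 <- harmonize_pair(tabs$a, tabs$b)
  expect_equal(pair2, pair, ignore_attr = TRUE)

  # flipping a1/a2 + negating z (+ mirroring frq) in one input is a no-op
  bflip <- sim$sumstats_b
  tmp <- bflip$a1; bflip$a1 <- bflip$a2; bflip$a2 <- tmp
  bflip$z <- -bflip$z
  bflip$frq <- 1 - bflip$frq
  pair3 <- harmonize_pair(sim$sumstats_a, bflip)
  # z-scores must agree bitwise; frequencies only to double-mirroring rounding
  expect_identical(pair3$z2, pair$z2)
  expect_identical(pair3$snp, pair$snp)
  expect_equal(pair3, pair, ignore_attr = TRUE)
})

test_that("exclusion-region filtering matches the published intervals exactly", {
  pts <- tibble::tibble(
    snp = c("mhc_in", "mhc_edge", "mapt_in", "apoe_out", "chr8_in"),
    chr = c("6", "6", "17", "19", "8"),
    bp = c(30000000, 25119105, 44836302, 45912651, 7200000),
    p1 = 0.5, p2 = 0.5
  )
  kept <- filter_exclusion_regions(pts)
  expect_setequal(kept$snp, c("mhc_edge", "apoe_out"))
  expect_equal(attr(kept, "excluded_n"), 3L)

  # brute-force interval scan agrees on random positions
  set.seed(42)
  rand <- tibble::tibble(
    snp = sprintf("r%d", 1:2000),
    chr = sample(c("6", "8", "17", "19", "2"), 2000, replace = TRUE),
    bp = sample.int(6e7, 2000)
  )
  regions <- default_exclusion_regions()
  manual <- vapply(seq_len(nrow(rand)), function(i) {
    any(regions$chr == rand$chr[i] & regions$start <= rand$bp[i] &
          regions$end >= rand$bp[i])
  }, logical(1))
  expect_equal(filter_exclusion_regions(rand)$snp, rand$snp[!manual])
})

test_that("interval and sumstats round-trips preserve content", {
  ld <- simulate_ld_blocks(200, 4, 0.5)
  sim <- simulate_bivariate_sumstats(architecture_params(200, seed = 9), ld)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(sim$sumstats_a, path)
  back <- read_sumstats(path)
  expect_equal(back$snp, sim$sumstats_a$snp)
  expect_equal(back$z, sim$sumstats_a$z, tolerance = 1e-12)

  ipath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chr = "1", start = 100L, end = 200L,
                                  label = "x"), ipath)
  iv <- read_intervals(ipath)
  expect_equal(iv$start, 100L)
  expect_equal(iv$end, 200L)
})
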