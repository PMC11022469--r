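test_that("greedy clumping retains the stated leads and matches brute force", {
  cand <- tibble::tibble(snp = c("s1", "s2", "s3"),
                         conjfdr = c(0.001, 0.002, 0.003))
  r2 <- matrix(c(1, 0.5, 0.05,
                 0.5, 1, 0.05,
                 0.05, 0.05, 1), 3, 3, byrow = TRUE)
  expect_setequal(clump_independent(cand, r2 = r2)$snp, c("s1", "s3"))

  # mutually independent candidates are all retained
  cand4 <- tibble::tibble(snp = paste0("x", 1:4), conjfdr = runif(4))
  expect_equal(nrow(clump_independent(cand4, r2 = diag(4))), 4L)

  # ties at identical conjFDR resolve to the lexicographically smaller id
  tied <- tibble::tibble(snp = c("rs9", "rs1"), conjfdr = c(0.01, 0.01))
  r2t <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  expect_equal(clump_independent(tied, r2 = r2t)$snp, "rs1")

  # randomized candidate sets against the exhaustive oracle
  set.seed(30)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    cf <- round(runif(n), 2)          # deliberate ties
    p1 <- runif(n)
    r2r <- matrix(runif(n * n), n, n)
    r2r <- (r2r + t(r2r)) / 2
    diag(r2r) <- 1
    cnd <- tibble::tibble(snp = sprintf("r%03d", sample(n)),
                          conjfdr = cf, p1 = p1)
    got <- clump_independent(cnd, r2 = r2r)$snp
    want <- cnd$snp[brute_clump(cf, p1, cnd$snp, r2r)]
    expect_setequal(got, want)
  }
})

test_that("clumped leads never share a linked LD block", {
  ld <- simulate_ld_blocks(2000, 10, 0.8)
  cand <- tibble::tibble(snp = sprintf("rs%07d", 1:200),
                         index = sample(2000, 200),
                         conjfdr = runif(200), p1 = runif(200))
  leads <- clump_independent(cand, ld = ld)
  blocks <- ld$block_of[leads$index]
  expect_equal(anyDuplicated(blocks), 0L)
})

test_that("novelty flags follow catalog overlap, counted like the locus table", {
  leads <- tibble::tibble(
    snp = paste0("l", 1:6), chr = as.character(1:6),
    bp = c(100L, 200L, 300L, 400L, 500L, 600L)
  )
  # three leads overlap trait-A intervals, one overlaps trait B
  cat_a <- tibble::tibble(chr = c("1", "2", "3"), start = c(50L, 150L, 250L),
                          end = c(150L, 250L, 350L))
  cat_b <- tibble::tibble(chr = "4", start = 390L, end = 410L)
  out <- flag_novel(leads, cat_a, cat_b)
  expect_equal(sum(!out$novel_for_a), 3L)
  expect_equal(sum(!out$novel_for_b), 1L)
  expect_equal(sum(out$novel_for_a), 3L)
  expect_equal(sum(out$novel_for_b), 5L)
  # a lead overlapping neither catalog is novel for both
  expect_true(out$novel_for_a[6] && out$novel_for_b[6])
})

test_that("positional gene mapping honours the 10 kb window and tie rules", {
  genes <- tibble::tibble(
    chr = c("1", "1", "1", "1"),
    start = c(20000L, 20000L, 60000L, 120000L),
    end = c(30000L, 40000L, 70000L, 125000L),
    gene = c("G1", "G2", "G3", "G4")
  )
  leads <- tibble::tibble(
    snp = c("in_two", "upstream_5kb", "away_10001", "edge_10000"),
    chr = "1",
    bp = c(25000L, 55000L, 80001L, 80000L)
  )
  out <- map_genes_positional(leads, genes, window = 10000L)
  # inside two overlapping genes: both mapped, nearest ties to smaller start
  expect_setequal(out$mapped_genes[[1]], c("G1", "G2"))
  expect_equal(out$nearest_gene[1], "G1")
  expect_equal(out$nearest_distance[1], 0)
  expect_equal(out$nearest_gene[2], "G3")      # 5 kb upstream of gene start
  expect_equal(out$mapped_genes[[3]], character(0))  # 10,001 bp away
  expect_equal(out$nearest_gene[4], "G3")      # exactly 10 kb away

  # agreement with the naive interval scan on random annotations
  set.seed(31)
  rg <- tibble::tibble(chr = "1",
                       start = as.integer(sample.int(1e6, 50)))
  rg$end <- rg$start + as.integer(sample.int(5e4, 50))
  rg$gene <- sprintf("g%02d", 1:50)
  rl <- tibble::tibble(snp = sprintf("s%02d", 1:30), chr = "1",
                       bp = as.integer(sample.int(1e6, 30)))
  got <- map_genes_positional(rl, rg, window = 10000L)$mapped_genes
  want <- brute_gene_map(rl$bp, rl$chr, rg, 10000L)
  for (i in seq_along(got)) expect_setequal(got[[i]], want[[i]])
})

test_that("replication concordance counts sign matches and significance", {
  leads <- tibble::tibble(snp = paste0("r", 1:6),
                          z1 = c(2.1, 3, -2.5, -4, 2.2, 5))
  repl <- toy_sumstats(c(0.8, -3, -2.8, 1.5, -0.5, 4.2),
                       snp = paste0("r", 1:6))
  out <- replication_concordance(leads, repl)
  expect_equal(out$concordant, c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  s <- attr(out, "summary")
  expect_equal(unname(s["n_concordant"]), 3)
  # significance requires both sign match and replication p below threshold
  expect_equal(out$replicated,
               out$concordant & out$p_replication < 0.05)
  # leads absent from the replication table are found = FALSE
  out2 <- replication_concordance(tibble::tibble(snp = "missing", z1 = 1),
                                  repl)
  expect_false(out2$found)
})

test_that("locus table assembles the standard columns", {
  leads <- tibble::tibble(
    snp = "rs1", chr = "11", bp = 88976157L, conjfdr = 7.81e-5,
    a1 = "T", a2 = "C", frq1 = 0.37, z1 = 2, z2 = 3,
    nearest_gene = "TYR", novel_for_a = TRUE, novel_for_b = FALSE
  )
  lt <- locus_table(leads)
  expect_equal(lt$nearest_gene, "TYR")
  expect_true(lt$concordant)
  expect_named(lt, c("snp", "chr", "bp", "nearest_gene", "a1", "a2", "frq",
                     "conjfdr", "novel_for_a", "novel_for_b", "concordant"))
})
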