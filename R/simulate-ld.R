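#' Simulate a block-exchangeable LD structure
#'
#' Builds a block-diagonal linkage-disequilibrium (LD) structure over `m_snps`
#' markers. Within a block every pair of SNPs has genotype correlation `rho`
#' (an exchangeable-correlation model); across blocks SNPs are independent.
#' This deliberately simple LD model is sufficient to exercise LD scores,
#' random pruning and clumping, which is what downstream stages consume.
#'
#' The per-SNP LD score is the sum of squared correlations with all SNPs
#' (including itself), so an LD-free SNP has score exactly 1 and a SNP in a
#' block of size `s` has score `1 + (s - 1) * rho^2`.
#'
#' @param m_snps Number of SNPs (positive integer).
#' @param block_size Number of SNPs per block; the final block is truncated if
#'   `m_snps` is not a multiple. `block_size = 1` yields an LD-free panel.
#' @param rho Within-block genotype correlation, in `[0, 1)`.
#'
#' @return An object of class `ld_structure`: a list with
#'   `m` (SNP count), `blocks` (a tibble with one row per block: `block`,
#'   `start`, `end`, `size`, `rho`), `block_of` (integer block index per SNP)
#'   and `ld_score` (numeric per-SNP LD score).
#' @examples
#' ld <- simulate_ld_blocks(100, block_size = 10, rho = 0.8)
#' head(ld$ld_score)
#' @export
simulate_ld_blocks <- function(m_snps, block_size, rho) {
  assert_that(length(m_snps) == 1L && m_snps >= 1 && m_snps == as.integer(m_snps),
              "`m_snps` must be a positive integer.")
  assert_that(length(block_size) == 1L && block_size >= 1 &&
                block_size == as.integer(block_size),
              "`block_size` must be a positive integer.")
  assert_that(is.numeric(rho) && length(rho) == 1L && is.finite(rho) &&
                rho >= 0 && rho < 1,
              "`rho` must lie in [0, 1).")
  m_snps <- as.integer(m_snps)
  block_size <- as.integer(block_size)

  n_blocks <- ceiling(m_snps / block_size)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(m_snps)]
  sizes <- tabulate(block_of, nbins = n_blocks)
  start <- cumsum(c(1L, sizes[-n_blocks]))
  blocks <- tibble::tibble(
    block = seq_len(n_blocks),
    start = start,
    end = start + sizes - 1L,
    size = sizes,
    rho = rho
  )
  ld_score <- 1 + (sizes[block_of] - 1) * rho^2

  structure(
    list(m = m_snps, blocks = blocks, block_of = block_of, ld_score = ld_score),
    class = "ld_structure"
  )
}

#' @export
print.ld_structure <- function(x, ...) {
  cat(sprintf(
    "<ld_structure> %d SNPs in %d exchangeable blocks (rho = %s)\n",
    x$m, nrow(x$blocks), format(x$blocks$rho[1])
  ))
  cat(sprintf("  LD score range: [%.3f, %.3f]\n",
              min(x$ld_score), max(x$ld_score)))
  invisible(x)
}

#' Within-block correlation matrix of one LD block
#'
#' @param ld An `ld_structure`.
#' @param block Block index.
#' @return A symmetric unit-diagonal correlation matrix.
#' @export
ld_block_matrix <- function(ld, block) {
  stopifnot(inherits(ld, "ld_structure"))
  b <- ld$blocks[ld$blocks$block == block, ]
  assert_that(nrow(b) == 1L, "unknown block index")
  s <- b$size
  mat <- matrix(b$rho, s, s)
  diag(mat) <- 1
  mat
}

#' Pairwise r-squared between SNPs under a block LD structure
#'
#' Returns the squared correlation for every pair of the supplied SNP indices:
#' 1 on the diagonal, `rho^2` for distinct SNPs sharing a block, 0 otherwise.
#' Intended for small candidate sets (clumping); not materialized genome-wide.
#'
#' @param ld An `ld_structure`.
#' @param idx Integer vector of SNP indices (1-based).
#' @return A length(idx) x length(idx) matrix of r-squared values.
#' @export
ld_r2_matrix <- function(ld, idx) {
  stopifnot(inherits(ld, "ld_structure"))
  assert_that(all(idx >= 1 & idx <= ld$m), "SNP index out of range")
  blk <- ld$block_of[idx]
  rho <- ld$blocks$rho[blk]
  same <- outer(blk, blk, "==")
  r2 <- same * outer(rho, rho, function(a, b) a * b) # rho^2 within a block
  diag(r2) <- 1
  r2
}
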