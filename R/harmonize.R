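#' Harmonize two summary-statistics tables to a common allele orientation
#'
#' Intersects the two tables on SNP id and aligns trait B's records to trait
#' A's effect allele. For each shared SNP the allele pair is classified as:
#' identical; swapped (B's z is sign-flipped and its frequency mirrored);
#' strand-complemented (alleles complemented, z unchanged); complemented and
#' swapped; or irreconcilable (dropped). Palindromic variants (A/T, C/G) carry
#' no strand information in their alleles and are dropped by default.
#'
#' @param a,b Summary-statistics tibbles (columns `snp, chr, bp, a1, a2, z, p,
#'   n, frq`), e.g. from [read_sumstats()].
#' @param keep_palindromic If `TRUE`, palindromic SNPs are retained when the
#'   two tables' effect-allele frequencies identify the orientation: kept
#'   as-is when `|frq1 - frq2| <= freq_tol`, sign-flipped when
#'   `|frq1 - (1 - frq2)| <= freq_tol`, dropped otherwise.
#' @param freq_tol Frequency-difference tolerance for the palindromic rule.
#' @return A harmonized-pair tibble with columns `snp, chr, bp, a1, a2, z1,
#'   p1, n1, frq1, z2, p2, n2, frq2` and an attribute `harmonize_log` counting
#'   `matched`, `swapped`, `strand_flipped`, `dropped_palindromic`,
#'   `dropped_irreconcilable`.
#' @examples
#' ld <- simulate_ld_blocks(500, 5, 0.6)
#' sim <- simulate_bivariate_sumstats(
#'   architecture_params(500, seed = 3), ld, perturb_b = TRUE)
#' pair <- harmonize_pair(sim$sumstats_a, sim$sumstats_b)
#' attr(pair, "harmonize_log")
#' @export
harmonize_pair <- function(a, b, keep_palindromic = FALSE, freq_tol = 0.2) {
  for (tab in list(a, b)) {
    assert_that(all(c("snp", "a1", "a2", "z", "p") %in% names(tab)),
                "inputs must be validated summary-statistics tables.")
  }
  j <- dplyr::inner_join(
    a, b, by = "snp", suffix = c("1", "2"), relationship = "one-to-one"
  )
  if (nrow(j) == 0L) {
    rlang::abort("no SNPs shared between the two tables.",
                 class = "crosstraitr_empty_intersection")
  }

  exact <- j$a11 == j$a12 & j$a21 == j$a22
  swap  <- j$a11 == j$a22 & j$a21 == j$a12
  c1 <- complement_allele(j$a12); c2 <- complement_allele(j$a22)
  flip      <- j$a11 == c1 & j$a21 == c2
  flip_swap <- j$a11 == c2 & j$a21 == c1
  pal <- is_palindromic(j$a11, j$a21) | is_palindromic(j$a12, j$a22)
  # for palindromic pairs "swap" and "flip_swap" (etc.) coincide; handle apart
  status <- dplyr::case_when(
    pal ~ "palindromic",
    exact ~ "exact",
    swap ~ "swap",
    flip ~ "flip",
    flip_swap ~ "flip_swap",
    .default = "irreconcilable"
  )

  keep_pal <- logical(nrow(j))
  pal_flip <- logical(nrow(j))
  if (isTRUE(keep_palindromic)) {
    # a palindromic pair's strand cannot be read off the alleles; the two
    # interpretations (same effect allele vs opposite) predict frq2 ~ frq1 and
    # frq2 ~ 1 - frq1 respectively — keep only when exactly one rule matches
    letters_match <- pal & (exact | swap | flip | flip_swap)
    frq_ok_same <- !is.na(j$frq1) & !is.na(j$frq2) &
      abs(j$frq1 - j$frq2) <= freq_tol
    frq_ok_flip <- !is.na(j$frq1) & !is.na(j$frq2) &
      abs(j$frq1 - (1 - j$frq2)) <= freq_tol
    keep_pal <- letters_match & xor(frq_ok_same, frq_ok_flip)
    pal_flip <- keep_pal & frq_ok_flip
  }

  z2 <- j$z2
  frq2 <- j$frq2
  sflip <- status %in% c("swap", "flip_swap") | (status == "palindromic" & pal_flip)
  z2[sflip] <- -z2[sflip]
  frq2[sflip] <- 1 - frq2[sflip]

  keep <- status %in% c("exact", "swap", "flip", "flip_swap") |
    (status == "palindromic" & keep_pal)

  out <- tibble::tibble(
    snp = j$snp, chr = j$chr1, bp = j$bp1,
    a1 = j$a11, a2 = j$a21,
    z1 = j$z1, p1 = j$p1, n1 = j$n1, frq1 = j$frq1,
    z2 = z2, p2 = j$p2, n2 = j$n2, frq2 = frq2
  )[keep, ]

  attr(out, "harmonize_log") <- c(
    matched = sum(keep),
    swapped = sum(status == "swap"),
    strand_flipped = sum(status %in% c("flip", "flip_swap")),
    dropped_palindromic = sum(status == "palindromic" & !keep_pal),
    dropped_irreconcilable = sum(status == "irreconcilable")
  )
  out
}

#' Split a harmonized pair back into two per-trait tables
#'
#' Useful for round-trip checks and for feeding single-trait stages.
#'
#' @param pair A harmonized-pair tibble.
#' @return A list of two summary-statistics tibbles `a` and `b`, both on the
#'   shared orientation.
#' @export
pair_tables <- function(pair) {
  list(
    a = tibble::tibble(snp = pair$snp, chr = pair$chr, bp = pair$bp,
                       a1 = pair$a1, a2 = pair$a2, z = pair$z1, p = pair$p1,
                       n = pair$n1, frq = pair$frq1),
    b = tibble::tibble(snp = pair$snp, chr = pair$chr, bp = pair$bp,
                       a1 = pair$a1, a2 = pair$a2, z = pair$z2, p = pair$p2,
                       n = pair$n2, frq = pair$frq2)
  )
}
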