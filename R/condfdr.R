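#' Log-spaced p-value cutpoints for the condFDR grid
#'
#' @param n Number of cutpoints.
#' @param p_min Smallest cutpoint; the grid always ends at 1.
#' @return Increasing numeric vector of length `n`.
#' @export
fdr_grid_cutpoints <- function(n = 101, p_min = 1e-12) {
  10^seq(log10(p_min), 0, length.out = n)
}

# bin index per p-value: smallest i with p <= cut[i]; values below cut[1]
# are clamped into the first cell
bin_index <- function(p, cut) {
  i <- findInterval(p, cut, left.open = TRUE) + 1L
  pmin(pmax(i, 1L), length(cut))
}

# one random pruning: within every LD block whose exchangeable r^2 exceeds
# the threshold, retain a single SNP uniformly at random; others keep all
prune_once <- function(ld, r2_thresh) {
  linked <- ld$blocks$rho^2 > r2_thresh & ld$blocks$size > 1L
  keep <- rep(TRUE, ld$m)
  if (any(linked)) {
    b <- ld$blocks[linked, ]
    pick <- b$start + floor(runif(nrow(b)) * b$size)
    drop <- ld$block_of %in% b$block
    keep[drop] <- FALSE
    keep[pick] <- TRUE
  }
  keep
}

#' Estimate the conditional-FDR lookup grid from a harmonized pair
#'
#' Computes, on a 2-D grid of p-value cutpoints, the conditional FDR of the
#' primary trait given the secondary:
#' `condFDR(u | v) = u * #\{p2 <= v\} / #\{p1 <= u & p2 <= v\}`,
#' with the null proportion conservatively fixed at 1 and values capped at 1.
#' When an LD structure is supplied, the counts are averaged over
#' `n_prunings` random prunings that keep one SNP per linked LD block
#' (exchangeable within-block r-squared above `r2_thresh`), so correlated
#' SNPs do not dominate the empirical CDFs. Cells whose denominator is empty
#' inherit the value of the nearest populated coarser cell, and monotonicity
#' in the primary p-value is enforced by a running maximum along each column.
#'
#' @param pair Harmonized-pair tibble (needs `p1`, `p2`).
#' @param direction `"A|B"` (primary = trait A, the default) or `"B|A"`.
#' @param p1_cut,p2_cut Increasing cutpoint vectors; default
#'   [fdr_grid_cutpoints()] (101 log-spaced points from 1e-12 to 1).
#' @param ld Optional [simulate_ld_blocks()] structure aligned with `pair`
#'   rows; `NULL` disables pruning.
#' @param n_prunings Number of random prunings to average over when `ld` is
#'   supplied.
#' @param r2_thresh Within-block r-squared above which a block is pruned to a
#'   single SNP per iteration.
#' @param seed Integer seed for the prunings (required when `ld` is given).
#' @return An object of class `fdr_grid`: list with `p1_cut`, `p2_cut`,
#'   `fdr` (matrix, rows = primary cutpoints), `direction`, `n_prunings`,
#'   `r2_thresh`, `m`, `seed`.
#' @export
empirical_cdf_grid <- function(pair, direction = c("A|B", "B|A"),
                               p1_cut = fdr_grid_cutpoints(),
                               p2_cut = fdr_grid_cutpoints(),
                               ld = NULL, n_prunings = 100L, r2_thresh = 0.1,
                               seed = NULL) {
  direction <- match.arg(direction)
  assert_that(nrow(pair) >= 100,
              "fewer than 100 SNPs: the empirical grid is unidentifiable.")
  assert_that(all(diff(p1_cut) > 0) && all(diff(p2_cut) > 0),
              "grid cutpoints must be strictly increasing.")
  if (!is.null(ld)) {
    assert_that(inherits(ld, "ld_structure") && ld$m == nrow(pair),
                "`ld` must align with the rows of `pair`.")
    seed <- assert_seed(seed)
  }

  if (direction == "A|B") {
    pp <- pair$p1; ps <- pair$p2
  } else {
    pp <- pair$p2; ps <- pair$p1
  }
  g1 <- length(p1_cut); g2 <- length(p2_cut)
  i1 <- bin_index(pp, p1_cut)
  i2 <- bin_index(ps, p2_cut)

  cell_counts <- function(keep) {
    tabulate(i1[keep] + (i2[keep] - 1L) * g1, nbins = g1 * g2)
  }

  if (is.null(ld)) {
    counts <- cell_counts(rep(TRUE, length(pp)))
    n_prunings <- 1L
  } else {
    counts <- numeric(g1 * g2)
    withr::local_seed(seed)
    for (r in seq_len(n_prunings)) {
      counts <- counts + cell_counts(prune_once(ld, r2_thresh))
    }
    counts <- counts / n_prunings
  }
  cells <- matrix(counts, g1, g2)
  n12 <- apply(cells, 2, cumsum)          # joint count, cumulative in p1
  n12 <- t(apply(n12, 1, cumsum))         # and in p2
  n2 <- n12[g1, ]                         # marginal secondary count

  fdr <- outer(p1_cut, n2) / n12
  fdr[n12 == 0] <- NA_real_
  fdr <- pmin(fdr, 1)

  # the joint count is cumulative in both axes, so empty cells form a bottom
  # prefix of each column (and fully empty columns a prefix in v): enforce
  # monotonicity by a running maximum over the populated cells of a column,
  # let the empty prefix inherit the nearest populated (coarser) value, and
  # let empty columns inherit the next coarser conditioning column
  for (k in g2:1) {
    col <- fdr[, k]
    first <- which(!is.na(col))[1]
    if (is.na(first)) {
      fdr[, k] <- fdr[, k + 1]            # column g2 is never empty (v = max)
    } else {
      col[first:g1] <- cummax(col[first:g1])
      if (first > 1) col[seq_len(first - 1)] <- col[first]
      fdr[, k] <- col
    }
  }

  structure(
    list(p1_cut = p1_cut, p2_cut = p2_cut, fdr = fdr, direction = direction,
         n_prunings = as.integer(n_prunings),
         r2_thresh = if (is.null(ld)) NA_real_ else r2_thresh,
         m = nrow(pair), seed = seed),
    class = "fdr_grid"
  )
}

#' @export
print.fdr_grid <- function(x, ...) {
  cat(sprintf(
    "<fdr_grid %s> %d x %d cutpoints, %d SNPs, %d pruning iteration(s)\n",
    x$direction, length(x$p1_cut), length(x$p2_cut), x$m, x$n_prunings))
  invisible(x)
}

#' @describeIn empirical_cdf_grid tidy method: the grid in long form
#'   (`p1_cut`, `p2_cut`, `condfdr`).
#' @param x An `fdr_grid`.
#' @param ... Unused.
#' @method tidy fdr_grid
#' @export
tidy.fdr_grid <- function(x, ...) {
  tibble::tibble(
    p1_cut = rep(x$p1_cut, times = length(x$p2_cut)),
    p2_cut = rep(x$p2_cut, each = length(x$p1_cut)),
    condfdr = as.vector(x$fdr)
  )
}

# bilinear interpolation of the grid surface in log10(p) coordinates;
# exact at the cutpoints, clamped outside the grid range
lookup_fdr <- function(grid, p_primary, p_secondary) {
  interp_axis <- function(p, cut) {
    lc <- log10(cut)
    x <- pmin(pmax(log10(p), lc[1]), lc[length(lc)])
    i <- findInterval(x, lc, all.inside = TRUE)
    w <- (x - lc[i]) / (lc[i + 1] - lc[i])
    list(i = i, w = w)
  }
  a1 <- interp_axis(p_primary, grid$p1_cut)
  a2 <- interp_axis(p_secondary, grid$p2_cut)
  f <- grid$fdr
  (1 - a1$w) * (1 - a2$w) * f[cbind(a1$i, a2$i)] +
    a1$w       * (1 - a2$w) * f[cbind(a1$i + 1L, a2$i)] +
    (1 - a1$w) * a2$w       * f[cbind(a1$i, a2$i + 1L)] +
    a1$w       * a2$w       * f[cbind(a1$i + 1L, a2$i + 1L)]
}

#' Assign per-SNP conditional and conjunctional FDR values
#'
#' Looks up each SNP's condFDR in both directions on the two estimated grids
#' (bilinear interpolation in log10 p; SNPs outside the grid range are
#' clamped to the boundary) and sets the conjunctional FDR to the maximum of
#' the two directional values. Significance flags use the conventional
#' thresholds: condFDR < 0.01 per direction, conjFDR < 0.05.
#'
#' @param pair Harmonized-pair tibble.
#' @param grid_ab Grid with direction `"A|B"` (primary trait A).
#' @param grid_ba Grid with direction `"B|A"`.
#' @param cond_threshold,conj_threshold Significance thresholds for the flags.
#' @return `pair` with added columns `condfdr_ab`, `condfdr_ba`, `conjfdr`,
#'   `flag_cond_ab`, `flag_cond_ba`, `flag_conj`.
#' @export
assign_condfdr <- function(pair, grid_ab, grid_ba,
                           cond_threshold = 0.01, conj_threshold = 0.05) {
  stopifnot(inherits(grid_ab, "fdr_grid"), inherits(grid_ba, "fdr_grid"))
  assert_that(grid_ab$direction == "A|B" && grid_ba$direction == "B|A",
              "grids must cover the two opposite conditioning directions.")
  out <- pair
  out$condfdr_ab <- lookup_fdr(grid_ab, pair$p1, pair$p2)
  out$condfdr_ba <- lookup_fdr(grid_ba, pair$p2, pair$p1)
  out$conjfdr <- pmax(out$condfdr_ab, out$condfdr_ba)
  out$flag_cond_ab <- out$condfdr_ab < cond_threshold
  out$flag_cond_ba <- out$condfdr_ba < cond_threshold
  out$flag_conj <- out$conjfdr < conj_threshold
  out
}

#' Write the per-SNP FDR table in the canonical TSV layout
#'
#' @param snp_fdr Result of [assign_condfdr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_condfdr <- function(snp_fdr, path) {
  out <- tibble::tibble(
    SNP = snp_fdr$snp, CHR = snp_fdr$chr, BP = snp_fdr$bp,
    condfdr_ab = snp_fdr$condfdr_ab, condfdr_ba = snp_fdr$condfdr_ba,
    conjfdr = snp_fdr$conjfdr,
    flag_cond_ab = snp_fdr$flag_cond_ab, flag_cond_ba = snp_fdr$flag_cond_ba,
    flag_conj = snp_fdr$flag_conj
  )
  readr::write_tsv(out, path)
  invisible(path)
}
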