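# independent brute-force oracles and small fixture builders shared by the
# test files; every oracle avoids the package's grid/cumulative machinery

# per-SNP condFDR by direct counting: for SNP j, the running maximum over all
# observed primary cutpoints u <= p1_j of min(1, u * #{p2 <= p2_j} / #{both})
brute_condfdr <- function(p_primary, p_secondary) {
  vapply(seq_along(p_primary), function(j) {
    n2 <- sum(p_secondary <= p_secondary[j])
    us <- sort(unique(p_primary[p_primary <= p_primary[j]]))
    vals <- vapply(us, function(u) {
      cnt <- sum(p_primary <= u & p_secondary <= p_secondary[j])
      if (cnt == 0) NA_real_ else min(1, u * n2 / cnt)
    }, numeric(1))
    max(vals, na.rm = TRUE)
  }, numeric(1))
}

# exhaustive greedy clumping on an explicit r2 matrix
brute_clump <- function(conjfdr, p1, snp, r2, r2_thresh = 0.2) {
  ord <- order(conjfdr, p1, snp)
  alive <- rep(TRUE, length(conjfdr))
  leads <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    leads <- c(leads, i)
    for (j in seq_along(alive)) if (r2[i, j] >= r2_thresh) alive[j] <- FALSE
  }
  leads
}

# naive O(n * m) positional gene mapping
brute_gene_map <- function(bp, chr, genes, window) {
  lapply(seq_along(bp), function(i) {
    hits <- character(0)
    for (g in seq_len(nrow(genes))) {
      if (genes$chr[g] != chr[i]) next
      d <- max(0, genes$start[g] - bp[i], bp[i] - genes$end[g])
      if (d <= window) hits <- c(hits, genes$gene[g])
    }
    hits
  })
}

# direct per-SNP mixture density evaluation (no grouping machinery): the
# independent check of the composite-likelihood implementation
brute_uni_loglik <- function(z, ld_scores, pi, sigma2, sigma0, n) {
  sum(vapply(seq_along(z), function(j) {
    L <- max(1L, as.integer(round(ld_scores[j])))
    h <- ld_scores[j] / L
    dens <- 0
    for (k in 0:L) {
      dens <- dens + dbinom(k, L, pi) *
        dnorm(z[j], 0, sqrt(sigma0^2 + n * sigma2 * h * k))
    }
    log(dens)
  }, numeric(1)))
}

brute_biv_loglik <- function(z1, z2, ld_scores, pi_a, pi_b, pi_ab,
                             rho_shared, rho0, s2a, s2b, s0a, s0b, n_a, n_b) {
  dmvn2 <- function(x, y, v1, v2, cv) {
    det <- v1 * v2 - cv^2
    exp(-log(2 * pi) - 0.5 * log(det) -
          0.5 * (v2 * x^2 - 2 * cv * x * y + v1 * y^2) / det)
  }
  p0 <- 1 - pi_a - pi_b - pi_ab
  sum(vapply(seq_along(z1), function(j) {
    L <- max(1L, as.integer(round(ld_scores[j])))
    h <- ld_scores[j] / L
    dens <- 0
    for (ka in 0:L) for (kb in 0:(L - ka)) for (kc in 0:(L - ka - kb)) {
      k0 <- L - ka - kb - kc
      w <- exp(lgamma(L + 1) - lgamma(ka + 1) - lgamma(kb + 1) -
                 lgamma(kc + 1) - lgamma(k0 + 1)) *
        pi_a^ka * pi_b^kb * pi_ab^kc * p0^k0
      if (w < 1e-14) next
      v1 <- s0a^2 + n_a * s2a * h * (ka + kc)
      v2 <- s0b^2 + n_b * s2b * h * (kb + kc)
      cv <- rho0 * s0a * s0b + rho_shared * sqrt(n_a * n_b * s2a * s2b) * h * kc
      dens <- dens + w * dmvn2(z1[j], z2[j], v1, v2, cv)
    }
    log(dens)
  }, numeric(1)))
}

# minimal valid summary-statistics tibble around given z-scores
toy_sumstats <- function(z, snp = sprintf("s%03d", seq_along(z)),
                         chr = "1", bp = seq_along(z), n = 1000) {
  tibble::tibble(
    snp = snp, chr = chr, bp = bp,
    a1 = "A", a2 = "G", z = z, p = 2 * pnorm(-abs(z)), n = n, frq = 0.3
  )
}

# harmonized pair straight from p-values (for FDR/QQ machinery tests)
toy_pair <- function(p1, p2) {
  tibble::tibble(
    snp = sprintf("s%04d", seq_along(p1)), chr = "1", bp = seq_along(p1),
    a1 = "A", a2 = "G",
    z1 = qnorm(p1 / 2, lower.tail = FALSE), p1 = p1, n1 = 1000, frq1 = 0.3,
    z2 = qnorm(p2 / 2, lower.tail = FALSE), p2 = p2, n2 = 1000, frq2 = 0.3
  )
}
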