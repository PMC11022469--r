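#' Reduce conjFDR-significant SNPs to independent lead SNPs
#'
#' Greedy LD clumping: candidates are visited in order of ascending conjFDR
#' (ties broken by ascending primary p-value, then SNP id); each selected
#' lead removes every remaining candidate in LD with it at
#' `r2 >= r2_thresh`. The retained leads are therefore pairwise independent
#' at the stated threshold. Results are returned in genomic order.
#'
#' @param candidates Tibble of significant SNPs: needs `snp`, `conjfdr`, and
#'   either row alignment with `ld` via an `index` column (row number in the
#'   LD panel) or a complete `r2` matrix; `p1`, `chr`, `bp`, `z1`, `z2`
#'   carried through when present.
#' @param ld Optional [simulate_ld_blocks()] structure; pairwise r-squared is
#'   derived from block membership.
#' @param r2 Optional explicit r-squared matrix (rows/cols follow
#'   `candidates`); overrides `ld`.
#' @param r2_thresh Independence threshold (default 0.2): a lead excludes
#'   candidates with `r2 >= r2_thresh`.
#' @return The retained lead rows, ordered by `chr`/`bp` when present, with a
#'   `lead_rank` column giving the greedy selection order.
#' @examples
#' cand <- tibble::tibble(snp = c("s1", "s2", "s3"),
#'                        conjfdr = c(0.001, 0.002, 0.003))
#' r2 <- matrix(c(1, .5, .05, .5, 1, .05, .05, .05, 1), 3, 3)
#' clump_independent(cand, r2 = r2)$snp
#' @export
clump_independent <- function(candidates, ld = NULL, r2 = NULL,
                              r2_thresh = 0.2) {
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  assert_that(!is.null(r2) || !is.null(ld),
              "supply either an `r2` matrix or an `ld` structure.")
  if (is.null(r2)) {
    idx <- candidates[["index"]] %||% match(candidates$snp,
                                       sprintf("rs%07d", seq_len(ld$m)))
    assert_that(!anyNA(idx),
                "candidates must carry an `index` column into the LD panel.")
    r2 <- ld_r2_matrix(ld, idx)
  }
  assert_that(nrow(r2) == n && ncol(r2) == n,
              "`r2` must be square and aligned with `candidates`.")

  p1 <- candidates[["p1"]] %||% rep(0, n)
  ord <- order(candidates$conjfdr, p1, candidates$snp)
  alive <- rep(TRUE, n)
  leads <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    leads <- c(leads, i)
    alive[r2[i, ] >= r2_thresh] <- FALSE
  }
  out <- candidates[leads, ]
  out$lead_rank <- seq_along(leads)
  if (all(c("chr", "bp") %in% names(out))) {
    out <- dplyr::arrange(out, suppressWarnings(as.numeric(.data$chr)),
                          .data$bp)
  }
  out
}

# distance from a position to a 1-based inclusive interval; 0 inside
interval_distance <- function(pos, start, end) {
  pmax(0, pmax(start - pos, pos - end))
}

#' Flag lead SNPs as novel against per-trait locus catalogs
#'
#' A lead is novel for a trait when its position overlaps no interval in that
#' trait's catalog of known associated loci (1-based inclusive coordinates).
#'
#' @param leads Lead tibble (`snp`, `chr`, `bp`).
#' @param catalog_a,catalog_b Interval tibbles (`chr`, `start`, `end`) of
#'   known loci for each trait, e.g. from [read_intervals()].
#' @return `leads` with logical columns `novel_for_a`, `novel_for_b`.
#' @export
flag_novel <- function(leads, catalog_a, catalog_b) {
  in_catalog <- function(chr, bp, cat) {
    if (is.null(cat) || nrow(cat) == 0L) return(rep(FALSE, length(bp)))
    vapply(seq_along(bp), function(i) {
      any(sub("^chr", "", as.character(cat$chr)) ==
            sub("^chr", "", as.character(chr[i])) &
            cat$start <= bp[i] & cat$end >= bp[i])
    }, logical(1))
  }
  leads$novel_for_a <- !in_catalog(leads$chr, leads$bp, catalog_a)
  leads$novel_for_b <- !in_catalog(leads$chr, leads$bp, catalog_b)
  leads
}

#' Positionally map lead SNPs to nearby genes
#'
#' Maps each lead to all genes whose interval, expanded by `window` on both
#' sides, contains the lead position. The nearest gene has minimal distance
#' (0 inside the gene body), ties broken by smaller gene start.
#'
#' @param leads Lead tibble (`snp`, `chr`, `bp`).
#' @param genes Gene annotation tibble: `chr`, `start`, `end`, `gene`
#'   (1-based inclusive), e.g. from [read_gene_annotation()].
#' @param window Mapping window in bp (default 10000).
#' @return `leads` with `nearest_gene`, `nearest_distance` and a list-column
#'   `mapped_genes` of all genes within the window.
#' @export
map_genes_positional <- function(leads, genes, window = 10000L) {
  assert_that(all(c("chr", "start", "end", "gene") %in% names(genes)),
              "`genes` must have columns chr, start, end, gene.")
  gchr <- sub("^chr", "", as.character(genes$chr))
  mapped <- purrr::map(seq_len(nrow(leads)), function(i) {
    same <- gchr == sub("^chr", "", as.character(leads$chr[i]))
    d <- interval_distance(leads$bp[i], genes$start, genes$end)
    hit <- same & d <= window
    g <- genes[hit, ]
    g$distance <- d[hit]
    dplyr::arrange(g, .data$distance, .data$start)
  })
  leads$mapped_genes <- purrr::map(mapped, function(g) g$gene)
  leads$nearest_gene <- purrr::map_chr(mapped, function(g) {
    if (nrow(g) == 0L) NA_character_ else g$gene[1]
  })
  leads$nearest_distance <- purrr::map_dbl(mapped, function(g) {
    if (nrow(g) == 0L) NA_real_ else g$distance[1]
  })
  leads
}

#' Read a gene annotation from BED or GFF into the package's tibble layout
#'
#' @param path BED (0-based half-open; converted) or GFF/GTF file; parsed via
#'   rtracklayer. GFF input is filtered to `type == "gene"` records when a
#'   type field is present, and the gene name is taken from the first of
#'   `Name`, `gene_name`, `gene_id`, `ID`, `name` available.
#' @return Tibble with `chr`, `start`, `end`, `gene`.
#' @export
read_gene_annotation <- function(path) {
  assert_that(requireNamespace("rtracklayer", quietly = TRUE),
              "reading annotations requires the rtracklayer package.")
  df <- as.data.frame(rtracklayer::import(path))
  if ("type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", ]
  }
  name_col <- intersect(c("Name", "gene_name", "gene_id", "ID", "name"),
                        names(df))[1]
  assert_that(!is.na(name_col), "no gene-name attribute found in annotation.")
  tibble::tibble(
    chr = sub("^chr", "", as.character(df$seqnames)),
    start = as.integer(df$start),
    end = as.integer(df$end),
    gene = as.character(df[[name_col]])
  )
}

#' Test direction-of-effect replication of lead SNPs in an independent cohort
#'
#' Joins the leads with a replication summary-statistics table (which must
#' already share the leads' effect-allele orientation) and reports, per lead,
#' whether it was found, whether the effect direction is concordant
#' (`sign(z1) == sign(z_replication)`) and whether it passes the replication
#' significance threshold.
#'
#' @param leads Lead tibble with `snp` and `z1` (discovery z-scores).
#' @param replication Summary-statistics tibble for the replication sample.
#' @param p_threshold Replication significance cutoff (default 0.05).
#' @return A tibble with per-lead columns `found`, `z_replication`,
#'   `p_replication`, `concordant`, `replicated` (concordant and significant);
#'   attribute `summary` holds the counts.
#' @export
replication_concordance <- function(leads, replication, p_threshold = 0.05) {
  rep_idx <- match(leads$snp, replication$snp)
  out <- leads
  out$found <- !is.na(rep_idx)
  out$z_replication <- replication$z[rep_idx]
  out$p_replication <- replication$p[rep_idx]
  out$concordant <- out$found & sign(out$z1) == sign(out$z_replication)
  out$replicated <- out$concordant & !is.na(out$p_replication) &
    out$p_replication < p_threshold
  attr(out, "summary") <- c(
    n_leads = nrow(out),
    n_found = sum(out$found),
    n_concordant = sum(out$concordant, na.rm = TRUE),
    n_replicated = sum(out$replicated, na.rm = TRUE)
  )
  out
}

#' Assemble the shared-locus table
#'
#' Combines clumped leads with gene mapping, novelty flags and cross-trait
#' sign concordance into the standard locus-table layout (SNP, chromosome,
#' position, nearest gene, alleles, frequency, conjFDR, flags).
#'
#' @param leads Result of [clump_independent()] after
#'   [map_genes_positional()] and/or [flag_novel()]; needs `z1` and `z2` for
#'   the concordance column.
#' @return A tibble with one row per locus.
#' @export
locus_table <- function(leads) {
  tibble::tibble(
    snp = leads$snp,
    chr = leads[["chr"]] %||% NA_character_,
    bp = leads[["bp"]] %||% NA_integer_,
    nearest_gene = leads[["nearest_gene"]] %||% NA_character_,
    a1 = leads[["a1"]] %||% NA_character_,
    a2 = leads[["a2"]] %||% NA_character_,
    frq = leads[["frq1"]] %||% NA_real_,
    conjfdr = leads$conjfdr,
    novel_for_a = leads[["novel_for_a"]] %||% NA,
    novel_for_b = leads[["novel_for_b"]] %||% NA,
    concordant = if (!is.null(leads[["z1"]]) && !is.null(leads[["z2"]]))
      sign(leads$z1) == sign(leads$z2) else NA
  )
}
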