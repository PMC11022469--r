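#' Default column-name dialect for summary-statistics files
#'
#' Maps canonical field names to the column headers expected in the file.
#' Override entries (or supply a YAML file with the same keys) when reading
#' tables from other tools.
#'
#' @return Named character vector: canonical name -> file column name.
#' @export
sumstats_dialect <- function() {
  c(snp = "SNP", chr = "CHR", bp = "BP", a1 = "A1", a2 = "A2",
    z = "Z", p = "P", n = "N", frq = "FRQ", beta = "BETA")
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab-delimited file, renames columns via the dialect, and enforces
#' the record invariants: p in (0, 1], `a1 != a2`, valid alleles, and (in
#' strict mode) consistency of z and p, `p = 2 * (1 - pnorm(|z|))` to relative
#' tolerance 1e-6. Rows failing a check are dropped and the per-rule drop
#' counts attached as the `"drop_log"` attribute. If the z column is absent
#' but a signed effect (`beta`) is present, z is reconstructed from p and the
#' effect direction. Duplicate SNP ids keep the record with the largest n.
#'
#' @param path File path (tab-delimited, header row).
#' @param dialect Named character vector as in [sumstats_dialect()], or a path
#'   to a YAML file with the same keys; partial mappings are merged over the
#'   default.
#' @param strict Drop rows whose z and p disagree (default `TRUE`).
#' @return A validated tibble with columns
#'   `snp, chr, bp, a1, a2, z, p, n, frq`, attribute `drop_log`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), strict = TRUE) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect)) {
    dialect <- unlist(yaml::read_yaml(dialect))
  }
  dialect <- utils::modifyList(as.list(sumstats_dialect()), as.list(dialect))

  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  if (nrow(raw) == 0L) {
    rlang::abort(sprintf("empty summary-statistics file: %s", path),
                 class = "crosstraitr_empty_input")
  }
  mandatory <- c("snp", "chr", "bp", "a1", "a2", "p")
  for (fld in mandatory) {
    if (!dialect[[fld]] %in% names(raw)) {
      rlang::abort(
        sprintf("missing mandatory column '%s' (mapped from field '%s')",
                dialect[[fld]], fld),
        class = "crosstraitr_schema_error"
      )
    }
  }
  pick <- function(fld) {
    col <- dialect[[fld]]
    if (col %in% names(raw)) raw[[col]] else NULL
  }
  tab <- tibble::tibble(
    snp = as.character(pick("snp")),
    chr = sub("^chr", "", as.character(pick("chr"))),
    bp = as.integer(pick("bp")),
    a1 = toupper(as.character(pick("a1"))),
    a2 = toupper(as.character(pick("a2"))),
    p = as.numeric(pick("p"))
  )
  z <- pick("z")
  if (is.null(z)) {
    beta <- pick("beta")
    assert_that(!is.null(beta),
                "neither a z nor a signed effect column is present; cannot recover direction.")
    z <- p_to_z(tab$p, sign(as.numeric(beta)))
  }
  tab$z <- as.numeric(z)
  tab$n <- if (!is.null(pick("n"))) as.numeric(pick("n")) else NA_real_
  tab$frq <- if (!is.null(pick("frq"))) as.numeric(pick("frq")) else NA_real_
  tab <- tab[, c("snp", "chr", "bp", "a1", "a2", "z", "p", "n", "frq")]

  drop_log <- c(bad_p = 0L, bad_alleles = 0L, inconsistent_zp = 0L,
                duplicate_id = 0L, missing_fields = 0L)

  ok <- !is.na(tab$snp) & !is.na(tab$p) & !is.na(tab$z) &
    !is.na(tab$a1) & !is.na(tab$a2)
  drop_log["missing_fields"] <- sum(!ok)
  tab <- tab[ok, ]

  ok <- tab$p > 0 & tab$p <= 1
  drop_log["bad_p"] <- sum(!ok)
  tab <- tab[ok, ]

  ok <- tab$a1 != tab$a2 &
    tab$a1 %in% c("A", "C", "G", "T") & tab$a2 %in% c("A", "C", "G", "T")
  drop_log["bad_alleles"] <- sum(!ok)
  tab <- tab[ok, ]

  if (isTRUE(strict)) {
    p_implied <- z_to_p(tab$z)
    ok <- abs(tab$p - p_implied) <= 1e-6 * pmax(tab$p, p_implied)
    drop_log["inconsistent_zp"] <- sum(!ok)
    tab <- tab[ok, ]
  }

  # duplicate ids: keep the largest n (ties: first occurrence)
  if (anyDuplicated(tab$snp)) {
    ord <- order(tab$snp, -ifelse(is.na(tab$n), -Inf, tab$n))
    tab <- tab[ord, ]
    dup <- duplicated(tab$snp)
    drop_log["duplicate_id"] <- sum(dup)
    tab <- tab[!dup, ]
  }

  if (sum(drop_log) > 0) {
    rlang::inform(sprintf(
      "read_sumstats: dropped %d record(s) [%s]", sum(drop_log),
      paste(sprintf("%s=%d", names(drop_log), drop_log), collapse = ", ")
    ))
  }
  attr(tab, "drop_log") <- drop_log
  tab
}

#' Write a summary-statistics table in the canonical tab-delimited layout
#'
#' Header is `SNP CHR BP A1 A2 Z P N FRQ`.
#'
#' @param tab Tibble as produced by [read_sumstats()] or the simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(tab, path) {
  out <- tab[, c("snp", "chr", "bp", "a1", "a2", "z", "p", "n", "frq")]
  names(out) <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "P", "N", "FRQ")
  readr::write_tsv(out, path)
  invisible(path)
}
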