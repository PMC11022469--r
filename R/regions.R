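#' Default complex-LD exclusion regions (hg19)
#'
#' Four regions with long-range LD conventionally removed before conditional
#' QQ construction: the extended major histocompatibility complex, the 8p23.1
#' inversion, the MAPT region on 17q21 and the APOE region on 19q13.
#' Coordinates are 1-based and inclusive on both ends.
#'
#' @return Tibble with columns `chr`, `start`, `end`, `label`.
#' @export
default_exclusion_regions <- function() {
  tibble::tribble(
    ~chr, ~start,    ~end,      ~label,
    "6",  25119106L, 33854733L, "MHC",
    "8",  7200000L,  12500000L, "8p23.1",
    "17", 40000000L, 47000000L, "MAPT",
    "19", 44909039L, 45912650L, "APOE"
  )
}

#' Remove SNPs inside exclusion regions
#'
#' Drops every record whose chromosome matches a region and whose position
#' lies within `[start, end]` (1-based, inclusive). By default this filter is
#' applied only ahead of the conditional QQ stage; cond/conjFDR discovery
#' operates on the full harmonized table unless the caller applies it there
#' too.
#'
#' @param x A harmonized-pair tibble or any tibble with `chr` and `bp`.
#' @param regions Regions tibble (`chr`, `start`, `end`, optional `label`);
#'   defaults to [default_exclusion_regions()].
#' @return `x` without the excluded records; attribute `excluded_n` counts the
#'   removals.
#' @examples
#' pair <- tibble::tibble(snp = c("a", "b"), chr = c("6", "6"),
#'                        bp = c(30e6, 2e6), z1 = 0, p1 = 1, z2 = 0, p2 = 1)
#' filter_exclusion_regions(pair)
#' @export
filter_exclusion_regions <- function(x, regions = default_exclusion_regions()) {
  assert_that(all(c("chr", "bp") %in% names(x)),
              "input must carry `chr` and `bp` columns.")
  assert_that(all(regions$start <= regions$end),
              "regions must satisfy start <= end.")
  chr <- sub("^chr", "", as.character(x$chr))
  hit <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chr == sub("^chr", "", as.character(regions$chr[i])) &
                    x$bp >= regions$start[i] & x$bp <= regions$end[i])
  }
  out <- x[!hit, ]
  attr(out, "excluded_n") <- sum(hit)
  out
}

#' Read genomic intervals from a 1-based TSV or a BED file
#'
#' TSV input must carry columns `chr`, `start`, `end` (1-based inclusive) and
#' optionally `label`/`name`. BED input (0-based half-open) is imported via
#' rtracklayer and converted to the package's 1-based inclusive convention.
#'
#' @param path File path.
#' @param format `"tsv"` or `"bed"`; guessed from the extension by default.
#' @return Tibble with `chr`, `start`, `end`, `label`.
#' @export
read_intervals <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    assert_that(requireNamespace("rtracklayer", quietly = TRUE),
                "reading BED files requires the rtracklayer package.")
    df <- as.data.frame(rtracklayer::import(path, format = "BED"))
    tibble::tibble(
      chr = sub("^chr", "", as.character(df$seqnames)),
      start = as.integer(df$start),      # rtracklayer already returns 1-based
      end = as.integer(df$end),
      label = if ("name" %in% names(df)) as.character(df$name) else NA_character_
    )
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    assert_that(all(c("chr", "start", "end") %in% names(tab)),
                "interval TSV must have columns chr, start, end.")
    tibble::tibble(
      chr = sub("^chr", "", as.character(tab$chr)),
      start = as.integer(tab$start),
      end = as.integer(tab$end),
      label = as.character(tab$label %||% tab$name %||% NA_character_)
    )
  }
}
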