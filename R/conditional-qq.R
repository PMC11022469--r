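#' Stratify primary-trait p-values by secondary-trait significance
#'
#' Builds the data behind a conditional QQ plot: for each secondary-trait
#' cutoff `t` the subset of SNPs with `p2 <= t` is taken, the primary
#' p-values are sorted, and observed `-log10(p1)` is paired with the expected
#' uniform quantile `-log10((i - 0.5) / n)` for rank `i` of `n`. The largest
#' threshold (1 by default) is the unconditional baseline curve. Successive
#' strata are nested, so rightward/upward deflection of stricter strata
#' relative to the baseline is the visual signature of cross-trait enrichment.
#'
#' @param pair Harmonized-pair tibble (ideally after
#'   [filter_exclusion_regions()]).
#' @param thresholds Strictly decreasing secondary p-value cutoffs in (0, 1];
#'   comparison is `p2 <= t`. Default `c(1, 0.1, 0.01, 0.001, 1e-4)`.
#' @param min_snps Strata smaller than this are emitted empty with a warning.
#' @return A tibble of class `qq_strata` with columns `stratum` (factor,
#'   ordered from baseline to strictest), `threshold`, `expected`, `observed`;
#'   attribute `stratum_counts` gives the SNP count per stratum.
#' @examples
#' ld <- simulate_ld_blocks(5000, 1, 0)
#' sim <- simulate_bivariate_sumstats(
#'   architecture_params(5000, pi_ab = 0.01, rho_shared = 0.8, seed = 2), ld)
#' pair <- harmonize_pair(sim$sumstats_a, sim$sumstats_b)
#' qq <- stratify_by_secondary(pair)
#' attr(qq, "stratum_counts")
#' @export
stratify_by_secondary <- function(pair,
                                  thresholds = c(1, 0.1, 0.01, 0.001, 1e-4),
                                  min_snps = 10L) {
  assert_that(nrow(pair) > 0, "`pair` is empty.")
  assert_that(all(thresholds > 0 & thresholds <= 1),
              "thresholds must lie in (0, 1].")
  assert_that(all(diff(thresholds) < 0),
              "thresholds must be strictly decreasing.")

  labels <- ifelse(thresholds == 1, "all SNPs",
                   sprintf("p2 <= %g", thresholds))
  strata <- purrr::map2_dfr(thresholds, labels, function(t, lab) {
    p1 <- sort(pair$p1[pair$p2 <= t])
    n <- length(p1)
    if (n < min_snps) {
      rlang::warn(sprintf(
        "stratum '%s' has %d SNP(s) (< %d); emitted empty.", lab, n, min_snps))
      return(tibble::tibble(stratum = character(), threshold = numeric(),
                            expected = numeric(), observed = numeric()))
    }
    tibble::tibble(
      stratum = lab, threshold = t,
      expected = neglog10((seq_len(n) - 0.5) / n),
      observed = neglog10(p1)
    )
  })
  strata$stratum <- factor(strata$stratum, levels = labels)
  counts <- table(factor(strata$stratum, levels = labels))
  out <- tibble::new_tibble(strata, class = "qq_strata")
  attr(out, "stratum_counts") <- setNames(as.integer(counts), labels)
  attr(out, "thresholds") <- thresholds
  out
}

#' Summarize conditional-QQ enrichment per stratum
#'
#' Quantifies the bulk deflection each conditioning stratum shows relative to
#' the unconditional baseline: for every stratum, the mean observed
#' `-log10(p1)` among SNPs below the stratum's median expected quantile, minus
#' the same quantity in the baseline stratum. Positive values indicate
#' enrichment; under cross-trait sharing the statistic grows as the
#' conditioning threshold tightens.
#'
#' @param strata A [stratify_by_secondary()] result.
#' @return Tibble with one row per stratum: `stratum`, `threshold`, `n`,
#'   `mean_low_observed`, `enrichment`.
#' @export
enrichment_summary <- function(strata) {
  assert_that(nrow(strata) > 0, "`strata` is empty.")
  per <- strata |>
    dplyr::group_by(.data$stratum, .data$threshold) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_low_observed = mean(.data$observed[.data$expected < median(.data$expected)]),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$threshold))
  baseline <- per$mean_low_observed[which.max(per$threshold)]
  per$enrichment <- per$mean_low_observed - baseline
  per
}

#' Compare stratum QQ curves with the baseline via pointwise binomial bands
#'
#' At a grid of baseline `-log10(p1)` quantiles, the proportion of each
#' stratum's observed values at or below the grid point is compared with the
#' baseline proportion; the standardized difference uses the binomial
#' standard error at the stratum size. Under independence of the two traits
#' every stratum is a random subset of the baseline, so the statistics behave
#' like (conservatively) standard normals.
#'
#' @param strata A [stratify_by_secondary()] result.
#' @param level Band coverage (default 0.95).
#' @param probs Baseline quantile grid.
#' @return Tibble with `stratum`, `threshold`, `x`, `p_base`, `p_stratum`,
#'   `zstat`, `within_band`.
#' @export
qq_band_check <- function(strata, level = 0.95, probs = seq(0.1, 0.9, 0.1)) {
  base_t <- max(strata$threshold)
  base_obs <- strata$observed[strata$threshold == base_t]
  x <- unname(quantile(base_obs, probs))
  p_base <- vapply(x, function(xi) mean(base_obs <= xi), numeric(1))
  zcrit <- qnorm(1 - (1 - level) / 2)

  sub <- dplyr::filter(strata, .data$threshold < base_t)
  purrr::map_dfr(split(sub, sub$threshold, drop = TRUE), function(s) {
    n_s <- nrow(s)
    p_s <- vapply(x, function(xi) mean(s$observed <= xi), numeric(1))
    zstat <- (p_s - p_base) / sqrt(p_base * (1 - p_base) / n_s)
    tibble::tibble(
      stratum = s$stratum[1], threshold = s$threshold[1],
      x = x, p_base = p_base, p_stratum = p_s, n = n_s,
      zstat = zstat, within_band = abs(zstat) <= zcrit
    )
  }) |> dplyr::arrange(dplyr::desc(.data$threshold))
}

#' Plot conditional QQ curves
#'
#' @param strata A [stratify_by_secondary()] result.
#' @return A ggplot object: one curve per conditioning stratum, identity line
#'   dashed.
#' @export
plot_conditional_qq <- function(strata) {
  ggplot2::ggplot(strata,
                  ggplot2::aes(x = .data$expected, y = .data$observed,
                               colour = .data$stratum)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      colour = "Conditioning stratum"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot qq_strata
#' @export
autoplot.qq_strata <- function(object, ...) plot_conditional_qq(object)

#' Write conditional QQ strata to a TSV
#'
#' Columns: `stratum`, `threshold`, `expected_neglog10p`, `observed_neglog10p`.
#' @param strata A [stratify_by_secondary()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qq_strata <- function(strata, path) {
  out <- tibble::tibble(
    stratum = as.character(strata$stratum),
    threshold = strata$threshold,
    expected_neglog10p = strata$expected,
    observed_neglog10p = strata$observed
  )
  readr::write_tsv(out, path)
  invisible(path)
}
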