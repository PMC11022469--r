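#' Dice coefficient of polygenic overlap
#'
#' `2 * n_shared / ((n_a_only + n_shared) + (n_b_only + n_shared))`:
#' 0 for disjoint architectures, 1 when every causal variant is shared.
#'
#' @param n_a_only,n_shared,n_b_only Variant counts (>= 0).
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' dice_coefficient(500, 300, 4900)  # 600 / 6000 = 0.1
#' @export
dice_coefficient <- function(n_a_only, n_shared, n_b_only) {
  assert_that(all(c(n_a_only, n_shared, n_b_only) >= 0),
              "variant counts must be non-negative.")
  tot <- (n_a_only + n_shared) + (n_b_only + n_shared)
  if (tot == 0) return(NA_real_)
  2 * n_shared / tot
}

#' Summarize polygenic overlap from a bivariate fit or explicit counts
#'
#' Produces the Venn-diagram quantities of a bivariate causal-mixture fit:
#' unique and shared variant counts (reported in thousands for display), the
#' Dice coefficient, and the percentage of each trait's causal variants that
#' are shared. Given a fitted model it also tabulates the composite
#' log-likelihood over a grid of shared-component proportions (the
#' log-likelihood-surface diagnostic), with the other parameters held at
#' their estimates.
#'
#' @param x A `bivariate_mixfit`, or a numeric vector/list with elements
#'   `n_a_only`, `n_shared`, `n_b_only` (explicit counts, e.g. from a printed
#'   Venn diagram).
#' @param pi_ab_grid Grid of `pi_ab` values for the likelihood surface
#'   (fitted models only); `NULL` for an automatic grid around the estimate.
#' @return An object of class `overlap_summary`: list with the raw and
#'   thousands-scale counts, `dice`, `dice_se` (if available),
#'   `shared_fraction_a`, `shared_fraction_b` (percent), and (for fits)
#'   `loglik_surface`, a tibble of `pi_ab`, `n_shared`, `loglik`.
#' @examples
#' s <- derive_overlap_summary(c(n_a_only = 500, n_shared = 300,
#'                               n_b_only = 4900))
#' s$shared_fraction_a  # 37.5
#' @export
derive_overlap_summary <- function(x, pi_ab_grid = NULL) {
  if (inherits(x, "bivariate_mixfit")) {
    counts <- c(n_a_only = x$n_a_only, n_shared = x$n_shared,
                n_b_only = x$n_b_only)
    dice_se <- x$dice_se
    if (is.null(pi_ab_grid)) {
      hi <- max(x$pi_ab * 3, 10 / x$m)
      pi_ab_grid <- seq(0, hi, length.out = 21)
    }
    surface <- tibble::tibble(
      pi_ab = pi_ab_grid,
      n_shared = pi_ab_grid * x$m,
      loglik = purrr::map_dbl(pi_ab_grid, function(p) {
        bivariate_loglik(x, pi_ab = p)
      })
    )
  } else {
    x <- unlist(x)
    assert_that(all(c("n_a_only", "n_shared", "n_b_only") %in% names(x)),
                "counts must be named n_a_only, n_shared, n_b_only.")
    counts <- x[c("n_a_only", "n_shared", "n_b_only")]
    dice_se <- NA_real_
    surface <- NULL
  }

  n_a_total <- counts[["n_a_only"]] + counts[["n_shared"]]
  n_b_total <- counts[["n_b_only"]] + counts[["n_shared"]]
  structure(
    list(
      n_a_only = counts[["n_a_only"]],
      n_shared = counts[["n_shared"]],
      n_b_only = counts[["n_b_only"]],
      venn_thousands = unname(counts) / 1000,
      dice = dice_coefficient(counts[["n_a_only"]], counts[["n_shared"]],
                              counts[["n_b_only"]]),
      dice_se = dice_se,
      shared_fraction_a = 100 * counts[["n_shared"]] / n_a_total,
      shared_fraction_b = 100 * counts[["n_shared"]] / n_b_total,
      loglik_surface = surface
    ),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary>\n")
  cat(sprintf("  Venn (thousands): %.1fk A-only | %.1fk shared | %.1fk B-only\n",
              x$venn_thousands[1], x$venn_thousands[2], x$venn_thousands[3]))
  cat(sprintf("  Dice = %.3f%s\n", x$dice,
              if (is.na(x$dice_se)) "" else sprintf(" (SE %.3f)", x$dice_se)))
  cat(sprintf("  shared fraction: %.1f%% of trait A, %.1f%% of trait B\n",
              x$shared_fraction_a, x$shared_fraction_b))
  invisible(x)
}

#' @describeIn derive_overlap_summary tidy method: one row per quantity.
#' @param ... Unused.
#' @method tidy overlap_summary
#' @export
tidy.overlap_summary <- function(x, ...) {
  tibble::tibble(
    term = c("n_a_only", "n_shared", "n_b_only", "dice",
             "shared_fraction_a", "shared_fraction_b"),
    estimate = c(x$n_a_only, x$n_shared, x$n_b_only, x$dice,
                 x$shared_fraction_a, x$shared_fraction_b)
  )
}

#' Venn-style overlap plot of a bivariate fit
#'
#' A schematic two-circle diagram scaled by each trait's polygenicity with
#' the shared count annotated; a numeric companion to the overlap summary.
#'
#' @param x An `overlap_summary` or `bivariate_mixfit`.
#' @return A ggplot object.
#' @export
plot_overlap_venn <- function(x) {
  if (inherits(x, "bivariate_mixfit")) x <- derive_overlap_summary(x)
  n_a <- x$n_a_only + x$n_shared
  n_b <- x$n_b_only + x$n_shared
  r_a <- sqrt(n_a); r_b <- sqrt(n_b)
  # place circle centres so the lens area is roughly proportional to overlap
  d <- (r_a + r_b) * (1 - x$dice)
  circ <- function(cx, r, lab) {
    th <- seq(0, 2 * pi, length.out = 200)
    tibble::tibble(x = cx + r * cos(th), y = r * sin(th), trait = lab)
  }
  dat <- dplyr::bind_rows(circ(0, r_a, "trait A"), circ(d, r_b, "trait B"))
  lab <- tibble::tibble(
    x = c(-r_a / 2, d / 2, d + r_b / 2), y = 0,
    text = sprintf("%.1fk", c(x$n_a_only, x$n_shared, x$n_b_only) / 1000)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$trait,
                                    colour = .data$trait)) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$text),
                       inherit.aes = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
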