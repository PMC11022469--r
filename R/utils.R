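# internal helpers shared across modules

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg, class = "crosstraitr_invalid_parameter")
  invisible(TRUE)
}

assert_seed <- function(seed) {
  assert_that(
    !is.null(seed) && length(seed) == 1L && is.finite(seed) &&
      seed == as.integer(seed),
    "`seed` must be supplied as a single integer: every stochastic operation is seeded."
  )
  as.integer(seed)
}

assert_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(if (lo_open) x > lo else x >= lo) &&
    all(if (hi_open) x < hi else x <= hi)
  assert_that(ok, sprintf("`%s` must lie in %s%g, %g%s.", name,
                          if (lo_open) "(" else "[", lo, hi,
                          if (hi_open) ")" else "]"))
  x
}

neglog10 <- function(p) -log10(p)

# two-sided normal tail for a signed z-score
z_to_p <- function(z) 2 * pnorm(-abs(z))

# signed z from a two-sided p and an effect direction
p_to_z <- function(p, sign) sign(sign) * qnorm(p / 2, lower.tail = FALSE)

# non-palindromic ordered allele pairs (palindromic = A/T or C/G)
NONPALINDROMIC_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

complement_allele <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
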