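---
title: "Methods: quantifying and localizing shared genetic architecture between two traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and localizing shared genetic architecture between two traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstraitr)
```

crosstraitr implements a complete cross-trait pleiotropy workflow for pairs of
GWAS summary-statistics tables — for example a cataract GWAS and a hearing
difficulty GWAS — together with the propensity-matched cohort analysis that
typically accompanies such a genetic study. This vignette explains the models,
the defaults and the numerical choices, and what the simulation-based tests do
and do not establish about real data.

## The generative model behind everything

All statistical machinery in the package is organized around one generative
picture: each SNP belongs to one of four components — influencing neither
trait, only trait A, only trait B, or both — with proportions
$(1-\pi_a-\pi_b-\pi_{ab},\ \pi_a,\ \pi_b,\ \pi_{ab})$. A causal SNP's effects
are zero-mean Gaussian with per-variant variances $\sigma^2_a,\sigma^2_b$;
within the shared component the two effects are correlated with coefficient
$\rho_{shared}$ (polygenic overlap is about *membership* in the shared
component, not about the sign of the correlation — two traits can share
variants with mixed effect directions and near-zero genetic correlation). The
observed z-score of trait $t$ at SNP $j$ is

$$z_{tj} = \sqrt{n_t}\, \sum_k r_{jk}\,\beta_{tk} + \epsilon_{tj},
\qquad \epsilon_{tj} \sim N(0, \sigma_{0t}^2),$$

where $r_{jk}$ is the LD correlation between SNPs $j$ and $k$, so causal
signal smears across LD neighbours, and $\sigma_{0t} \ge 1$ captures residual
inflation. `simulate_bivariate_sumstats()` draws from exactly this model and
keeps the component labels as a ground-truth sidecar that downstream stages
never see.

### The LD model and what it leaves out

`simulate_ld_blocks()` uses exchangeable-correlation blocks: a single
within-block correlation `rho`, independence across blocks. This is enough to
exercise every LD-dependent step — LD scores ($\ell_j = \sum_k r_{jk}^2$,
exactly $1 + (s-1)\rho^2$ in a block of size $s$), random pruning, clumping —
with closed-form expectations the tests can check. It does **not** emulate
real LD maps: no distance decay, no long-range irregularity, no variation in
block size. Consequences for interpreting test results are discussed at the
end.

### Defaults

The simulator's defaults are fixed once and used throughout the tests and the
acceptance script: per-causal effect variance $\sigma^2 = 10^{-4}$, GWAS
sample sizes $n_a = n_b = 10^5$, no inflation ($\sigma_0 = 1$). These give a
per-causal non-centrality $n\sigma^2 = 10$ (z-scores around $3$ for an
isolated causal variant) — a mid-power GWAS regime in which discovery is
possible but not trivial, which is the interesting regime for conditional FDR
methods. Effect variance is constant per causal variant (no coupling to allele
frequency); allele pairs are drawn without palindromic pairs unless the
harmonization-stress flag is set. Every source of randomness takes a mandatory
integer seed.

## Harmonization and region exclusion

`harmonize_pair()` aligns the two tables to one effect-allele orientation:
swapped alleles flip the sign of $z_2$, strand-complemented alleles are
matched after complementing, and palindromic (A/T, C/G) variants are dropped
by default because their strand cannot be read off the alleles. With
`keep_palindromic = TRUE` a palindromic SNP is retained only when the two
allele frequencies identify the orientation unambiguously (one of
$|f_1 - f_2|$ and $|f_1 - (1-f_2)|$ within 0.2, not both); this conservative
rule loses some markers near frequency 0.5 by design. Duplicate SNP ids keep
the record with the largest sample size.

Coordinates are 1-based with both interval ends inclusive; BED input is
converted at the file boundary. Four long-range-LD regions (extended MHC,
8p23.1, MAPT, APOE) are excluded by default **only** ahead of the conditional
QQ stage: one of the shared loci the discovery stage is expected to find on
real data lies inside the MAPT interval, so applying the exclusion globally
would contradict the discovery stage's contract. A flag on
`filter_exclusion_regions()` callers can apply it anywhere.

## Conditional QQ and the enrichment statistic

`stratify_by_secondary()` computes, for each secondary-trait cutoff
$t \in \{1, 0.1, 0.01, 10^{-3}, 10^{-4}\}$ (comparison `p2 <= t`; with
continuous p-values the choice of strict versus non-strict inequality is
measure-zero, and `<=` is deterministic on tied synthetic values), the QQ
curve of the primary trait within the stratum: sorted observed
$-\log_{10} p_1$ against expected $-\log_{10}((i-0.5)/n)$. All SNPs surviving
region exclusion enter; no LD thinning is applied at this stage (thinning
lives in the FDR estimation, where it matters for counts).

Because "leftward deflection" is a visual notion, `enrichment_summary()`
reduces each stratum to a number: the mean observed $-\log_{10} p_1$ among
SNPs below the stratum's median expected quantile, minus the baseline
stratum's same quantity. The statistic is zero when a stratum behaves like
the baseline bulk and grows as conditioning enriches the stratum. Band
agreement for independent traits is checked with pointwise binomial bands
against the baseline ECDF; a 95% pointwise band is expected to miss about 5%
of grid points even under the null, so the tests require at least 90% of
points within the 95% band and all points within the 99.9% band.

## Conditional and conjunctional FDR

The conditional FDR of the primary trait given the secondary is estimated on
a 2-D grid of p-value cutpoints as

$$\widehat{\mathrm{condFDR}}(u \mid v) \;=\;
\frac{u \cdot \#\{p_2 \le v\}}{\#\{p_1 \le u,\ p_2 \le v\}},$$

with the null proportion $\pi_0$ fixed at 1 — the conservative convention of
the conditional-FDR literature; the package deliberately estimates no
$\pi_0$ — and values capped at 1 (the grid corner $(1,1)$ is exactly 1).
Numerical choices:

* **Grid**: 101 log-spaced cutpoints per axis from $10^{-12}$ to 1; per-SNP
  values are bilinear interpolations in $\log_{10} p$, exact at cutpoints and
  clamped at the grid boundary.
* **LD pruning**: counts are averaged over 100 random prunings (one SNP kept
  uniformly at random per LD block linked at $r^2 > 0.1$), so LD-duplicated
  signals do not distort the empirical CDFs. The count is configurable and
  seeded.
* **Empty cells**: the joint count is cumulative in both axes, so cells with
  an empty denominator form a bottom prefix of each column. After a running
  maximum over the populated cells of a column (the monotonicity enforcement
  in $p_1$), the empty prefix inherits the first populated value and fully
  empty columns inherit the next coarser conditioning column. Inheriting
  rather than extrapolating avoids manufacturing condFDR values below $p_1$.
* **Ties**: identical p-values are processed in stable SNP-id order.

Inverting the roles of the traits gives the second direction, and the
conjunctional FDR is defined per SNP as the maximum of the two directional
values — a conservative bound on the probability that a SNP is null for at
least one trait. Flags are set at condFDR < 0.01 and conjFDR < 0.05, the
conventional thresholds. With the conditioning threshold at $v = 1$ the
procedure collapses to the unconditional empirical-FDR (Benjamini–Hochberg
style) ratio, which the tests assert.

`fdr_calibration_experiment()` closes the loop against ground truth: across
replicates it counts discoveries at conjFDR < 0.05 and calls a discovery
false when its LD block contains no shared-component causal variant (an LD
proxy of a shared causal SNP is a correct discovery at locus resolution).
At the study scale used by the tests (100k SNPs, blocks of 10 at
$\rho = 0.8$, $\pi_{ab} = 0.002$, $\rho_{shared} = 0.8$, 10 replicates) the
mean false-discovery proportion stays below the 0.10 bound, and the pure-null
architecture yields essentially no discoveries.

## The causal-mixture ("MiXeR-style") fits

The exact MiXeR likelihood convolves effect-size distributions over the full
LD structure via FFT. At desk scale the package replaces this with a
moment-matched binomial-mixture approximation: a SNP with LD score $\ell_j$
carries $L_j = \max(1, \mathrm{round}(\ell_j))$ causal-partner slots, each
independently causal with the component probabilities, and given $k$ causal
partners the z-score is Gaussian with variance
$\sigma_0^2 + n\sigma^2 (\ell_j/L_j) k$. The factor $\ell_j/L_j$ preserves
$E[z^2]$ exactly, and the composite likelihood matches a brute-force per-SNP
mixture-density evaluation to $10^{-10}$ relative error in the tests — that
brute-force check is the approximation's correctness anchor.

`fit_univariate()` estimates $(\pi, \sigma^2, \sigma_0)$ per trait by
maximizing the composite likelihood in unconstrained coordinates (logit,
log, log) with Nelder–Mead from five deterministic Latin-hypercube starts.
`fit_bivariate()` then holds the variance/inflation parameters at their
univariate estimates (two-stage fitting stabilizes the five remaining
parameters $\pi_a, \pi_b, \pi_{ab}, \rho_{shared}, \rho_0$ at these problem
sizes; `joint = TRUE` polishes all nine afterwards). Quantities derived from
the fitted proportions with $M$ analyzed SNPs:

* variant counts $n_{a\,\mathrm{only}} = \pi_a M$, $n_{shared} = \pi_{ab} M$,
  $n_{b\,\mathrm{only}} = \pi_b M$ (displayed in thousands, Venn-style);
* Dice coefficient
  $2 n_{shared} / (n_{a,\mathrm{tot}} + n_{b,\mathrm{tot}})$;
* shared fractions, e.g. $n_{shared}/n_{a,\mathrm{tot}}$ as a percentage.

On the reference architecture used throughout (500 unique-A, 300 shared,
4,900 unique-B causal variants among 100k SNPs) the shared fraction of trait
A is 37.5% and the Dice coefficient $2\cdot300/6000 = 0.10$. Note that a
Dice value printed alongside such counts in the literature is occasionally
inconsistent with this arithmetic (e.g. 0.08 where the counts give 0.10);
the package always applies the definition above. Overlap evidence is
summarized the same way the field does: AIC of the full model against the
$\pi_{ab} = 0$ submodel, plus a composite log-likelihood surface over
$\pi_{ab}$ (`derive_overlap_summary()`). The standard error of Dice comes
from a parametric bootstrap (refits on data simulated at the point estimate;
size configurable) since no closed form exists for it.

Two caveats are deliberate. At the null boundary the univariate model has a
flat ridge ($\pi \to 0$ with $\sigma^2$ unbounded), so on null data only the
identified quantities — the causal count and the likelihood gain over
$\pi = 0$ — are meaningful, and those are what the tests assert. And the
bivariate component proportions are estimated freely rather than constrained
to the univariate totals; count conservation
($n_{a\,\mathrm{only}} + n_{shared} = \pi_{a,\mathrm{tot}} M$) holds by
construction of the derived counts.

## Locus definition, novelty, gene mapping, replication

Discovery SNPs (conjFDR < 0.05) are reduced to independent leads by greedy
clumping: candidates in ascending conjFDR order (ties by ascending $p_1$,
then SNP id), each selected lead removing candidates with $r^2 \ge 0.2$ to
it. The selection order is a design choice — the independence criterion alone
does not determine one — and ascending significance is the standard
convention. Novelty is assessed against user-supplied per-trait catalog
intervals (hermetic and version-stable, rather than live catalog queries);
a lead is novel for a trait when it overlaps no interval. Positional gene
mapping assigns all genes within 10 kb (distance 0 inside a gene, else
base pairs to the nearer boundary; nearest-gene ties break to the smaller
gene start). Replication takes an independent cohort's summary statistics
already harmonized to the lead orientation and reports per-lead sign
concordance and significance. All three operations are checked against
exhaustive scans in the tests.

## The cohort stage

The epidemiologic module mirrors the standard observational workflow:
logistic propensity scores (`estimate_propensity()`, listwise deletion with
counts, separation detected and a ridge fallback offered), greedy 1:1
nearest-neighbour matching without replacement on the logit propensity score
with a caliper of 0.2 SD of the logit score (`match_1to1()` — the most common
convention; both pieces are configurable because published analyses often
leave them unstated), covariate balance by standardized mean differences
(|SMD| < 0.1 as the balance convention, with the pre-match pooled SD as the
common denominator), and maximum-likelihood logistic odds ratios with Wald
95% intervals (`fit_or()`, which also emits a pairwise covariate-correlation
report as the multicollinearity check). Matching processes exposed subjects
in a seeded random order after canonicalizing row order by subject id, so
permuting input rows changes nothing. Effect modification is tested by
likelihood ratio on the exposure-by-modifier product term, and the two
sensitivity analyses re-run the matched pipeline after the stated filters
(stricter outcome definition; exclusion of surgically treated exposed
subjects).

The synthetic cohort (`simulate_epi_cohort()`) generates twelve covariates
(continuous standardized age and deprivation index, the rest binary with
realistic prevalences), a logistic exposure model and a logistic outcome
model with a known conditional odds ratio — the recovery target. At
$n = 50{,}000$ with true OR 2.0 the matched estimate lands within $\pm 0.2$,
all post-match |SMD| fall below 0.1, and the Wald interval covers the truth
in at least 90% of 100 seeded replicates.

## Problem sizes and reproducibility

The tests and `scripts/acceptance.R` run at the sizes quoted above: 100k
SNPs for the calibration, QQ and mixture experiments (10, 5 and 4 replicate
fits respectively), 50k subjects and 100 replicates for the cohort stage;
smaller sizes appear only in unit tests of exact properties, where scale adds
nothing. Every stochastic call takes an explicit integer seed, the pipeline
(`run_pipeline()`) funnels all seeds through its configuration and writes a
manifest with a configuration hash, and a rerun with the same configuration
reproduces byte-identical tables.

## What passing tests do and do not show

The synthetic generator shares the estimators' model family, so parameter
recovery here demonstrates internal consistency, not robustness: real GWAS
data bring irregular LD, frequency-dependent effect sizes, sample overlap,
imputation artefacts and stratification beyond a scalar inflation. The
exchangeable-block LD model in particular makes pruning and clumping cleaner
than they are in practice. The condFDR calibration bound (FDP $\le 0.10$ at
the 0.05 threshold) includes the slack the $\pi_0 = 1$ convention buys;
on architectures with much denser polygenicity the conservatism shrinks.
The cohort simulator draws covariates independently, so it understates the
collinearity a real cohort would show — the multicollinearity report exists
for real data, not for the simulator.
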