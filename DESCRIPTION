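Package: crosstraitr
Title: Cross-Trait Pleiotropy Analysis with Conditional FDR and Causal-Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and localizing shared genetic architecture
    between two complex traits from GWAS summary statistics: harmonization of
    paired summary-statistics tables, conditional quantile-quantile enrichment,
    conditional and conjunctional false discovery rate (cond/conjFDR) discovery
    of jointly associated loci with LD-aware pruning, a lightweight bivariate
    causal-mixture model of polygenic overlap (polygenicity, shared-variant
    counts, Dice coefficient), independent-locus clumping with positional gene
    mapping and novelty annotation, and a propensity-score matched cohort stage
    for the companion epidemiologic association. Includes simulators for paired
    summary statistics under a four-component causal mixture with block LD and
    for confounded binary cohorts, with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
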