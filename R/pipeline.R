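#' Default pipeline configuration
#'
#' Returns the fully populated default configuration for [run_pipeline()];
#' supply overrides as a nested list or YAML file with the same shape.
#' Every stochastic stage has a named seed and all thresholds are explicit.
#'
#' @return Nested list with components `outdir`, `stages`, `seeds`,
#'   `simulate`, `thresholds`, `condfdr`, `mixer`, `epi`.
#' @export
default_pipeline_config <- function() {
  list(
    outdir = "crosstraitr-run",
    stages = c("simulate", "harmonize", "qq", "condfdr", "mixer", "loci"),
    seeds = list(simulate = 1L, condfdr = 2L, mixer = 3L, epi = 4L),
    simulate = list(
      m_snps = 20000L, block_size = 10L, rho = 0.8,
      pi_a = 0.002, pi_b = 0.005, pi_ab = 0.002,
      sigma2_a = 1e-4, sigma2_b = 1e-4, rho_shared = 0.8,
      sigma0_a = 1, sigma0_b = 1, n_a = 1e5, n_b = 1e5
    ),
    thresholds = list(
      cond_fdr = 0.01, conj_fdr = 0.05, r2_clump = 0.2,
      qq = c(1, 0.1, 0.01, 0.001, 1e-4)
    ),
    condfdr = list(n_prunings = 100L, r2_prune = 0.1),
    mixer = list(n_starts = 5L, n_boot = 0L),
    epi = list(n_subjects = 20000L, true_or = 2, caliper = 0.2)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the cross-trait analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order — `simulate` (or loading
#' of user-supplied summary-statistics files), `harmonize`, `qq`, `condfdr`,
#' `mixer`, `loci`, and optionally `epi` — writing each stage's canonical
#' text outputs under `outdir` and a JSON run manifest (configuration hash,
#' package version, seeds, per-stage status and row counts). Stages
#' communicate only through the written file interfaces, so a rerun with the
#' same configuration reproduces byte-identical numeric tables. A stage
#' failure is recorded in the manifest and downstream stages are skipped.
#'
#' @param config Nested list (see [default_pipeline_config()]) or path to a
#'   YAML file with overrides; merged over the defaults.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$outdir, f)

  manifest <- list(
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("crosstraitr")),
    seeds = cfg$seeds,
    stages = list()
  )
  failed <- FALSE

  record <- function(stage, status, outputs = character(), rows = NA_integer_) {
    manifest$stages[[stage]] <<- list(status = status,
                                      outputs = as.list(outputs),
                                      rows = rows)
  }
  run_stage <- function(stage, fn) {
    if (!(stage %in% cfg$stages)) return(invisible(NULL))
    if (failed) {
      record(stage, "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      record(stage, paste("failed:", conditionMessage(res)))
    }
    invisible(NULL)
  }

  ld <- with(cfg$simulate, simulate_ld_blocks(m_snps, block_size, rho))

  run_stage("simulate", function() {
    s <- cfg$simulate
    arch <- architecture_params(
      s$m_snps, pi_a = s$pi_a, pi_b = s$pi_b, pi_ab = s$pi_ab,
      sigma2_a = s$sigma2_a, sigma2_b = s$sigma2_b, rho_shared = s$rho_shared,
      sigma0_a = s$sigma0_a, sigma0_b = s$sigma0_b,
      n_a = s$n_a, n_b = s$n_b, seed = cfg$seeds$simulate
    )
    sim <- simulate_bivariate_sumstats(arch, ld)
    write_sumstats(sim$sumstats_a, pth("sumstats_a.tsv"))
    write_sumstats(sim$sumstats_b, pth("sumstats_b.tsv"))
    readr::write_tsv(sim$truth, pth("truth.tsv"))
    record("simulate", "ok",
           c("sumstats_a.tsv", "sumstats_b.tsv", "truth.tsv"),
           nrow(sim$sumstats_a))
  })

  run_stage("harmonize", function() {
    a <- read_sumstats(cfg$inputs$sumstats_a %||% pth("sumstats_a.tsv"))
    b <- read_sumstats(cfg$inputs$sumstats_b %||% pth("sumstats_b.tsv"))
    pair <- harmonize_pair(a, b)
    readr::write_tsv(pair, pth("harmonized.tsv"))
    record("harmonize", "ok", "harmonized.tsv", nrow(pair))
  })

  run_stage("qq", function() {
    pair <- readr::read_tsv(pth("harmonized.tsv"), show_col_types = FALSE)
    pair <- filter_exclusion_regions(pair)
    qq_ab <- stratify_by_secondary(pair, cfg$thresholds$qq)
    pair_ba <- dplyr::rename(pair, p1 = "p2", p2 = "p1", z1 = "z2", z2 = "z1")
    qq_ba <- stratify_by_secondary(pair_ba, cfg$thresholds$qq)
    write_qq_strata(qq_ab, pth("qq_ab.tsv"))
    write_qq_strata(qq_ba, pth("qq_ba.tsv"))
    readr::write_tsv(enrichment_summary(qq_ab), pth("qq_enrichment_ab.tsv"))
    readr::write_tsv(enrichment_summary(qq_ba), pth("qq_enrichment_ba.tsv"))
    record("qq", "ok", c("qq_ab.tsv", "qq_ba.tsv", "qq_enrichment_ab.tsv",
                         "qq_enrichment_ba.tsv"), nrow(qq_ab))
  })

  run_stage("condfdr", function() {
    pair <- readr::read_tsv(pth("harmonized.tsv"), show_col_types = FALSE)
    use_ld <- if (nrow(pair) == ld$m) ld else NULL
    grid_ab <- empirical_cdf_grid(pair, "A|B", ld = use_ld,
                                  n_prunings = cfg$condfdr$n_prunings,
                                  r2_thresh = cfg$condfdr$r2_prune,
                                  seed = cfg$seeds$condfdr)
    grid_ba <- empirical_cdf_grid(pair, "B|A", ld = use_ld,
                                  n_prunings = cfg$condfdr$n_prunings,
                                  r2_thresh = cfg$condfdr$r2_prune,
                                  seed = cfg$seeds$condfdr + 1L)
    snp_fdr <- assign_condfdr(pair, grid_ab, grid_ba,
                              cond_threshold = cfg$thresholds$cond_fdr,
                              conj_threshold = cfg$thresholds$conj_fdr)
    write_condfdr(snp_fdr, pth("condfdr.tsv"))
    readr::write_tsv(tidy(grid_ab), pth("fdr_grid_ab.tsv"))
    readr::write_tsv(tidy(grid_ba), pth("fdr_grid_ba.tsv"))
    record("condfdr", "ok",
           c("condfdr.tsv", "fdr_grid_ab.tsv", "fdr_grid_ba.tsv"),
           nrow(snp_fdr))
  })

  run_stage("mixer", function() {
    pair <- readr::read_tsv(pth("harmonized.tsv"), show_col_types = FALSE)
    scores <- if (nrow(pair) == ld$m) ld$ld_score else rep(1, nrow(pair))
    tabs <- pair_tables(pair)
    fa <- fit_univariate(tabs$a, scores, seed = cfg$seeds$mixer)
    fb <- fit_univariate(tabs$b, scores, seed = cfg$seeds$mixer + 1L)
    fab <- fit_bivariate(pair, fa, fb, ld_scores = scores,
                         n_starts = cfg$mixer$n_starts,
                         seed = cfg$seeds$mixer + 2L,
                         n_boot = cfg$mixer$n_boot)
    summ <- derive_overlap_summary(fab)
    report <- list(
      univariate_a = as.list(tidy(fa) |> tibble::deframe()),
      univariate_b = as.list(tidy(fb) |> tibble::deframe()),
      bivariate = as.list(tidy(fab) |> tibble::deframe()),
      dice_se = fab$dice_se,
      aic = c(full = fab$aic, no_overlap = fab$aic_no_overlap)
    )
    jsonlite::write_json(report, pth("mixer.json"), auto_unbox = TRUE,
                         digits = NA)
    readr::write_tsv(summ$loglik_surface, pth("mixer_loglik_surface.tsv"))
    record("mixer", "ok", c("mixer.json", "mixer_loglik_surface.tsv"),
           nrow(pair))
  })

  run_stage("loci", function() {
    snp_fdr <- readr::read_tsv(pth("condfdr.tsv"), show_col_types = FALSE)
    pair <- readr::read_tsv(pth("harmonized.tsv"), show_col_types = FALSE)
    cand <- dplyr::bind_cols(
      pair[match(snp_fdr$SNP, pair$snp), ],
      snp_fdr[, c("condfdr_ab", "condfdr_ba", "conjfdr", "flag_conj")]
    )
    cand$index <- match(cand$snp, pair$snp)
    cand <- cand[cand$flag_conj, ]
    leads <- clump_independent(cand, ld = if (nrow(pair) == ld$m) ld else NULL,
                               r2 = if (nrow(pair) == ld$m) NULL else
                                 diag(nrow(cand)),
                               r2_thresh = cfg$thresholds$r2_clump)
    readr::write_tsv(locus_table(leads), pth("loci.tsv"))
    record("loci", "ok", "loci.tsv", nrow(leads))
  })

  run_stage("epi", function() {
    e <- cfg$epi
    cohort <- simulate_epi_cohort(
      cohort_params(e$n_subjects, true_or = e$true_or, seed = cfg$seeds$epi))
    res <- purrr::map_dfr(c("model1", "model2"), function(lb) {
      spec <- model_spec(lb)
      unmatched <- fit_or(cohort, spec)
      unmatched$analysis <- "unmatched"
      matched <- run_matched_analysis(cohort, spec, caliper = e$caliper,
                                      seed = cfg$seeds$epi + 1L)$estimate
      matched$analysis <- "matched"
      dplyr::bind_rows(unmatched, matched)
    })
    readr::write_tsv(res, pth("epi.tsv"))
    record("epi", "ok", "epi.tsv", nrow(res))
  })

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
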