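## ---------------------------------------------------------------------------
## End-to-end pipeline: generate -> one-per-family -> indicators -> fit K
## range -> screen -> characterize -> compare, with a reproducibility
## manifest.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param cohort a `cohort_config` (or an existing cohort data.frame).
#' @param K_range profile counts to fit.
#' @param n_starts,n_final multi-start EM settings.
#' @param seed master seed for family selection, fitting, and draws.
#' @param threshold characterization deviation threshold (SD units).
#' @param min_prevalence smallest admissible modal profile share.
#' @param prefer_K profile count characterized/compared when no criterion
#'   selects one (substantive choice, surfaced in the report).
#' @param specs outcome model specifications.
#' @param alpha significance level.
#' @param M number of pseudo-class draws.
#' @param lmr compute LMR-LRT p-values in the solution table?
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            K_range = 2:9, n_starts = 100L, n_final = 20L,
                            seed = 1L, threshold = 0.30,
                            min_prevalence = 0.03, prefer_K = 5L,
                            specs = default_outcome_specs(),
                            alpha = 0.05, M = 20L, lmr = TRUE) {
  stopifnot(length(K_range) >= 1)
  structure(list(cohort = cohort, K_range = K_range, n_starts = n_starts,
                 n_final = n_final, seed = as.integer(seed),
                 threshold = threshold, min_prevalence = min_prevalence,
                 prefer_K = prefer_K, specs = specs, alpha = alpha,
                 M = M, lmr = lmr),
            class = "pipeline_config")
}

#' Run the full profile pipeline
#'
#' Generates (or takes) a cohort, keeps one participant per family, builds
#' the standardized indicator matrix, fits the configured range of profile
#' counts, screens solutions, characterizes the chosen solution, and —
#' when it has at least two profiles — compares profiles on all outcome
#' families. Rerunning with the same configuration reproduces every
#' numeric output.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional directory; when given, all stage artifacts and
#'   a manifest are written there.
#' @return list: `cohort`, `analysis_sample`, `indicators`, `fits`,
#'   `solution_table`, `chosen_K`, `fit` (chosen), `characterization`,
#'   `comparisons` (`NULL` for a single-profile solution), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("generate", {
    if (inherits(config$cohort, "cohort_config")) {
      generate_cohort(config$cohort)
    } else config$cohort
  })
  sample1 <- stage("select_one_per_family",
                   select_one_per_family(cohort, seed = config$seed))
  im <- stage("preprocess", build_indicator_matrix(sample1))
  analysis <- sample1[im$rows, , drop = FALSE]
  w <- analysis$sampling_weight
  rng <- stage("fit", fit_lpa_range(
    im$values, K_range = config$K_range, weights = w,
    n_starts = config$n_starts, n_final = config$n_final,
    seed = config$seed, lmr = config$lmr,
    min_prevalence = config$min_prevalence))
  tab <- rng$table
  chosen <- attr(tab, "selected_K")
  if (is.na(chosen)) {
    chosen <- if (!is.null(config$prefer_K) &&
                  config$prefer_K %in% tab$K) {
      config$prefer_K
    } else tab$K[which.min(tab$BIC)]
  }
  fit <- rng$fits[[paste0("K", chosen)]]
  chr <- stage("characterize",
               characterize_profiles(fit, threshold = config$threshold))
  cmp <- NULL
  if (fit$K >= 2) {
    cmp <- stage("compare", compare_profiles(
      analysis, fit$posteriors, specs = config$specs, M = config$M,
      alpha = config$alpha, seed = config$seed))
  } else {
    warning("run_pipeline: single-profile solution; ",
            "comparison stage skipped (no contrasts for K = 1)")
  }
  manifest <- list(
    seed = config$seed, K_range = config$K_range, chosen_K = chosen,
    n_subjects = nrow(cohort), n_analysis = nrow(analysis),
    n_dropped_indicators = im$n_dropped,
    threshold = config$threshold, min_prevalence = config$min_prevalence,
    M = config$M, alpha = config$alpha,
    package_version = as.character(utils::packageVersion("brainprofiles")))
  res <- list(cohort = cohort, analysis_sample = analysis,
              indicators = im, fits = rng$fits, solution_table = tab,
              chosen_K = chosen, fit = fit, characterization = chr,
              comparisons = cmp, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (inherits(config$cohort, "cohort_config")) {
      write_cohort(cohort, config$cohort, file.path(out_dir, "cohort"))
    }
    write_indicator_matrix(im, file.path(out_dir, "indicators.csv"))
    write_solution_table(tab, file.path(out_dir, "solution_table.tsv"))
    write_profile_report(chr, fit, out_dir)
    if (!is.null(cmp)) write_comparison_result(cmp, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
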