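#' Default confounders and candidate risk factors for the class models
#'
#' The five locked confounders (infant age at measurement, sex, birth
#' weight, birth mode, parity) and the ten candidate maternal risk
#' factors subject to bootstrap selection.
#'
#' @export
DEFAULT_CONFOUNDERS <- c("age_at_measurement_days", "infant_sex",
                         "birth_weight_g", "birth_mode",
                         "parity_primiparous")

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: simulation spec (or
#' external inputs), the class range and selection criteria, BLRT and
#' bootstrap replication counts, the risk-factor and confounder lists,
#' the legacy milk-production threshold used in the comparison, and the
#' master seed from which each stage's seed is derived deterministically
#' (so single stages can be rerun stably).
#'
#' @param spec a [cohort_spec()] for simulation (ignored when `measures`
#'   is supplied to [run_pipeline()]).
#' @param k_range candidate class numbers (contiguous from 1).
#' @param n_boot_blrt bootstrap replicates for the BLRT.
#' @param criteria model-selection thresholds, see [select_model()].
#' @param risk_factors,confounders predictor sets for the class models.
#' @param B stability-selection resamples.
#' @param retention stability retention threshold.
#' @param composites list of 2-vectors: binary factor pairs to model as
#'   four-level composites.
#' @param legacy_mp_threshold previously proposed milk-production cut
#'   (mL/24 h) compared against the derived one.
#' @param min_roc_n minimum subgroup size for panel curves.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), k_range = 1:5,
                            n_boot_blrt = 99,
                            criteria = list(entropy = 0.8,
                                            avg_posterior = 0.5,
                                            min_share = 0.05, alpha = 0.05),
                            risk_factors = RISK_FACTORS,
                            confounders = DEFAULT_CONFOUNDERS,
                            B = 200, retention = 0.5,
                            composites = list(
                              c("ow", "advanced_age"),
                              c("minimal_breast_growth", "advanced_age")),
                            legacy_mp_threshold = 600,
                            min_roc_n = 20, seed = 1L) {
  stopifnot(criteria$entropy >= 0, criteria$avg_posterior >= 0,
            criteria$min_share >= 0, criteria$min_share < 1,
            retention >= 0, retention < 1, B >= 1)
  structure(list(spec = spec, k_range = k_range, n_boot_blrt = n_boot_blrt,
                 criteria = criteria, risk_factors = risk_factors,
                 confounders = confounders, B = B, retention = retention,
                 composites = composites,
                 legacy_mp_threshold = legacy_mp_threshold,
                 min_roc_n = min_roc_n, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full low-milk-supply analysis pipeline
#'
#' Orchestrates the stages end to end: simulate (or accept) a cohort,
#' derive per-dyad feeding and growth measures from the diaries,
#' classify dyads by latent profile analysis with multi-criterion model
#' selection, derive diagnostic thresholds by ROC analysis (with the
#' legacy-vs-new milk-production threshold comparison), and fit the
#' risk-factor models with bootstrap stability selection and composite
#' factors. Deterministic given the master seed. When classification
#' does not yield both NMS and LMS groups (e.g. `k_range = 1`), the
#' threshold and risk stages are skipped and the manifest records why.
#'
#' @param config a [pipeline_config()].
#' @param measures optionally, a precomputed per-dyad measures tibble
#'   (skips simulation and derivation; must contain the indicator,
#'   risk-factor and confounder columns).
#' @param outdir optional directory; when given, CSV/JSON reports are
#'   written (cohort summary, model report, assignments, ROC panel,
#'   stability and OR tables, manifest).
#' @return object of class `lms_pipeline`: the cohort, measures,
#'   selection, assignment, ROC panel, threshold comparison, risk
#'   results, and a `manifest` list with every headline number, the
#'   stage funnel, and a config fingerprint.
#' @export
run_pipeline <- function(config = pipeline_config(), measures = NULL,
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed)
  funnel <- list()
  cohort <- NULL

  if (is.null(measures)) {
    spec <- config$spec
    spec$seed <- derive_seed(config$seed, 1L)
    cohort <- generate_cohort(spec, diaries = TRUE)
    measures <- derive_dyad_measures(cohort$diaries, cohort$cohort)
    funnel$n_generated <- nrow(measures)
  } else {
    funnel$n_generated <- nrow(measures)
  }

  # --- classification ---------------------------------------------------
  prep <- prepare_indicators(measures)
  funnel$n_lpa_complete_cases <- nrow(prep$x)
  sel <- select_model(prep, k_range = config$k_range,
                      n_boot = config$n_boot_blrt,
                      seed = derive_seed(config$seed, 2L),
                      criteria = config$criteria)
  manifest$selected_k <- sel$selected_k
  manifest$model_report <- sel$report
  assignment <- NULL
  if (!is.na(sel$selected_k) && sel$selected_k >= 2) {
    best <- sel$models[[paste0("k", sel$selected_k)]]
    assignment <- assign_profiles(best, prep)
    manifest$entropy <- best$entropy
    manifest$lms_share_pct <- percent(sum(assignment$group == "LMS"),
                                      nrow(assignment))
    manifest$class_counts <- table(assignment$class)
  } else {
    manifest$note_grouping <-
      "no multi-class solution selected; NMS/LMS grouping impossible"
  }

  analysis <- measures
  if (!is.null(assignment)) {
    analysis <- dplyr::left_join(measures, assignment, by = "dyad_id")
  }

  # --- thresholds -------------------------------------------------------
  panel <- NULL
  comparison <- NULL
  if (!is.null(assignment) && length(unique(assignment$group)) == 2) {
    panel <- predictor_panel(analysis, min_n = config$min_roc_n)
    mp_roc <- panel$roc[[which(panel$predictor == "mp_24h")]]
    comparison <- threshold_comparison(
      analysis$mp_24h, analysis$group == "LMS",
      threshold_old = config$legacy_mp_threshold,
      threshold_new = youden_optimal(mp_roc),
      direction = "lower")
    manifest$roc_panel <- dplyr::select(panel, -"roc")
    manifest$threshold_comparison <- comparison
  } else {
    manifest$note_thresholds <- "threshold stage skipped: single group"
  }

  # --- risk factors -----------------------------------------------------
  stability <- NULL
  composites <- NULL
  if (!is.null(assignment) &&
      length(unique(assignment$class)) >= 2) {
    risk_data <- dplyr::mutate(analysis, class = factor(.data$class))
    funnel$n_risk_complete_cases <- sum(complete.cases(
      risk_data[c("class", config$risk_factors, config$confounders)]))
    stability <- bootstrap_stability(
      risk_data, "class", config$risk_factors, config$confounders,
      B = config$B, retention = config$retention,
      seed = derive_seed(config$seed, 3L), reference = "1")
    manifest$stability <- stability$frequencies
    manifest$odds_ratios <- tidy(stability$final_model)
    composites <- purrr::map(config$composites, function(pair) {
      fit_composite_model(risk_data, "class", pair[1], pair[2],
                          confounders = config$confounders,
                          other_predictors = setdiff(stability$retained, pair),
                          reference = "1")
    })
    names(composites) <- purrr::map_chr(config$composites, paste,
                                        collapse = "_x_")
    manifest$composite_odds_ratios <- purrr::map(composites,
                                                 function(cm) tidy(cm$model))
  } else {
    manifest$note_risks <- "risk stage skipped: fewer than 2 classes"
  }

  manifest$funnel <- funnel
  manifest$config_hash <- rlang::hash(config)

  out <- structure(list(cohort = cohort, measures = measures, prep = prep,
                        selection = sel, assignment = assignment,
                        panel = panel, comparison = comparison,
                        stability = stability, composites = composites,
                        manifest = manifest, config = config),
                   class = "lms_pipeline")
  if (!is.null(outdir)) write_pipeline_reports(out, outdir)
  out
}

#' @export
print.lms_pipeline <- function(x, ...) {
  cat(sprintf("<lms_pipeline> n = %d, selected k = %s",
              nrow(x$measures),
              ifelse(is.na(x$selection$selected_k), "none",
                     x$selection$selected_k)))
  if (!is.null(x$manifest$lms_share_pct)) {
    cat(sprintf(", LMS share = %.1f%%", x$manifest$lms_share_pct))
  }
  cat("\n")
  invisible(x)
}

write_pipeline_reports <- function(pipeline, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  readr::write_csv(describe_cohort(pipeline$measures,
                                   intersect(c("mp_24h", "total_intake_24h",
                                               "breastmilk_intake_24h",
                                               "formula_intake_24h",
                                               "waz_current", "delta_waz",
                                               "avg_daily_gain", "bmi",
                                               "maternal_age"),
                                             names(pipeline$measures))),
                  file.path(outdir, "cohort_summary.csv"))
  readr::write_csv(pipeline$selection$report,
                   file.path(outdir, "model_selection.csv"))
  if (!is.null(pipeline$assignment)) {
    readr::write_csv(pipeline$assignment,
                     file.path(outdir, "assignments.csv"))
  }
  if (!is.null(pipeline$panel)) {
    readr::write_csv(dplyr::select(pipeline$panel, -"roc"),
                     file.path(outdir, "roc_panel.csv"))
  }
  if (!is.null(pipeline$stability)) {
    readr::write_csv(pipeline$stability$frequencies,
                     file.path(outdir, "stability.csv"))
    readr::write_csv(tidy(pipeline$stability$final_model),
                     file.path(outdir, "odds_ratios.csv"))
  }
  manifest <- pipeline$manifest
  manifest$class_counts <- as.list(manifest$class_counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(outdir)
}
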