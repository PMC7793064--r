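#' Default pipeline configuration
#'
#' A single structured configuration covering every stage: cohort
#' simulation (panel, effects, sizes), preprocessing, percentile grid,
#' Fisher model settings, validation schemes and the association
#' stage. Any subset can be overridden through `...` or by a YAML file
#' with the same structure.
#'
#' @param ... Named overrides merged over the defaults (nested lists
#'   merged shallowly per section).
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    cohort = list(n_patients = 56, prevalence = 13 / 56,
                  events_per_tube = 5000, delta = -1, fraction = 1),
    preprocess = list(n_events = 2000, min_markers = 15,
                      gate_marker = "CD19", clip = TRUE),
    logicle = list(w = 0.75, t = 262144, m = 4.5, a = 0),
    grid = seq(5, 95, by = 5),
    fisher = list(threshold = 0.5, location = "median",
                  convention = "proximity", distance = "feature"),
    validate = list(k = 5, repeats = 20),
    associate = list(marker = "CD38", levels = c(15, 50, 85))
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

#' Run the full analysis pipeline from one configuration
#'
#' Simulates a cohort, maps it to raw scale with spillover, writes FCS
#' 3.0 files and the clinical table, preprocesses them back in
#' (compensation, logicle, merging, normalisation, gating,
#' subsampling), builds percentile features, fits the Fisher model,
#' cross-validates it (LOOCV and k-fold), and runs the association
#' stage. All randomness flows from the single master seed, so a rerun
#' with the same configuration is bit-identical.
#'
#' Reports written to `out_dir`: `performance.csv` (scheme x metric,
#' mean and sd), `fisher_features.csv`, `marker_fr.csv`,
#' `correlations.csv` plus `correlation_matrix.csv` (r lower triangle,
#' p upper), and `provenance.json`.
#'
#' @param config A list from [pipeline_config()], or a path to a YAML
#'   file with the same structure.
#' @param out_dir Output directory for reports and intermediate files.
#' @return (Invisibly) a list with the cohort, samples, features,
#'   model, cv results and correlation report.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("pipeline")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- do.call(pipeline_config, config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  params <- do.call(logicle_params, cfg$logicle)
  effects <- default_effects(delta = cfg$cohort$delta,
                             fraction = cfg$cohort$fraction)
  cohort <- simulate_cohort(
    n_patients = cfg$cohort$n_patients,
    prevalence = cfg$cohort$prevalence,
    events_per_tube = cfg$cohort$events_per_tube,
    effects = effects, seed = cfg$seed, include = "tubes")
  raw <- cohort_raw(cohort, params = params)
  fcs_dir <- file.path(out_dir, "fcs")
  write_cohort(raw, fcs_dir)

  samples <- preprocess_cohort(
    fcs_dir, backbone = cohort$design$backbone,
    n_events = cfg$preprocess$n_events, seed = cfg$seed,
    params = params, gate_marker = cfg$preprocess$gate_marker,
    min_markers = cfg$preprocess$min_markers,
    clip = cfg$preprocess$clip)

  features <- percentile_features(samples, grid = cfg$grid)
  model <- fisher_fit(features, threshold = cfg$fisher$threshold,
                      location = cfg$fisher$location,
                      convention = cfg$fisher$convention,
                      distance = cfg$fisher$distance)

  cv_loo <- cross_validate(features, "loocv",
                           repeats = cfg$validate$repeats,
                           seed = cfg$seed,
                           threshold = cfg$fisher$threshold,
                           convention = cfg$fisher$convention,
                           distance = cfg$fisher$distance)
  cv_k <- cross_validate(features, "kfold", k = cfg$validate$k,
                         repeats = cfg$validate$repeats,
                         seed = cfg$seed,
                         threshold = cfg$fisher$threshold,
                         convention = cfg$fisher$convention,
                         distance = cfg$fisher$distance)
  perf <- dplyr::bind_rows(
    dplyr::mutate(cv_loo$summary, scheme = "loocv", .before = 1),
    dplyr::mutate(cv_k$summary,
                  scheme = sprintf("%d-fold", cfg$validate$k),
                  .before = 1))

  clinical <- attr(samples, "clinical")
  corr <- correlate_markers(clinical, features,
                            marker = cfg$associate$marker,
                            levels = cfg$associate$levels)

  num <- function(d) dplyr::mutate(d, dplyr::across(
    dplyr::where(is.numeric), function(v) round(v, 10)))
  utils::write.csv(num(perf), file.path(out_dir, "performance.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(num(model$features),
                   file.path(out_dir, "fisher_features.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(num(marker_fr(model)),
                   file.path(out_dir, "marker_fr.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(num(corr$pairs),
                   file.path(out_dir, "correlations.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(round(report_matrix(corr), 10),
                   file.path(out_dir, "correlation_matrix.csv"),
                   na = "")
  jsonlite::write_json(
    list(seed = cfg$seed, config = cfg,
         n_patients = length(samples),
         events_per_patient = nrow(samples[[1]]$events),
         markers = colnames(samples[[1]]$events),
         selected_features = sum(model$features$selected)),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = cfg, cohort = cohort, samples = samples,
                 features = features, model = model,
                 cv = list(loocv = cv_loo, kfold = cv_k),
                 performance = perf, correlations = corr,
                 out_dir = out_dir))
}
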