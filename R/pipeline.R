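#' Run the glycemic-variability pattern pipeline end to end
#'
#' Wires the full analysis: simulate or read CGM data, deduplicate, window
#' and density-filter, optionally grid-search the windowing hyperparameters,
#' choose the number of patterns by the elbow (unless `k` is fixed), fit the
#' DTW k-medoids pattern model, compute per-patient time in patterns and
#' glycemic metrics, cluster patients on their compositions, and write
#' per-pattern envelopes, hourly occurrence tables and (when clinical data
#' are supplied) the cluster comparison table. Every artifact is a plain CSV
#' or JSON file under `out_dir`; the resolved configuration (including the
#' seed and package version) is written alongside as `run_config.json`.
#' Reruns with identical inputs, seed and configuration produce
#' byte-identical artifacts.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed used for every stochastic step.
#' @param input path to a CGM CSV; `NULL` (default) simulates a cohort.
#' @param dialect,unit passed to [read_cgm_csv()] when `input` is given.
#' @param clinical optional path to a clinical covariate CSV.
#' @param sim_config [synthetic_config()] used when simulating (its seed is
#'   overridden by `seed`).
#' @param grid run [grid_search()] to pick duration/overlap (default FALSE).
#' @param duration,overlap,min_density windowing settings when `grid` is
#'   FALSE.
#' @param k number of patterns; `NULL` (default) selects k by
#'   [elbow_select_k()] over `k_range`.
#' @param k_range candidate pattern counts for the elbow.
#' @param dtw a [dtw_config()].
#' @param distance composition distance for patient clustering.
#' @param subsample,restarts tuning knobs passed through.
#' @return invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, input = NULL,
                         dialect = "long", unit = "auto", clinical = NULL,
                         sim_config = NULL, grid = FALSE,
                         duration = 150, overlap = 50, min_density = 4,
                         k = NULL, k_range = 3:8, dtw = dtw_config(),
                         distance = "hellinger", subsample = 500,
                         restarts = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  truth <- NULL
  if (is.null(input)) {
    cfg <- sim_config %||% synthetic_config()
    cfg$seed <- seed
    message("INFO simulating cohort: ", cfg$n_patients, " patients x ",
            cfg$days_per_patient, " days")
    cohort <- generate_cohort(cfg)
    data <- cohort$data
    truth <- cohort$truth
    paths$cgm <- file.path(out_dir, "cgm.csv")
    write_cgm_csv(data, paths$cgm)
    paths$truth <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(
      data.frame(patient_id = truth$patient_id,
                 segment_start = format(truth$segment_start,
                                        "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                 template = truth$template, archetype = truth$archetype),
      paths$truth, row.names = FALSE, quote = FALSE)
  } else {
    data <- read_cgm_csv(input, dialect = dialect, unit = unit)
    rep <- drop_report(data)
    message("INFO read ", rep$n_rows, " rows, dropped ", rep$n_dropped)
  }
  data <- dedup_minute_median(data)

  if (grid) {
    gs <- grid_search(data, k_fixed = if (is.null(k)) 6 else k,
                      dtw = dtw, seed = seed, min_density = min_density,
                      subsample = subsample, restarts = restarts)
    wcfg <- gs$best
    paths$validity <- file.path(out_dir, "validity_report.csv")
    utils::write.csv(gs$report, paths$validity, row.names = FALSE)
    message("INFO grid search selected ", wcfg$duration, " min / ",
            wcfg$overlap_pct, "% overlap")
  } else {
    wcfg <- windowing_config(duration = duration, overlap_pct = overlap,
                             min_density = min_density)
  }
  wins_all <- extract_windows(data, wcfg)
  filt <- density_filter(wins_all, wcfg$min_density)
  windows <- filt$kept
  message("INFO windows: ", nrow(wins_all), " extracted, ",
          filt$n_discarded, " discarded by density filter, ",
          nrow(windows), " kept")

  if (is.null(k)) {
    elbow <- elbow_select_k(windows, k_range = k_range, dtw = dtw,
                            seed = seed, restarts = restarts)
    k <- elbow$k_star
    paths$elbow <- file.path(out_dir, "elbow_curve.csv")
    utils::write.csv(elbow$curve, paths$elbow, row.names = FALSE)
    message("INFO elbow selected k = ", k)
  }
  model <- cluster_windows(windows, k, dtw = dtw, seed = seed,
                           restarts = restarts)
  paths$model <- file.path(out_dir, "pattern_model.json")
  write_pattern_model(model, paths$model)
  labeled <- tibble::tibble(patient_id = windows$patient_id,
                            window_start = format(windows$start,
                                                  "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                            start_hour = windows$start_hour,
                            pattern = model$labels)
  paths$labels <- file.path(out_dir, "window_labels.csv")
  utils::write.csv(labeled, paths$labels, row.names = FALSE, quote = FALSE)

  tip <- time_in_patterns(labeled, k)
  paths$tip <- file.path(out_dir, "time_in_patterns.csv")
  utils::write.csv(tip, paths$tip, row.names = FALSE, quote = FALSE)
  summ <- target_fulfillment(glycemic_summary(data))
  metrics <- dplyr::left_join(summ, tip, by = "patient_id")
  paths$metrics <- file.path(out_dir, "patient_metrics.csv")
  utils::write.csv(metrics, paths$metrics, row.names = FALSE, quote = FALSE)

  clusters <- NULL
  if (nrow(tip) >= 2) {
    tree <- hcluster_patients(tip, method = distance)
    clusters <- cut_by_largest_gap(tree)
    paths$linkage <- file.path(out_dir, "linkage.json")
    write_linkage_json(tree, paths$linkage)
    paths$clusters <- file.path(out_dir, "patient_clusters.csv")
    utils::write.csv(data.frame(patient_id = names(clusters),
                                cluster = unname(clusters)),
                     paths$clusters, row.names = FALSE, quote = FALSE)
    message("INFO patients grouped into ", max(clusters), " clusters")
  }

  bands <- pattern_range_summary(model, windows, labels = model$labels)
  paths$envelopes <- file.path(out_dir, "pattern_envelopes.csv")
  utils::write.csv(bands$envelopes, paths$envelopes, row.names = FALSE)
  paths$bands <- file.path(out_dir, "pattern_bands.csv")
  utils::write.csv(bands$bands, paths$bands, row.names = FALSE, quote = FALSE)
  hourly <- pattern_occurrence_by_hour(labeled, k)
  paths$hourly <- file.path(out_dir, "pattern_hourly.csv")
  utils::write.csv(hourly, paths$hourly, row.names = FALSE)

  stats_table <- NULL
  if (!is.null(clinical) && !is.null(clusters)) {
    clin <- read_clinical_csv(clinical)
    stats_table <- compare_clusters(clin, clusters)
    paths$stats <- file.path(out_dir, "cluster_stats.csv")
    utils::write.csv(stats_table, paths$stats, row.names = FALSE)
  }

  resolved <- list(
    package_version = as.character(utils::packageVersion("gvpatterns")),
    seed = seed, input = input %||% "simulated",
    windowing = list(duration = wcfg$duration, overlap_pct = wcfg$overlap_pct,
                     min_density = wcfg$min_density),
    dtw = list(local_cost = dtw$local_cost, band = dtw$band,
               normalize_inputs = dtw$normalize_inputs),
    k = k, distance = distance
  )
  paths$config <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(resolved, paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")

  invisible(list(model = model, windows = windows, labeled = labeled,
                 tip = tip, metrics = metrics, clusters = clusters,
                 stats_table = stats_table, windowing = wcfg, paths = paths))
}

#' Assign new CGM data to a trained pattern model
#'
#' External-validation path: applies the model's own windowing duration, the
#' density filter and DTW-nearest-medoid assignment to a new cohort.
#'
#' @param model a `pattern_model` (or a path to a model JSON).
#' @param data CGM tibble, or a path to a CGM CSV (long dialect).
#' @param overlap overlap percentage for windowing (default 50).
#' @param min_density density-filter threshold (default 4).
#' @param out optional CSV path for the labels (one row per kept window).
#' @return tibble `patient_id`, `window_start`, `start_hour`, `pattern`,
#'   `distance`.
#' @export
assign_cgm <- function(model, data, overlap = 50, min_density = 4,
                       out = NULL) {
  if (is.character(model)) model <- read_pattern_model(model)
  if (is.character(data)) data <- read_cgm_csv(data)
  data <- dedup_minute_median(data)
  wcfg <- windowing_config(duration = model$duration, overlap_pct = overlap,
                           min_density = min_density)
  windows <- density_filter(extract_windows(data, wcfg), min_density)$kept
  lab <- assign_windows(model, windows)
  res <- tibble::tibble(
    patient_id = windows$patient_id,
    window_start = format(windows$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    start_hour = windows$start_hour,
    pattern = as.integer(lab),
    distance = attr(lab, "distance")
  )
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}
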