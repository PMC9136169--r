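# End-to-end pipeline: simulate -> preprocess -> features -> classify ----

#' Configure an end-to-end pipeline run
#'
#' Bundles every tunable of the pipeline: the synthetic cohort, the
#' preprocessing settings, the NCC analysis sources, and the classifier
#' settings. A run is reproducible from the configuration alone.
#'
#' @param cohort A [cohort_config()].
#' @param sources Signal sources to analyze, subset of
#'   `c("x", "y", "z", "rss")`.
#' @param template_index Template cycle among the midsection cycles.
#' @param n_cycles Midsection cycles per trial. Default 5.
#' @param normalized_length Normalized cycle length. Default 100.
#' @param filter_order,cutoff_hz Butterworth settings.
#' @param min_separation_s,depth_sd Heel-strike detector settings.
#' @param k Fixed K or `"auto"`.
#' @param candidates Candidate grid for `k = "auto"`.
#' @param folds Cross-validation folds. Default 5.
#' @param seed Seed for fold assignment (the cohort has its own seed).
#' @param group_by_participant Keep each participant's trials in one fold.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            sources = c("rss", "x"),
                            template_index = 3,
                            n_cycles = 5,
                            normalized_length = 100,
                            filter_order = 8,
                            cutoff_hz = 20,
                            min_separation_s = 0.5,
                            depth_sd = 0.5,
                            k = "auto",
                            candidates = c(3, 5, 7, 9, 11),
                            folds = 5,
                            seed = 1L,
                            group_by_participant = FALSE) {
  sources <- match.arg(sources, c("x", "y", "z", "rss"), several.ok = TRUE)
  structure(
    list(cohort = cohort, sources = sources, template_index = template_index,
         n_cycles = n_cycles, normalized_length = normalized_length,
         filter_order = filter_order, cutoff_hz = cutoff_hz,
         min_separation_s = min_separation_s, depth_sd = depth_sd,
         k = k, candidates = candidates, folds = folds,
         seed = as.integer(seed),
         group_by_participant = group_by_participant),
    class = "pipeline_config"
  )
}

#' Run the full fall-risk assessment pipeline
#'
#' Simulates the configured cohort, extracts gait-pattern features for every
#' requested signal source, fits the cross-validated kNN classifier per
#' source, and (optionally) writes the run artifacts: the trial CSVs and
#' manifest, the feature table, and a JSON report with the confusion
#' matrices, metric panels, and K-selection curves.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return A `fall_pipeline` object: `cohort`, `features`, `fits` (one
#'   `fall_knn_cv` per source), `report` (plain-list summary), `config`.
#' @export
#' @examples
#' cfg <- pipeline_config(cohort = cohort_config(n_nonfallers = 6, n_fallers = 6, seed = 5))
#' run <- run_fall_pipeline(cfg)
#' run$report$panels$rss$accuracy
run_fall_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config")
  cohort <- simulate_cohort(config$cohort)
  features <- extract_gait_features(
    cohort, sources = config$sources,
    template_index = config$template_index, n_cycles = config$n_cycles,
    L = config$normalized_length, filter_order = config$filter_order,
    cutoff_hz = config$cutoff_hz,
    min_separation_s = config$min_separation_s, depth_sd = config$depth_sd
  )
  fits <- lapply(setNames(config$sources, config$sources), function(src) {
    fit_fall_knn(features[features$source == src, ],
                 k = config$k, candidates = config$candidates,
                 n_folds = config$folds, seed = config$seed,
                 group_by_participant = config$group_by_participant)
  })
  report <- list(
    n_trials = nrow(cohort),
    n_vectors = nrow(features),
    n_quarantined = NROW(attr(features, "quarantined")),
    sources = config$sources,
    panels = lapply(fits, function(f) {
      list(k = f$k,
           confusion = unclass(f$confusion),
           accuracy = f$metrics$accuracy,
           mcc = f$metrics$mcc,
           per_class = f$metrics$per_class,
           k_curve = f$k_curve)
    })
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "trials"))
    write_gait_features(features, file.path(out_dir, "gait_features.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    metrics_csv <- dplyr::bind_rows(lapply(names(fits), function(src) {
      tb <- tidy(fits[[src]])
      tb$source <- src
      tb
    }))
    readr::write_csv(metrics_csv, file.path(out_dir, "metrics.csv"))
  }
  structure(
    list(cohort = cohort, features = features, fits = fits,
         report = report, config = config),
    class = "fall_pipeline"
  )
}

#' @export
print.fall_pipeline <- function(x, ...) {
  cat(sprintf("<fall_pipeline> %d trials, %d gait-pattern vectors\n",
              x$report$n_trials, x$report$n_vectors))
  for (src in names(x$fits)) {
    f <- x$fits[[src]]
    cat(sprintf("  %-4s k = %d  accuracy %.3f  MCC %.3f\n",
                src, f$k, f$metrics$accuracy, f$metrics$mcc))
  }
  invisible(x)
}

#' Write the diagnostic figures of a completed pipeline run
#'
#' Produces one file per diagnostic: a segmented example trial, the four
#' NCC series of that trial, the feature distribution line chart, and the
#' K-selection error curve. Plot failures are caught and warned about;
#' they never corrupt the numeric artifacts.
#'
#' @param pipeline A `fall_pipeline` object from [run_fall_pipeline()].
#' @param out_dir Directory for the figure files.
#' @param device File extension understood by [ggplot2::ggsave()]. Default
#'   `"png"`.
#' @return Character vector of the files written, invisibly.
#' @export
plot_diagnostics <- function(pipeline, out_dir, device = "png") {
  if (!inherits(pipeline, "fall_pipeline") || pipeline$report$n_trials == 0) {
    warn("no completed run artifacts; no figures written")
    return(invisible(character(0)))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  src <- pipeline$config$sources[[1]]
  trial <- pipeline$cohort[1, ]
  figs <- list(
    segmented_trial = function() plot_trial(trial, source = src),
    ncc_series = function() plot_ncc_series(trial, source = src),
    feature_distribution = function() plot_gait_features(
      pipeline$features[pipeline$features$source == src, ]
    ),
    k_selection = function() autoplot(pipeline$fits[[src]])
  )
  written <- character(0)
  for (nm in names(figs)) {
    path <- file.path(out_dir, paste0(nm, ".", device))
    ok <- tryCatch({
      ggplot2::ggsave(path, figs[[nm]](), width = 7, height = 5, dpi = 120)
      TRUE
    }, error = function(e) {
      warn(sprintf("figure `%s` failed: %s", nm, conditionMessage(e)))
      FALSE
    })
    if (ok) written <- c(written, path)
  }
  invisible(written)
}
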