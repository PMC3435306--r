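# End-to-end orchestration: configuration, staged execution, artifact
# writing, and the run report.

#' Assemble a full pipeline configuration
#'
#' Every parameter has a documented default equal to the module defaults;
#' the serialized configuration plus the seed reproduces a run bit for bit.
#' Input is either a simulation configuration (`sim`) or a directory of
#' spectra plus sample sheet (`input_dir`), exactly one of the two.
#'
#' @param sim a [sim_config()] (default: the standard 35 case / 23 control
#'   cohort) or `NULL` when reading from disk.
#' @param input_dir directory readable by [read_cohort()], or `NULL`.
#' @param grid m/z grid for preprocessing; `NULL` for the default 1 Da grid.
#' @param baseline_window_Da,target_tic,min_tic,min_corr_to_mean
#'   preprocessing and QC parameters, see [preprocess_cohort()].
#' @param snr_min,min_separation_Da,noise_window_Da,smooth_Da
#'   peak-detection parameters, see [detect_peaks()].
#' @param n_trees,mtry forest parameters, see [fit_forest()].
#' @param cv_folds,cv_repetitions cross-validation geometry.
#' @param run_nested also compute the nested generalization estimate
#'   (default `TRUE`).
#' @param seed master seed for the whole run; every stage derives its seeds
#'   from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            grid = NULL, baseline_window_Da = 200,
                            target_tic = 1, min_tic = 1,
                            min_corr_to_mean = 0.5,
                            snr_min = 2, min_separation_Da = 5,
                            noise_window_Da = 250, smooth_Da = 5,
                            n_trees = 500, mtry = NULL,
                            cv_folds = 10, cv_repetitions = 10,
                            run_nested = TRUE, seed = 1L) {
  if (is.null(sim) && is.null(input_dir)) {
    stop("either sim or input_dir must be given")
  }
  if (!is.null(sim) && !is.null(input_dir)) {
    stop("give either sim or input_dir, not both")
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    stop("sim must be a sim_config")
  }
  structure(
    list(
      sim = sim, input_dir = input_dir, grid = grid,
      baseline_window_Da = baseline_window_Da, target_tic = target_tic,
      min_tic = min_tic, min_corr_to_mean = min_corr_to_mean,
      snr_min = snr_min, min_separation_Da = min_separation_Da,
      noise_window_Da = noise_window_Da, smooth_Da = smooth_Da,
      n_trees = n_trees, mtry = mtry,
      cv_folds = cv_folds, cv_repetitions = cv_repetitions,
      run_nested = isTRUE(run_nested), seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr, quiet) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!quiet) {
    message(sprintf("[maldirf] %-12s done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Run the full profiling pipeline
#'
#' Executes simulate (or read) -> preprocess -> peak detection ->
#' quantification -> full-set repeated CV -> median-MDA recursive feature
#' elimination -> nested CV -> univariate screening of the selected panel,
#' and assembles a run report. With `outdir` set, all intermediate
#' artifacts and the report are written as CSV/JSON.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param quiet suppress per-stage progress messages (default `FALSE`).
#' @return an object of class `run_report` (a list): `qc_summary`,
#'   `n_peaks`, `peakset`, `features`, `cv_full`, `rfe`, `ranked_panel`
#'   (peak id + MDA z-score for the selected panel), `cv_selected`,
#'   `cv_nested`, `roc`, `univariate`, `truth_recovery` (when simulated),
#'   and `provenance`.
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_seeds <- derive_seeds(config$seed, 6L)

  truth <- NULL
  cohort <- run_stage("input", {
    if (!is.null(config$sim)) {
      sim_cfg <- config$sim
      sim_cfg$seed <- stage_seeds[1L]
      sim <- generate_cohort(sim_cfg)
      truth <- sim$truth
      sim$cohort
    } else {
      read_cohort(config$input_dir)
    }
  }, quiet)

  prep <- run_stage("preprocess", preprocess_cohort(
    cohort, grid = config$grid,
    baseline_window_Da = config$baseline_window_Da,
    target_tic = config$target_tic, min_tic = config$min_tic,
    min_corr_to_mean = config$min_corr_to_mean
  ), quiet)

  peakset <- run_stage("detect", detect_peaks(
    prep$mean, snr_min = config$snr_min,
    min_separation_Da = config$min_separation_Da,
    noise_window_Da = config$noise_window_Da, smooth_Da = config$smooth_Da
  ), quiet)
  if (!length(peakset$centers)) stop("stage 'detect' failed: no peaks found")

  features <- run_stage("quantify", quantify(prep$cohort, peakset), quiet)

  cv_full <- run_stage("cv_full", repeated_cv(
    features, n_folds = config$cv_folds,
    n_repetitions = config$cv_repetitions,
    n_trees = config$n_trees, mtry = config$mtry, seed = stage_seeds[2L]
  ), quiet)

  trace <- run_stage("rfe", rfe(
    features, n_trees = config$n_trees, mtry = config$mtry,
    cv_folds = config$cv_folds, cv_repetitions = config$cv_repetitions,
    seed = stage_seeds[3L]
  ), quiet)

  cv_nested <- if (config$run_nested) {
    run_stage("nested", nested_performance(
      features,
      selected_fraction = length(trace$selected_features) /
        ncol(features$values),
      n_folds = config$cv_folds, n_repetitions = config$cv_repetitions,
      n_trees = config$n_trees, mtry = config$mtry, seed = stage_seeds[4L]
    ), quiet)
  } else NULL

  report <- run_stage("report", {
    panel_fm <- fm_subset(features, peak_ids = trace$selected_features)
    panel_model <- fit_forest(panel_fm, n_trees = config$n_trees,
                              mtry = config$mtry, seed = stage_seeds[5L])
    ranked <- data.frame(
      peak = panel_model$feature_ids,
      mda_z = panel_model$mda_z,
      stringsAsFactors = FALSE
    )
    ranked <- ranked[order(-ranked$mda_z), ]
    rownames(ranked) <- NULL

    uni <- univariate_table(panel_fm)
    roc <- roc_points(trace$selected_cv$predictions$vote,
                      trace$selected_cv$predictions$label)

    truth_recovery <- if (!is.null(truth) && length(truth$marker_centers)) {
      sel_centers <- peakset$centers[match(trace$selected_features,
                                           peakset$peak_ids)]
      step <- stats::median(diff(prep$grid))
      hits <- vapply(truth$marker_centers, function(cm) {
        any(abs(sel_centers - cm) <= 2 * step)
      }, logical(1))
      list(n_markers = length(truth$marker_centers),
           n_recovered = sum(hits),
           marker_centers = truth$marker_centers,
           recovered = hits)
    } else NULL

    cfg_json <- config_json(config)
    structure(
      list(
        qc_summary = list(
          n_spectra_in = length(cohort$spectra),
          n_excluded = sum(prep$qc_report$excluded)
        ),
        qc_report = prep$qc_report,
        n_peaks = length(peakset$centers),
        peakset = peakset,
        features = features,
        cv_full = cv_full,
        rfe = trace,
        ranked_panel = ranked,
        cv_selected = trace$selected_cv,
        cv_nested = cv_nested,
        roc = roc,
        univariate = uni,
        truth_recovery = truth_recovery,
        provenance = list(
          package = "maldirf",
          version = as.character(utils::packageVersion("maldirf")),
          seed = config$seed,
          config_hash = fnv1a32(cfg_json),
          config = config
        )
      ),
      class = "run_report"
    )
  }, quiet)

  if (!is.null(outdir)) {
    run_stage("write", write_report(report, outdir), quiet)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<run_report> %d spectra (%d excluded by QC), %d peaks\n",
      "  full set   : AUC %.3f, accuracy %.1f%%\n",
      "  selected   : %d peaks, AUC %.3f, accuracy %.1f%%\n"
    ),
    x$qc_summary$n_spectra_in, x$qc_summary$n_excluded, x$n_peaks,
    x$cv_full$auc, x$cv_full$accuracy,
    nrow(x$ranked_panel), x$cv_selected$auc, x$cv_selected$accuracy
  ))
  if (!is.null(x$cv_nested)) {
    cat(sprintf("  nested     : AUC %.3f, accuracy %.1f%%\n",
                x$cv_nested$auc, x$cv_nested$accuracy))
  }
  if (!is.null(x$truth_recovery)) {
    cat(sprintf("  truth      : %d / %d planted markers in the panel\n",
                x$truth_recovery$n_recovered, x$truth_recovery$n_markers))
  }
  invisible(x)
}

config_json <- function(config) {
  jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

cv_summary_list <- function(cv) {
  if (is.null(cv)) return(NULL)
  list(
    auc = cv$auc, accuracy = cv$accuracy, sensitivity = cv$sensitivity,
    specificity = cv$specificity, counts = as.list(cv$counts),
    n_folds = cv$n_folds, n_repetitions = cv$n_repetitions,
    n_predictions = nrow(cv$predictions)
  )
}

#' Write all artifacts of a run report to a directory
#'
#' Emits `config.json`, `qc_report.csv`, `peaks.csv`,
#' `feature_matrix.csv`, `ranked_panel.csv`, `roc_points.csv`,
#' `univariate.csv`, `rfe_trace.json`, `cv_predictions.csv` and
#' `report.json`. The report JSON contains only numbers recomputable from
#' the configuration and seed, so two runs with the same configuration
#' produce byte-identical files.
#'
#' @param report a `run_report`.
#' @param outdir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create directory: ", outdir)
  p <- function(f) file.path(outdir, f)

  writeLines(config_json(report$provenance$config), p("config.json"))
  utils::write.csv(report$qc_report, p("qc_report.csv"), row.names = FALSE)
  write_peakset_csv(report$peakset, p("peaks.csv"))
  write_features_csv(report$features, p("feature_matrix.csv"))
  utils::write.csv(report$ranked_panel, p("ranked_panel.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc, p("roc_points.csv"), row.names = FALSE)
  utils::write.csv(report$univariate, p("univariate.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cv_selected$predictions,
                   p("cv_predictions.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(sets = report$rfe$sets, sizes = report$rfe$sizes,
         cv_auc = report$rfe$cv_auc,
         selected_index = report$rfe$selected_index,
         selected_features = report$rfe$selected_features),
    p("rfe_trace.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  summary <- list(
    qc = report$qc_summary,
    n_peaks = report$n_peaks,
    cv_full = cv_summary_list(report$cv_full),
    rfe = list(sizes = report$rfe$sizes, cv_auc = report$rfe$cv_auc,
               selected_size = length(report$rfe$selected_features)),
    cv_selected = cv_summary_list(report$cv_selected),
    cv_nested = cv_summary_list(report$cv_nested),
    ranked_panel = report$ranked_panel,
    univariate = report$univariate,
    truth_recovery = report$truth_recovery,
    provenance = list(
      package = report$provenance$package,
      version = report$provenance$version,
      seed = report$provenance$seed,
      config_hash = report$provenance$config_hash
    )
  )
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(vapply(
    c("config.json", "qc_report.csv", "peaks.csv", "feature_matrix.csv",
      "ranked_panel.csv", "roc_points.csv", "univariate.csv",
      "cv_predictions.csv", "rfe_trace.json", "report.json"),
    p, character(1)
  ))
}
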