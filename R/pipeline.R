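#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()]: cohort
#' parameters (5 experts + 5 novices, 2 min baseline and 10 min task
#' segments at 500 Hz, the default class parameter sets), windowing
#' (10 s / 5 s overlap for ECG, 30 s / 10 s for GSR), LASSO selection
#' (cross-validated penalty, threshold 0.01), the four classifier kinds,
#' the aggregation mode, and the t-SNE settings.
#'
#' @param seed Master seed recorded in the config.
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 42) {
  structure(
    list(
      seed = seed,
      cohort = list(
        n_expert = 5, n_novice = 5,
        expert = unclass(expert_params_default()),
        novice = unclass(novice_params_default()),
        baseline_duration = 120, task_duration = 600, fs = 500,
        ecg_noise = list(
          baseline_wander_amp = 0.1, powerline_amp = 0.05,
          broadband_sd = 0.05
        ),
        gsr_noise_sd = 0.02, gsr_drift_amp = 0.3, jitter = 0.03
      ),
      windows = list(
        ecg_window = 10, ecg_overlap = 5,
        gsr_window = 30, gsr_overlap = 10
      ),
      lasso = list(penalty = "cv", threshold = 0.01),
      classifiers = c("svm", "dt", "rf", "knn"),
      aggregation = "mean-over-folds",
      modalities = c("ecg", "gsr", "multimodal"),
      tsne = list(perplexity = 30, max_iter = 10000, eta = 10)
    ),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Checks structure and invariants (positive durations, overlap smaller
#' than window, known classifier kinds and aggregation mode) before any
#' compute is started. Unknown top-level keys are rejected so typos fail
#' fast.
#'
#' @param config A configuration list, or a path to a YAML file holding one.
#' @return The validated config list, invisibly classed `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  template <- default_config()
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
      class = "physioload_config_error"
    )
  }
  config <- modifyList(unclass(template), config)
  w <- config$windows
  if (w$ecg_overlap >= w$ecg_window || w$gsr_overlap >= w$gsr_window) {
    abort("Window overlap must be smaller than the window length.",
      class = "physioload_config_error"
    )
  }
  ch <- config$cohort
  if (ch$baseline_duration <= 0 || ch$task_duration <= 0 || ch$fs <= 0) {
    abort("Durations and sampling rate must be positive.",
      class = "physioload_config_error"
    )
  }
  if (ch$baseline_duration < w$gsr_window) {
    abort("Baseline must be at least one GSR window long.",
      class = "physioload_config_error"
    )
  }
  bad <- setdiff(config$classifiers, c("svm", "dt", "rf", "knn"))
  if (length(bad)) {
    abort(paste0("Unknown classifier kind(s): ", paste(bad, collapse = ", ")),
      class = "physioload_config_error"
    )
  }
  if (!config$aggregation %in% c("mean-over-folds", "pooled-windows")) {
    abort("`aggregation` must be \"mean-over-folds\" or \"pooled-windows\".",
      class = "physioload_config_error"
    )
  }
  bad_m <- setdiff(config$modalities, c("ecg", "gsr", "multimodal"))
  if (length(bad_m)) {
    abort(paste0("Unknown modality: ", paste(bad_m, collapse = ", ")),
      class = "physioload_config_error"
    )
  }
  class(config) <- "pipeline_config"
  invisible(config)
}

#' Run the full simulate-to-report pipeline
#'
#' Executes the analysis chain end to end: cohort simulation, ECG/GSR
#' preprocessing and feature extraction, baseline normalization, matrix
#' assembly per modality, LASSO feature selection, LOSO evaluation of every
#' configured classifier on every modality, and the t-SNE projection of the
#' multimodal matrix. All intermediate CSVs, the ranking, a JSON report, a
#' classifier-by-modality summary CSV and a stage log are written to
#' `out_dir`. Rerunning with the same config and seed reproduces identical
#' outputs.
#'
#' @param config A config list (see [default_config()]) or YAML path;
#'   validated before any compute.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of `config$seed`.
#' @return A list with `summary` (tibble: modality x classifier accuracy/F1),
#'   `reports`, `rankings`, `matrices`, `embedding`, `config` and the output
#'   paths, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  log_stage <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  log_stage("simulate: %d expert + %d novice subjects", config$cohort$n_expert, config$cohort$n_novice)
  ch <- config$cohort
  cohort <- generate_cohort(
    n_expert = ch$n_expert, n_novice = ch$n_novice,
    expert_params = do.call(class_params, ch$expert),
    novice_params = do.call(class_params, ch$novice),
    seed = config$seed,
    baseline_duration = ch$baseline_duration, task_duration = ch$task_duration,
    fs = ch$fs, ecg_noise = ch$ecg_noise,
    gsr_noise_sd = ch$gsr_noise_sd, gsr_drift_amp = ch$gsr_drift_amp,
    jitter = ch$jitter
  )
  write_cohort(cohort, file.path(out_dir, "cohort"))

  log_stage("features: windows ecg %g/%g s, gsr %g/%g s", config$windows$ecg_window,
    config$windows$ecg_overlap, config$windows$gsr_window, config$windows$gsr_overlap)
  features <- extract_features(cohort,
    fs = ch$fs,
    ecg_window = config$windows$ecg_window, ecg_overlap = config$windows$ecg_overlap,
    gsr_window = config$windows$gsr_window, gsr_overlap = config$windows$gsr_overlap
  )

  matrices <- list()
  rankings <- list()
  reports <- list()
  summary_rows <- list()
  for (mod in config$modalities) {
    mat <- assemble_matrix(features, mod)
    matrices[[mod]] <- mat
    write_feature_matrix(mat, file.path(out_dir, paste0("features_", mod, ".csv")))
    log_stage("matrix %s: %d rows, %d features", mod, nrow(mat), length(feature_columns(mat)))

    ranking <- lasso_rank(mat, penalty = config$lasso$penalty, seed = config$seed)
    rankings[[mod]] <- ranking
    write_ranking(ranking, file.path(out_dir, paste0("ranking_", mod, ".csv")),
      threshold = config$lasso$threshold
    )
    selected <- withCallingHandlers(
      apply_threshold(ranking, config$lasso$threshold),
      warning = function(w) {
        if (inherits(w, "physioload_empty_selection")) {
          invokeRestart("muffleWarning")
        }
      }
    )
    if (length(selected) == 0L) {
      log_stage("select %s: empty selection, falling back to all features", mod)
      selected <- ranking$feature
    } else {
      log_stage("select %s: %d features above %.3g", mod, length(selected), config$lasso$threshold)
    }

    for (kind in config$classifiers) {
      rep <- run_experiment(mat,
        spec = classifier_spec(kind),
        aggregation = config$aggregation,
        features = selected, seed = config$seed
      )
      reports[[paste(mod, kind, sep = "_")]] <- rep
      agg <- rep$aggregate[rep$aggregate$aggregation == config$aggregation, ]
      summary_rows[[length(summary_rows) + 1L]] <- tibble(
        modality = mod, classifier = kind,
        accuracy = agg$accuracy, f1 = agg$f1
      )
      log_stage("classify %s/%s: accuracy %.4f, F1 %.4f", mod, kind, agg$accuracy, agg$f1)
    }
  }
  summary <- bind_rows(summary_rows)
  wide <- tidyr::pivot_wider(summary,
    names_from = "classifier",
    values_from = c("accuracy", "f1")
  )
  readr::write_csv(wide, file.path(out_dir, "classification_summary.csv"))
  write_report(reports, file.path(out_dir, "report.json"))

  embedding <- NULL
  if ("multimodal" %in% names(matrices)) {
    log_stage("embed: t-SNE perplexity %g, %d iterations", config$tsne$perplexity,
      config$tsne$max_iter)
    embedding <- suppressWarnings(tsne_embed(matrices$multimodal,
      perplexity = config$tsne$perplexity, max_iter = config$tsne$max_iter,
      eta = config$tsne$eta, seed = config$seed
    ))
    write_embedding(embedding, file.path(out_dir, "embedding_multimodal.csv"))
    log_stage("embed: silhouette %.3f", attr(embedding, "silhouette"))
  }

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  writeLines(log_lines, log_path)
  invisible(list(
    summary = summary, reports = reports, rankings = rankings,
    matrices = matrices, embedding = embedding, config = config,
    out_dir = out_dir
  ))
}
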