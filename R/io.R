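# CSV readers/writers for signals, ground truth, features and reports.

#' Read a signal CSV
#'
#' Expects the two-column `t_seconds,value` layout written by
#' [write_cohort()].
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `t_seconds` and `value`.
#' @export
read_signal_csv <- function(path) {
  out <- readr::read_csv(path,
    col_types = readr::cols(
      t_seconds = readr::col_double(),
      value = readr::col_double()
    )
  )
  if (!all(c("t_seconds", "value") %in% names(out))) {
    stop_invalid("Signal CSV must have columns `t_seconds` and `value`.")
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes one `t_seconds,value` CSV per subject and segment, one ground
#' truth CSV per subject (`kind,time_seconds,extra`, with R-peak and SCR
#' event times per segment), and a cohort manifest CSV listing the files.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    sid <- cohort$subject_id[i]
    files <- c(
      ecg_baseline = file.path(dir, paste0(sid, "_ecg_baseline.csv")),
      ecg_task = file.path(dir, paste0(sid, "_ecg_task.csv")),
      gsr_baseline = file.path(dir, paste0(sid, "_gsr_baseline.csv")),
      gsr_task = file.path(dir, paste0(sid, "_gsr_task.csv"))
    )
    for (nm in names(files)) {
      readr::write_csv(cohort[[nm]][[i]], files[[nm]])
    }
    truth <- cohort$truth[[i]]
    gt <- bind_rows(
      tibble(kind = "r_peak", time_seconds = truth$r_peaks_baseline, extra = "baseline"),
      tibble(kind = "r_peak", time_seconds = truth$r_peaks_task, extra = "task"),
      tibble(kind = "scr_event", time_seconds = truth$scr_baseline, extra = "baseline"),
      tibble(kind = "scr_event", time_seconds = truth$scr_task, extra = "task")
    )
    gt_path <- file.path(dir, paste0(sid, "_truth.csv"))
    readr::write_csv(gt, gt_path)
    tibble(
      subject_id = sid, label = cohort$label[i],
      ecg_baseline = files[["ecg_baseline"]], ecg_task = files[["ecg_task"]],
      gsr_baseline = files[["gsr_baseline"]], gsr_task = files[["gsr_task"]],
      truth = gt_path
    )
  })
  manifest <- bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Write/read a feature matrix CSV
#'
#' @param matrix A [assemble_matrix()] tibble.
#' @param path Output CSV path.
#' @return The input, invisibly (`write`) or the matrix tibble (`read`).
#' @export
write_feature_matrix <- function(matrix, path) {
  readr::write_csv(matrix, path)
  invisible(matrix)
}

#' @rdname write_feature_matrix
#' @param modality Modality recorded on the object read back.
#' @export
read_feature_matrix <- function(path, modality = "multimodal") {
  out <- readr::read_csv(path, col_types = readr::cols())
  attr(out, "modality") <- modality
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Write a LASSO ranking CSV
#'
#' Columns `feature,coefficient,abs_coefficient,selected`.
#'
#' @param ranking A [lasso_rank()] tibble.
#' @param path Output CSV path.
#' @param threshold Selection threshold used for the `selected` column.
#' @export
write_ranking <- function(ranking, path, threshold = 0.01) {
  out <- as_tibble(ranking)
  out$selected <- out$abs_coefficient > threshold
  readr::write_csv(out, path)
  invisible(out)
}

#' Write an evaluation report as JSON
#'
#' @param report An [run_experiment()] result (or a list of them).
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  serialize_one <- function(r) {
    list(
      classifier = r$spec$kind,
      hyperparameters = unclass(r$spec),
      aggregation = r$aggregation,
      n_rows = r$n_rows,
      positive = r$positive,
      seed = r$seed,
      config_hash = r$config_hash,
      per_fold = r$per_fold,
      aggregate = r$aggregate
    )
  }
  payload <- if (inherits(report, "evaluation_report")) {
    serialize_one(report)
  } else {
    lapply(report, serialize_one)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a t-SNE embedding CSV
#'
#' Columns `dim1,dim2,subject_id,label`.
#'
#' @param embedding A [tsne_embed()] tibble.
#' @param path Output CSV path.
#' @export
write_embedding <- function(embedding, path) {
  readr::write_csv(as_tibble(embedding), path)
  invisible(embedding)
}
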