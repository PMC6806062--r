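# Shared fixtures and scoring helpers for the test suite.

# Sensitivity / positive predictivity of detected event times against
# ground truth, with a symmetric matching window (seconds).
match_stats <- function(detected, truth, window) {
  if (length(truth) == 0L) {
    return(c(sensitivity = NA_real_, ppv = NA_real_))
  }
  tp <- sum(vapply(truth, function(t) any(abs(detected - t) <= window), logical(1)))
  fp <- if (length(detected)) {
    sum(vapply(detected, function(t) !any(abs(truth - t) <= window), logical(1)))
  } else {
    0L
  }
  c(
    sensitivity = tp / length(truth),
    ppv = if (length(detected)) (length(detected) - fp) / length(detected) else 0
  )
}

# A strictly periodic RR pattern (period 5 s, 10 beats) so that every 10 s
# window with 5 s step sees the identical interval sequence; used for the
# baseline-equals-task normalization fixture.
periodic_rr <- function(n_blocks = 24) {
  block <- 0.5 + c(0.04, -0.04, 0.03, -0.03, 0.02, -0.02, 0.06, -0.06, 0, 0)
  stopifnot(abs(sum(block) - 5) < 1e-12)
  rep(block, n_blocks)
}

# Small two-class cohort used by several tests; built once per run.
small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(small_cohort_cache$cohort)) {
    small_cohort_cache$cohort <- generate_cohort(
      n_expert = 2, n_novice = 2, seed = 11,
      baseline_duration = 60, task_duration = 180, fs = 500
    )
  }
  small_cohort_cache$cohort
}

small_features <- function() {
  if (is.null(small_cohort_cache$features)) {
    small_cohort_cache$features <-
      suppressMessages(extract_features(small_cohort()))
  }
  small_cohort_cache$features
}

# Two well-separated Gaussian blobs as a feature matrix (one subject per
# blob half, so LOSO folds exist).
blob_matrix <- function(n_per_subject = 50, gap = 5, seed = 5) {
  withr::with_seed(seed, {
    mk <- function(mu, lab, sid) {
      tibble::tibble(
        subject_id = sid, label = lab,
        f1 = stats::rnorm(n_per_subject, mu), f2 = stats::rnorm(n_per_subject, mu),
        f3 = stats::rnorm(n_per_subject, mu)
      )
    }
    dplyr::bind_rows(
      mk(0, "novice", "n1"), mk(0, "novice", "n2"),
      mk(gap, "expert", "e1"), mk(gap, "expert", "e2")
    )
  })
}
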