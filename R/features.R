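#' Segment a recording into overlapping windows
#'
#' Windows start at multiples of `window - overlap` and must lie entirely
#' inside `[0, duration]`, giving
#' `floor((duration - window) / (window - overlap)) + 1` windows.
#' The defaults used downstream are 10 s windows with 5 s overlap for ECG
#' and 30 s windows with 10 s overlap for GSR.
#'
#' @param duration Segment duration in seconds.
#' @param window Window length in seconds.
#' @param overlap Overlap between successive windows in seconds
#'   (`0 <= overlap < window <= duration`).
#' @return A tibble with columns `window_id`, `start`, `end`.
#' @examples
#' nrow(segment_windows(600, 10, 5)) # 119
#' nrow(segment_windows(600, 30, 10)) # 29
#' @export
segment_windows <- function(duration, window, overlap) {
  if (overlap >= window) stop_invalid("`overlap` must be smaller than `window`.")
  if (overlap < 0) stop_invalid("`overlap` must be >= 0.")
  if (window > duration) stop_invalid("`window` must not exceed `duration`.")
  step <- window - overlap
  k <- floor((duration - window) / step + 1e-9)
  starts <- (0:k) * step
  tibble(window_id = seq_along(starts), start = starts, end = starts + window)
}

ecg_feature_names <- function() {
  c(
    "RR_min", "RR_max", "RR_diff", "RR_mean", "RR_SD", "RR_CV",
    "SDSD", "NN50", "PNN50",
    "ULF", "VLF", "LF", "HF", "TP", "LF_norm", "HF_norm", "LF_HF", "LMHF"
  )
}

gsr_feature_names <- function() {
  event_stats <- as.vector(outer(
    c("RT", "HRT", "Amp", "Area", "Prom"),
    c("mean", "min", "max", "SD"),
    paste,
    sep = "_"
  ))
  c(event_stats, "SCL", "MAV1Diff_SCL", "MAV2Diff_SCL", "BP", "PSD")
}

na_features <- function(names) {
  setNames(as.list(rep(NA_real_, length(names))), names)
}

#' Time-domain HRV features of one RR window
#'
#' Computes the nine time-domain descriptors of a window of RR intervals:
#' minimum, maximum, range, mean, standard deviation, coefficient of
#' variation, the SD of successive differences (SDSD), NN50 (number of
#' successive differences exceeding 50 ms) and pNN50 (NN50 as a percentage
#' of the number of successive differences).
#'
#' @param rr Numeric vector of (unflagged) RR intervals in seconds.
#' @return A named list of 9 values; all `NA` when fewer than 3 intervals
#'   are available (the window is marked missing, not an error).
#' @examples
#' ecg_time_features(c(0.80, 0.86, 0.90, 0.91))
#' @export
ecg_time_features <- function(rr) {
  names9 <- ecg_feature_names()[1:9]
  rr <- rr[is.finite(rr)]
  n <- length(rr)
  if (n < 3L) {
    return(na_features(names9))
  }
  d <- diff(rr)
  nn50 <- sum(abs(d) > 0.050)
  m <- mean(rr)
  s <- sd(rr)
  list(
    RR_min = min(rr), RR_max = max(rr), RR_diff = max(rr) - min(rr),
    RR_mean = m, RR_SD = s, RR_CV = s / m,
    SDSD = if (length(d) > 1L) sd(d) else 0,
    NN50 = nn50, PNN50 = 100 * nn50 / length(d)
  )
}

hrv_bands <- function() {
  list(
    ULF = c(0.0, 0.003), VLF = c(0.003, 0.04),
    LF = c(0.04, 0.15), HF = c(0.15, 0.4), TP = c(0.0, 0.4),
    MF = c(0.08, 0.15)
  )
}

#' HRV band powers from the Lomb periodogram of an RR tachogram
#'
#' Evaluates the Lomb-Scargle periodogram of the unevenly sampled RR series
#' on a fixed frequency grid (0.001-0.4 Hz, step 0.001 by default) and
#' integrates it with the trapezoidal rule over the standard HRV bands:
#' ULF below 0.003 Hz, VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz
#' and total power 0-0.4 Hz. A constant series yields zero power in every
#' band.
#'
#' @param rr_times Beat times in seconds (strictly increasing).
#' @param rr_values RR intervals in seconds (same length).
#' @param grid Frequency grid in Hz.
#' @return Named list with `ULF`, `VLF`, `LF`, `HF`, `TP` (s^2); all `NA`
#'   when fewer than 4 points are available.
#' @examples
#' t <- cumsum(rep(0.8, 64))
#' lomb_band_powers(t, 0.8 + 0.05 * sin(2 * pi * 0.1 * t))
#' @export
lomb_band_powers <- function(rr_times, rr_values,
                             grid = seq(0.001, 0.4, by = 0.001)) {
  nm <- c("ULF", "VLF", "LF", "HF", "TP")
  if (length(rr_times) < 4L) {
    return(na_features(nm))
  }
  if (var(rr_values) < 1e-18) {
    return(setNames(as.list(rep(0, 5)), nm))
  }
  pg <- lomb_periodogram(rr_times, rr_values, grid)
  bands <- hrv_bands()
  out <- lapply(bands[nm], function(b) {
    sel <- pg$frequency >= b[1] - 1e-12 & pg$frequency <= b[2] + 1e-12
    if (sum(sel) < 2L) {
      return(0)
    }
    trapz_(pg$frequency[sel], pg$power[sel])
  })
  out
}

#' Frequency-domain HRV features of one RR window
#'
#' Band powers from [lomb_band_powers()] plus the derived ratios:
#' normalized LF and HF (`100 * LF / (LF + HF)` and its complement), the
#' LF/HF ratio, and the sympathovagal balance `LMHF = (LF + MF) / HF` with
#' the mid-frequency band MF = 0.08-0.15 Hz. Ratios are marked missing when
#' HF is zero.
#'
#' @inheritParams lomb_band_powers
#' @return Named list with `ULF`, `VLF`, `LF`, `HF`, `TP`, `LF_norm`,
#'   `HF_norm`, `LF_HF`, `LMHF`.
#' @export
ecg_freq_features <- function(rr_times, rr_values,
                              grid = seq(0.001, 0.4, by = 0.001)) {
  nm <- ecg_feature_names()[10:18]
  if (length(rr_times) < 4L) {
    return(na_features(nm))
  }
  degenerate <- var(rr_values) < 1e-18
  pg <- if (degenerate) NULL else lomb_periodogram(rr_times, rr_values, grid)
  band <- function(b) {
    if (degenerate) {
      return(0)
    }
    sel <- pg$frequency >= b[1] - 1e-12 & pg$frequency <= b[2] + 1e-12
    if (sum(sel) < 2L) {
      return(0)
    }
    trapz_(pg$frequency[sel], pg$power[sel])
  }
  bands <- hrv_bands()
  bp <- list(
    ULF = band(bands$ULF), VLF = band(bands$VLF), LF = band(bands$LF),
    HF = band(bands$HF), TP = band(bands$TP)
  )
  mf <- band(bands$MF)
  lf <- bp$LF
  hf <- bp$HF
  denom <- lf + hf
  list(
    ULF = bp$ULF, VLF = bp$VLF, LF = lf, HF = hf, TP = bp$TP,
    LF_norm = if (denom > 0) 100 * lf / denom else NA_real_,
    HF_norm = if (denom > 0) 100 * hf / denom else NA_real_,
    LF_HF = if (hf > 0) lf / hf else NA_real_,
    LMHF = if (hf > 0) (lf + mf) / hf else NA_real_
  )
}

# Welch PSD estimate: Hann-windowed overlapping segments, one-sided density.
welch_psd <- function(x, fs, seg_seconds = 10, overlap_frac = 0.5) {
  n <- length(x)
  nseg <- min(n, round(seg_seconds * fs))
  step <- max(1L, floor(nseg * (1 - overlap_frac)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  u <- sum(win^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg))^2 / (u * fs)
    half <- sp[seq_len(nf)]
    half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    acc <- acc + half
  }
  tibble(
    frequency = (seq_len(nf) - 1) * fs / nseg,
    power = acc / length(starts)
  )
}

#' Electrodermal features of one GSR window
#'
#' Aggregates the per-event SCR descriptors (rise time RT, half recovery
#' time HRT, amplitude, area, prominence) over the events whose peak lies in
#' the window, by mean/min/max/SD (SD is 0 for a single event; censored HRT
#' values are excluded from the HRT aggregates). Adds the tonic and signal
#' summaries: SCL (window mean), mean absolute first and second difference
#' of the samples, band power in 0.01-1 Hz (Welch estimate) and the total
#' periodogram power over 0-1 Hz. Prominence is recomputed relative to the
#' window SCL. Windows without any SCR event have the event aggregates
#' marked missing.
#'
#' @param samples Filtered GSR samples of the window (the smoothed `value`
#'   column of [filter_gsr()] output).
#' @param events The [detect_scr_events()] tibble for the whole segment.
#' @param fs Sampling rate in Hz.
#' @param window_start Start time of the window in seconds (so event peak
#'   times can be matched against it).
#' @param window_end End time of the window in seconds.
#' @return Named list of 25 values.
#' @export
gsr_window_features <- function(samples, events, fs,
                                window_start = 0,
                                window_end = window_start + length(samples) / fs) {
  scl <- mean(samples)
  mav1 <- if (length(samples) > 1L) mean(abs(diff(samples))) else 0
  mav2 <- if (length(samples) > 2L) mean(abs(diff(samples, differences = 2))) else 0
  psd <- welch_psd(samples, fs)
  in_band <- function(lo, hi) {
    sel <- psd$frequency >= lo & psd$frequency <= hi
    if (sum(sel) < 2L) {
      return(0)
    }
    trapz_(psd$frequency[sel], psd$power[sel])
  }
  out <- c(
    na_features(gsr_feature_names()[1:20]),
    list(
      SCL = scl, MAV1Diff_SCL = mav1, MAV2Diff_SCL = mav2,
      BP = in_band(0.01, 1), PSD = in_band(0, 1)
    )
  )
  ev <- events[events$peak_t >= window_start & events$peak_t < window_end, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(out)
  }
  agg <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      return(list(mean = NA_real_, min = NA_real_, max = NA_real_, SD = NA_real_))
    }
    list(
      mean = mean(v), min = min(v), max = max(v),
      SD = if (length(v) > 1L) sd(v) else 0
    )
  }
  prom_window <- ev$peak_value - scl
  vals <- list(
    RT = agg(ev$rt), HRT = agg(ev$hrt[!ev$censored]),
    Amp = agg(ev$amp), Area = agg(ev$area), Prom = agg(prom_window)
  )
  for (feat in names(vals)) {
    for (stat in c("mean", "min", "max", "SD")) {
      out[[paste(feat, stat, sep = "_")]] <- vals[[feat]][[stat]]
    }
  }
  out
}

#' Baseline-ratio normalization of feature vectors
#'
#' Divides each task feature by the subject's corresponding baseline
#' feature. Baseline entries with magnitude below `eps` give missing-marked
#' ratios rather than infinities.
#'
#' @param task_fv A tibble of task-window feature rows (feature columns
#'   plus any metadata columns, which are passed through).
#' @param baseline_fv A named numeric vector (or single-row data frame) of
#'   the subject's aggregated baseline features.
#' @param eps Magnitude below which a baseline feature is treated as zero.
#' @return `task_fv` with each feature column divided by its baseline value.
#' @examples
#' task <- tibble::tibble(RR_mean = 0.9)
#' baseline_normalize(task, c(RR_mean = 0.75))
#' @export
baseline_normalize <- function(task_fv, baseline_fv, eps = 1e-9) {
  if (is.data.frame(baseline_fv)) {
    baseline_fv <- unlist(baseline_fv[1, , drop = TRUE])
  }
  feats <- intersect(names(task_fv), names(baseline_fv))
  if (length(feats) == 0L) {
    abort("No shared feature names between task and baseline vectors.",
      class = "physioload_schema_error"
    )
  }
  missing_in_baseline <- setdiff(feature_columns(task_fv), names(baseline_fv))
  if (length(missing_in_baseline)) {
    abort(
      paste0(
        "Task features missing from baseline vector: ",
        paste(missing_in_baseline, collapse = ", ")
      ),
      class = "physioload_schema_error"
    )
  }
  out <- task_fv
  for (f in feats) {
    b <- baseline_fv[[f]]
    out[[f]] <- if (!is.finite(b) || abs(b) < eps) {
      NA_real_
    } else {
      task_fv[[f]] / b
    }
  }
  out
}

# Features of every ECG window of one segment.
ecg_segment_features <- function(signal, fs, window = 10, overlap = 5) {
  duration <- nrow(signal) / fs
  rr <- process_ecg(signal, fs)
  rr_ok <- rr[!rr$flagged, , drop = FALSE]
  wins <- segment_windows(duration, window, overlap)
  rows <- purrr::pmap(wins, function(window_id, start, end) {
    sel <- rr_ok$t_seconds > start & rr_ok$t_seconds <= end
    vals <- rr_ok$rr_seconds[sel]
    tms <- rr_ok$t_seconds[sel]
    feats <- c(
      ecg_time_features(vals),
      if (length(vals) >= 4L) {
        ecg_freq_features(tms, vals)
      } else {
        na_features(ecg_feature_names()[10:18])
      }
    )
    as_tibble(c(list(window_id = window_id, start = start, end = end), feats))
  })
  bind_rows(rows)
}

# Features of every GSR window of one segment; the segment's detected
# events ride along as the "events" attribute.
gsr_segment_features <- function(signal, fs, window = 30, overlap = 10) {
  duration <- nrow(signal) / fs
  filt <- filter_gsr(signal, fs)
  events <- detect_scr_events(filt, fs)
  wins <- segment_windows(duration, window, overlap)
  rows <- purrr::pmap(wins, function(window_id, start, end) {
    i0 <- floor(start * fs) + 1L
    i1 <- min(nrow(filt), round(end * fs))
    feats <- gsr_window_features(
      filt$value[i0:i1], events, fs,
      window_start = start, window_end = end
    )
    as_tibble(c(list(window_id = window_id, start = start, end = end), feats))
  })
  out <- bind_rows(rows)
  attr(out, "events") <- events
  out
}

aggregate_baseline <- function(baseline_windows) {
  feats <- setdiff(names(baseline_windows), c("window_id", "start", "end"))
  v <- vapply(feats, function(f) {
    x <- baseline_windows[[f]]
    x <- x[is.finite(x)]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  setNames(v, feats)
}

# Baseline vector for GSR: signal-level features are averaged over the
# baseline windows, but the per-event aggregates (mean/min/max/SD of RT,
# HRT, Amp, Area, Prom) are computed from the POOLED baseline events. A
# 2 min baseline holds only a handful of SCRs, so most windows see a single
# event, whose within-window SD is the degenerate 0 -- useless as a ratio
# denominator; the pooled events give the natural subject-level baseline.
aggregate_baseline_gsr <- function(baseline_windows) {
  v <- aggregate_baseline(baseline_windows)
  events <- attr(baseline_windows, "events")
  if (!is.null(events) && nrow(events) > 0) {
    agg <- function(x) {
      x <- x[is.finite(x)]
      if (length(x) == 0L) {
        return(c(mean = NA_real_, min = NA_real_, max = NA_real_, SD = NA_real_))
      }
      c(
        mean = mean(x), min = min(x), max = max(x),
        SD = if (length(x) > 1L) sd(x) else 0
      )
    }
    pooled <- list(
      RT = agg(events$rt), HRT = agg(events$hrt[!events$censored]),
      Amp = agg(events$amp), Area = agg(events$area), Prom = agg(events$prom)
    )
    for (feat in names(pooled)) {
      for (stat in c("mean", "min", "max", "SD")) {
        v[[paste(feat, stat, sep = "_")]] <- pooled[[feat]][[stat]]
      }
    }
  }
  v
}

#' Extract normalized window features for a whole cohort
#'
#' For each subject, processes the baseline and task segments of both
#' modalities: ECG segments are windowed into 10 s windows with 5 s overlap
#' and summarized by the 18 HRV features; GSR segments into 30 s windows
#' with 10 s overlap and 25 electrodermal features. Baseline windows are
#' aggregated into one baseline vector per subject and modality (mean over
#' windows, ignoring missing windows), and task-window features are divided
#' by it ([baseline_normalize()]).
#'
#' @param cohort A [generate_cohort()] tibble, or any tibble with the same
#'   columns (`subject_id`, `label`, and list-columns `ecg_baseline`,
#'   `ecg_task`, `gsr_baseline`, `gsr_task`).
#' @param fs Sampling rate in Hz; defaults to the cohort's `fs` attribute.
#' @param ecg_window,ecg_overlap,gsr_window,gsr_overlap Windowing
#'   parameters in seconds.
#' @param normalize Divide task features by the aggregated baseline vector
#'   (default `TRUE`).
#' @return A list of class `physio_features` with elements `ecg` and `gsr`,
#'   each a tibble of per-window feature rows with `subject_id`, `label`,
#'   `window_id`, `start`, `end` and the feature columns.
#' @export
extract_features <- function(cohort, fs = attr(cohort, "fs"),
                             ecg_window = 10, ecg_overlap = 5,
                             gsr_window = 30, gsr_overlap = 10,
                             normalize = TRUE) {
  if (is.null(fs)) stop_invalid("`fs` is required when the cohort carries no fs attribute.")
  per_subject <- purrr::map(seq_len(nrow(cohort)), function(i) {
    sid <- cohort$subject_id[i]
    lab <- cohort$label[i]
    ecg_base <- ecg_segment_features(cohort$ecg_baseline[[i]], fs, ecg_window, ecg_overlap)
    ecg_task <- ecg_segment_features(cohort$ecg_task[[i]], fs, ecg_window, ecg_overlap)
    gsr_base <- gsr_segment_features(cohort$gsr_baseline[[i]], fs, gsr_window, gsr_overlap)
    gsr_task <- gsr_segment_features(cohort$gsr_task[[i]], fs, gsr_window, gsr_overlap)
    if (normalize) {
      ecg_task <- baseline_normalize(ecg_task, aggregate_baseline(ecg_base))
      gsr_task <- baseline_normalize(gsr_task, aggregate_baseline_gsr(gsr_base))
    }
    meta <- function(df) {
      bind_cols(tibble(subject_id = sid, label = lab), df)
    }
    list(ecg = meta(ecg_task), gsr = meta(gsr_task))
  })
  out <- list(
    ecg = bind_rows(purrr::map(per_subject, "ecg")),
    gsr = bind_rows(purrr::map(per_subject, "gsr"))
  )
  class(out) <- "physio_features"
  out
}

#' @export
print.physio_features <- function(x, ...) {
  cat(sprintf(
    "<physio_features> ECG: %d windows x %d features; GSR: %d windows x %d features\n",
    nrow(x$ecg), length(feature_columns(x$ecg)),
    nrow(x$gsr), length(feature_columns(x$gsr))
  ))
  invisible(x)
}

#' Assemble a feature matrix for classification
#'
#' Builds the analysis matrix for one modality, or the multimodal union.
#' ECG and GSR matrices use each modality's own windows as rows. Multimodal
#' rows anchor on the 30 s GSR windows: each is paired with the mean of the
#' ECG feature vectors whose 10 s windows overlap it in time. Rows
#' containing any missing value are dropped (never imputed) and the dropped
#' count is reported via a message.
#'
#' @param features A `physio_features` list from [extract_features()].
#' @param modality `"ecg"`, `"gsr"` or `"multimodal"`.
#' @return A tibble of class `feature_matrix` with `subject_id`, `label`,
#'   `window_id`, `start`, `end` and one column per feature; attribute
#'   `"modality"` records the choice.
#' @export
assemble_matrix <- function(features, modality = c("multimodal", "ecg", "gsr")) {
  modality <- match.arg(modality)
  base <- switch(modality,
    ecg = features$ecg,
    gsr = features$gsr,
    multimodal = {
      gsr <- features$gsr
      ecg <- features$ecg
      efeats <- feature_columns(ecg)
      rows <- purrr::map(seq_len(nrow(gsr)), function(i) {
        g <- gsr[i, , drop = FALSE]
        e <- ecg[ecg$subject_id == g$subject_id &
          ecg$start < g$end & ecg$end > g$start, efeats, drop = FALSE]
        if (nrow(e) == 0L) {
          emean <- na_features(efeats)
        } else {
          emean <- as.list(colMeans(as.matrix(e)))
        }
        bind_cols(g, as_tibble(emean))
      })
      bind_rows(rows)
    }
  )
  feats <- feature_columns(base)
  complete <- stats::complete.cases(base[, feats, drop = FALSE])
  dropped <- sum(!complete)
  if (dropped > 0) {
    inform(sprintf(
      "assemble_matrix: dropped %d of %d %s rows with missing values.",
      dropped, nrow(base), modality
    ))
  }
  out <- base[complete, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort("Feature matrix is empty after dropping incomplete rows.",
      class = "physioload_empty_matrix"
    )
  }
  attr(out, "modality") <- modality
  class(out) <- c("feature_matrix", class(out))
  out
}
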