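#' Pan-Tompkins filter chain for ECG
#'
#' Applies the classic QRS-enhancement pipeline: (a) zero-phase Butterworth
#' bandpass 5-15 Hz (order 3, run forward-backward so R-peak latency is not
#' shifted); (b) the 5-point derivative
#' `y(n) = (fs/8) * (2 x(n) + x(n-1) - x(n-3) - 2 x(n-4))`;
#' (c) elementwise absolute value; (d) moving-average integration over a
#' 150 ms window. The output is nonnegative and has the same length and
#' sampling rate as the input.
#'
#' @param signal A signal tibble (`t_seconds`, `value`) or numeric vector of
#'   ECG samples (mV).
#' @param fs Sampling rate in Hz (>= 100).
#' @return A tibble with columns `t_seconds`, `bandpassed` (output of stage
#'   a) and `integrated` (output of stage d).
#' @examples
#' ecg <- synthesize_ecg(rep(0.8, 10), fs = 250)
#' chain <- pt_filter_chain(ecg$signal, fs = 250)
#' @export
pt_filter_chain <- function(signal, fs) {
  x <- signal_values(signal)
  if (fs < 100) stop_invalid("`fs` must be at least 100 Hz.")
  if (length(x) < 2 * fs) {
    abort("ECG segment shorter than 2 s cannot be processed.",
      class = "physioload_too_short"
    )
  }
  if (any(!is.finite(x))) stop_invalid("ECG samples must be finite.")
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  band <- filtfilt_reflect(bf, x)
  der <- as.numeric(stats::filter(band, fs * c(2, 1, 0, -1, -2) / 8, sides = 1))
  der[is.na(der)] <- 0
  rect <- abs(der)
  integ <- moving_average_reflect(rect, round(0.15 * fs))
  tibble(
    t_seconds = (seq_along(x) - 1) / fs,
    bandpassed = band,
    integrated = pmax(integ, 0)
  )
}

#' Detect R-peaks with adaptive dual thresholds
#'
#' Scans local maxima of the integrated waveform with the classic
#' Pan-Tompkins running estimates of signal and noise peak levels,
#' maintained in parallel on both the integrated and the bandpassed
#' waveforms: `SPK <- 0.125 h + 0.875 SPK` on accepted peaks, `NPK`
#' analogously on rejected candidates, `THRESHOLD1 = NPK + 0.25 (SPK -
#' NPK)` and `THRESHOLD2 = 0.5 THRESHOLD1`. A candidate is accepted only
#' when it clears THRESHOLD1 on both waveforms (the dual test of the
#' original algorithm, which is what keeps the detector robust once the
#' rectification is an absolute value rather than a square). If no peak is
#' accepted for two seconds a search-back re-scans the gap against the
#' lower thresholds (accepting with update weight 0.25). A 200 ms
#' refractory period suppresses double detections, and each accepted peak
#' is re-localized to the highest point of the bandpassed signal within
#' +/-75 ms, so RR intervals are not biased by the integration-window lag.
#' Because all thresholds are relative, the detector is invariant to
#' global amplitude scaling.
#'
#' @param chain The tibble returned by [pt_filter_chain()] (columns
#'   `bandpassed` and `integrated`).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of R-peak times in seconds (empty for flat input).
#' @examples
#' ecg <- synthesize_ecg(rep(0.8, 20), fs = 250)
#' peaks <- pt_filter_chain(ecg$signal, 250) |> detect_r_peaks(250)
#' @export
detect_r_peaks <- function(chain, fs) {
  if (!all(c("bandpassed", "integrated") %in% names(chain))) {
    stop_invalid("`chain` must come from pt_filter_chain().")
  }
  integ <- chain$integrated
  band <- chain$bandpassed
  n <- length(integ)
  cand <- local_maxima(integ)
  cand <- cand[integ[cand] > 0]
  if (length(cand) == 0L) {
    return(numeric(0))
  }
  tt <- (cand - 1) / fs
  h <- integ[cand]
  w75 <- round(0.075 * fs)
  hb <- vapply(cand, function(i) {
    max(band[max(1L, i - w75):min(n, i + w75)])
  }, numeric(1))
  slope <- vapply(cand, function(i) {
    idx <- max(1L, i - w75):min(n - 1L, i + w75)
    max(abs(band[idx + 1L] - band[idx]))
  }, numeric(1))

  init_i <- integ[seq_len(min(n, 2 * fs))]
  init_f <- band[seq_len(min(n, 2 * fs))]
  spki <- max(init_i)
  npki <- 0.5 * mean(init_i)
  spkf <- max(init_f)
  npkf <- 0.5 * mean(abs(init_f))
  if (spki <= 0) {
    return(numeric(0))
  }
  thr <- function(spk, npk) npk + 0.25 * (spk - npk)

  refractory <- 0.2
  accepted <- integer(0)
  acc_t <- numeric(0)
  taken <- logical(length(cand))

  last_slope <- Inf
  accept <- function(j, weight) {
    taken[j] <<- TRUE
    accepted <<- c(accepted, cand[j])
    acc_t <<- c(acc_t, tt[j])
    spki <<- weight * h[j] + (1 - weight) * spki
    spkf <<- weight * hb[j] + (1 - weight) * spkf
    last_slope <<- slope[j]
  }

  for (j in seq_along(cand)) {
    last_t <- if (length(acc_t)) acc_t[length(acc_t)] else -Inf
    # search-back: two seconds without an accepted peak, lower thresholds
    if (is.finite(last_t) && tt[j] - last_t > 2) {
      gap <- which(!taken & tt > last_t + refractory & tt < tt[j] &
        h > 0.5 * thr(spki, npki) & hb > 0.5 * thr(spkf, npkf))
      if (length(gap)) {
        best <- gap[which.max(h[gap])]
        accept(best, 0.25)
        last_t <- acc_t[length(acc_t)]
      }
    }
    if (tt[j] - last_t < refractory) next
    # T-wave discrimination: a candidate soon after the last beat whose
    # steepest slope is under half the beat's is a T wave, not a QRS
    t_wave <- tt[j] - last_t < 0.36 && slope[j] < 0.5 * last_slope
    if (!t_wave && h[j] > thr(spki, npki) && hb[j] > thr(spkf, npkf)) {
      accept(j, 0.125)
    } else {
      npki <- 0.125 * h[j] + 0.875 * npki
      npkf <- 0.125 * hb[j] + 0.875 * npkf
    }
  }
  if (length(accepted) == 0L) {
    return(numeric(0))
  }

  # re-localize to the bandpassed waveform
  w <- round(0.075 * fs)
  peaks <- vapply(sort(accepted), function(i) {
    lo <- max(1L, i - w)
    hi <- min(n, i + w)
    lo + which.max(band[lo:hi]) - 1L
  }, numeric(1))
  peaks <- sort(unique(peaks))
  # close-pair arbitration inside the 360 ms T-wave zone: of two accepted
  # peaks closer than that, keep the one with the larger bandpassed apex
  repeat {
    if (length(peaks) < 2L) break
    gaps <- diff(peaks) / fs
    bad <- which(gaps < 0.36)
    if (length(bad) == 0L) break
    i <- bad[1]
    drop <- if (band[peaks[i]] >= band[peaks[i + 1L]]) i + 1L else i
    peaks <- peaks[-drop]
  }
  (peaks - 1) / fs
}

#' Compute RR intervals from R-peak times
#'
#' Successive differences of the R-peak times. Intervals outside the
#' physiologically plausible 0.3-2.0 s range are retained but flagged so
#' that downstream feature windows can exclude them.
#'
#' @param r_peak_times Sorted numeric vector of R-peak times (seconds),
#'   at least 2 long.
#' @return A tibble with columns `t_seconds` (time of the interval's closing
#'   peak), `rr_seconds` and `flagged`.
#' @examples
#' compute_rr(c(1.0, 1.8, 2.6))
#' @export
compute_rr <- function(r_peak_times) {
  if (length(r_peak_times) < 2L) {
    abort("Need at least two R-peaks to form RR intervals.",
      class = "physioload_insufficient_peaks"
    )
  }
  rr <- diff(r_peak_times)
  tibble(
    t_seconds = r_peak_times[-1],
    rr_seconds = rr,
    flagged = rr < 0.3 | rr > 2.0
  )
}

#' Full ECG preprocessing: filter chain, peak detection, RR intervals
#'
#' @param signal A signal tibble or numeric vector of ECG samples.
#' @param fs Sampling rate in Hz.
#' @return The RR tibble from [compute_rr()].
#' @export
process_ecg <- function(signal, fs) {
  chain <- pt_filter_chain(signal, fs)
  peaks <- detect_r_peaks(chain, fs)
  compute_rr(peaks)
}
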