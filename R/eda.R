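#' Filter a GSR signal
#'
#' Two-stage smoothing: a zero-phase Butterworth low-pass at 1 Hz (order 2,
#' forward-backward) followed by a centered moving average of `2 s * fs`
#' samples (exactly 1000 samples at the nominal 500 Hz) with reflect padding,
#' so the output keeps the input length. Both stages have unit DC gain, so a
#' constant signal passes through unchanged.
#'
#' @param signal A signal tibble (`t_seconds`, `value`) or numeric vector of
#'   skin conductance samples (microsiemens).
#' @param fs Sampling rate in Hz.
#' @return A tibble with columns `t_seconds`, `lowpass` (after the 1 Hz
#'   stage) and `value` (after both stages). Event detection picks peaks on
#'   `value` and measures morphology on `lowpass`.
#' @examples
#' gsr <- synthesize_gsr(tibble::tibble(t_seconds = 5, amplitude = 0.5),
#'   duration = 20, fs = 50
#' )
#' filt <- filter_gsr(gsr$signal, fs = 50)
#' @export
filter_gsr <- function(signal, fs) {
  x <- signal_values(signal)
  if (length(x) < 4 * fs) {
    abort("GSR segment shorter than 4 s cannot be filtered.",
      class = "physioload_too_short"
    )
  }
  if (any(!is.finite(x))) stop_invalid("GSR samples must be finite.")
  bf <- signal::butter(2, 1 / (fs / 2), type = "low")
  low <- filtfilt_reflect(bf, x)
  smooth <- moving_average_reflect(low, round(2 * fs))
  tibble(t_seconds = (seq_along(x) - 1) / fs, lowpass = low, value = smooth)
}

#' Detect skin conductance response (SCR) events
#'
#' Peaks are picked on the moving-average-smoothed signal (`value` column):
#' each local maximum is paired with the preceding local minimum as its
#' onset. Because the 2 s moving average attenuates and widens the phasic
#' waveform, the peak and onset are then re-localized on the 1 Hz low-passed
#' signal (`lowpass` column) before morphology is measured, so amplitudes
#' and rise times are close to their unsmoothed values. Events with
#' amplitude below `min_amplitude`, or with a rise time longer than
#' `max_rise_time` (slow tonic fluctuations, not SCRs), are discarded.
#'
#' Half recovery is the first time after the peak at which the signal falls
#' to onset value plus half the amplitude; it is censored (flagged, `NA`
#' time) when the next event's onset or the end of the segment intervenes.
#' Area is the trapezoidal integral of the signal above the onset level from
#' onset to half recovery (or the censoring point).
#'
#' @param filtered Output of [filter_gsr()] (a tibble with `value` and,
#'   optionally, `lowpass`; a plain signal tibble or numeric vector is
#'   accepted and used for both roles).
#' @param fs Sampling rate in Hz.
#' @param min_amplitude Minimum peak-above-onset amplitude in microsiemens
#'   (default 0.01, suppressing numerical ripple).
#' @param max_rise_time Maximum onset-to-peak time in seconds (default 10).
#' @return A tibble of class `scr_events` with one row per event:
#'   `onset_t`, `peak_t`, `half_rec_t` (`NA` if censored), `rt`, `hrt`
#'   (`NA` if censored), `amp`, `area`, `prom`, `peak_value`, `censored`.
#' @examples
#' gsr <- synthesize_gsr(tibble::tibble(t_seconds = 10, amplitude = 0.5),
#'   duration = 40, fs = 100
#' )
#' filter_gsr(gsr$signal, 100) |> detect_scr_events(100)
#' @export
detect_scr_events <- function(filtered, fs, min_amplitude = 0.01,
                              max_rise_time = 10) {
  if (is.data.frame(filtered)) {
    x <- filtered$value
    y <- if ("lowpass" %in% names(filtered)) filtered$lowpass else filtered$value
  } else {
    x <- as.numeric(filtered)
    y <- x
  }
  n <- length(x)
  empty <- tibble(
    onset_t = numeric(0), peak_t = numeric(0), half_rec_t = numeric(0),
    rt = numeric(0), hrt = numeric(0), amp = numeric(0), area = numeric(0),
    prom = numeric(0), peak_value = numeric(0), censored = logical(0)
  )
  class(empty) <- c("scr_events", class(empty))
  peaks <- local_maxima(x)
  if (length(peaks) == 0L) {
    return(empty)
  }
  mins <- local_minima(x)
  scl_segment <- mean(x)
  reloc <- round(1.5 * fs) # search radius when moving to the lowpass signal

  dy <- c(0, diff(y))
  events <- list()
  for (p in peaks) {
    prev_min <- mins[mins < p]
    o <- if (length(prev_min)) max(prev_min) else 1L
    if (x[p] - x[o] < min_amplitude / 2) next # cheap pre-filter on smoothed

    # re-localize peak on the lowpass signal
    lo <- max(1L, p - reloc)
    hi <- min(n, p + reloc)
    p_y <- lo + which.max(y[lo:hi]) - 1L
    # onset: last point before the steepest rise where the slope is under a
    # quarter of the maximal slope. The Bateman rise starts at maximal
    # slope, so on the zero-phase-filtered signal this crossing sits at the
    # kernel's midpoint, i.e. close to the true onset; it also separates
    # the phasic rise from slow tonic drift (whose slope is far smaller)
    olo <- max(1L, p_y - round(max_rise_time * fs))
    if (p_y - olo < 2L) next
    slope_win <- max(olo, p_y - round(3 * fs)):p_y
    max_slope <- max(dy[slope_win])
    if (max_slope <= 0) next
    steep <- slope_win[which.max(dy[slope_win])]
    if (steep <= olo) next
    slow <- which(dy[olo:(steep - 1L)] <= 0.25 * max_slope)
    o_y <- if (length(slow)) olo + max(slow) - 1L else olo
    amp <- y[p_y] - y[o_y]
    rt <- (p_y - o_y) / fs
    if (amp < min_amplitude || rt <= 0 || rt > max_rise_time) next
    events[[length(events) + 1L]] <- list(o = o_y, p = p_y, amp = amp, rt = rt)
  }
  if (length(events) == 0L) {
    return(empty)
  }
  # drop duplicate re-localized peaks (several smoothed maxima can map to one)
  pk <- vapply(events, `[[`, numeric(1), "p")
  events <- events[!duplicated(pk)]
  pk <- vapply(events, `[[`, numeric(1), "p")
  ord <- order(pk)
  events <- events[ord]

  rows <- purrr::imap(events, function(ev, i) {
    limit <- min(n, if (i < length(events)) events[[i + 1L]]$o else n)
    target <- y[ev$o] + ev$amp / 2
    after <- if (ev$p + 1L > limit) integer(0) else seq(ev$p + 1L, limit)
    hit <- after[which(y[after] <= target)]
    censored <- length(hit) == 0L
    hr_idx <- if (censored) limit else hit[1]
    span <- seq(ev$o, max(ev$o, hr_idx))
    area <- trapz_((span - 1) / fs, pmax(y[span] - y[ev$o], 0))
    tibble(
      onset_t = (ev$o - 1) / fs,
      peak_t = (ev$p - 1) / fs,
      half_rec_t = if (censored) NA_real_ else (hr_idx - 1) / fs,
      rt = ev$rt,
      hrt = if (censored) NA_real_ else (hr_idx - ev$p) / fs,
      amp = ev$amp,
      area = area,
      prom = y[ev$p] - scl_segment,
      peak_value = y[ev$p],
      censored = censored
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("scr_events", class(out))
  out
}
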