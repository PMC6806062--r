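#' Class-level generator parameters for a synthetic cohort
#'
#' Bundles the physiological targets that distinguish the two classes of a
#' synthetic cohort: mean heart period and its variability, the spectral
#' balance of the RR modulation, and electrodermal activity levels. The
#' `task_shift` multiplier describes how the task segment departs from the
#' subject's own baseline: under higher cognitive load the heart period and
#' its variability drop (`mean_rr / task_shift`, `sdnn / task_shift`) while
#' sympathetic activation raises SCR rate, SCR amplitude and the LF/HF
#' balance (multiplied by `task_shift`).
#'
#' @param mean_rr Mean RR interval (s).
#' @param sdnn Marginal standard deviation of the RR intervals (s).
#' @param lf_hf_ratio Target ratio of low-frequency (0.04-0.15 Hz) to
#'   high-frequency (0.15-0.4 Hz) power of the RR modulation.
#' @param scr_rate Skin conductance response rate (events/minute).
#' @param scr_amp_mean Mean SCR amplitude (microsiemens).
#' @param scl_level Tonic skin conductance level (microsiemens).
#' @param task_shift Multiplier applied to task-segment parameters relative
#'   to baseline (dimensionless, > 0; 1 = no shift).
#' @return An object of class `class_params` (a named list).
#' @examples
#' class_params(mean_rr = 0.8, sdnn = 0.05)
#' @export
class_params <- function(mean_rr = 0.8, sdnn = 0.05, lf_hf_ratio = 2,
                         scr_rate = 4, scr_amp_mean = 0.4, scl_level = 5,
                         task_shift = 1.2) {
  if (!is.numeric(mean_rr) || mean_rr <= 0) {
    stop_invalid("`mean_rr` must be > 0.")
  }
  if (sdnn < 0) stop_invalid("`sdnn` must be >= 0.")
  if (lf_hf_ratio <= 0) stop_invalid("`lf_hf_ratio` must be > 0.")
  if (scr_rate < 0) stop_invalid("`scr_rate` must be >= 0.")
  if (scr_amp_mean < 0) stop_invalid("`scr_amp_mean` must be >= 0.")
  if (task_shift <= 0) stop_invalid("`task_shift` must be > 0.")
  structure(
    list(
      mean_rr = mean_rr, sdnn = sdnn, lf_hf_ratio = lf_hf_ratio,
      scr_rate = scr_rate, scr_amp_mean = scr_amp_mean,
      scl_level = scl_level, task_shift = task_shift
    ),
    class = "class_params"
  )
}

#' @export
print.class_params <- function(x, ...) {
  cat("<class_params>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Default expert-class generator parameters
#'
#' Experts operate under lower cognitive load: slower heart rate, higher
#' vagally mediated variability, fewer and smaller SCRs, and a milder
#' task-induced shift. The two default parameter sets are strongly separated
#' (mean RR 0.9 vs 0.7 s, SCR rate 2 vs 6 per minute).
#'
#' @return A [class_params()] object.
#' @export
expert_params_default <- function() {
  class_params(
    mean_rr = 0.9, sdnn = 0.06, lf_hf_ratio = 1.5,
    scr_rate = 2, scr_amp_mean = 0.3, scl_level = 4, task_shift = 1.1
  )
}

#' Default novice-class generator parameters
#'
#' @return A [class_params()] object.
#' @rdname expert_params_default
#' @export
novice_params_default <- function() {
  class_params(
    mean_rr = 0.7, sdnn = 0.045, lf_hf_ratio = 3,
    scr_rate = 6, scr_amp_mean = 0.5, scl_level = 6, task_shift = 1.35
  )
}

# Apply the task-segment shift to a parameter set.
shift_params <- function(params) {
  class_params(
    mean_rr = params$mean_rr / params$task_shift,
    sdnn = params$sdnn / params$task_shift,
    lf_hf_ratio = params$lf_hf_ratio * params$task_shift,
    scr_rate = params$scr_rate * params$task_shift,
    scr_amp_mean = params$scr_amp_mean * params$task_shift,
    scl_level = params$scl_level,
    task_shift = params$task_shift
  )
}

#' Generate a synthetic RR-interval series
#'
#' Draws beat-to-beat RR intervals from a mean-reverting AR(1) process
#' modulated by two sinusoids, one inside the low-frequency band
#' (0.04-0.15 Hz) and one inside the high-frequency band (0.15-0.4 Hz), whose
#' power ratio equals `lf_hf_ratio`. The marginal mean and standard deviation
#' of the intervals match `mean_rr` and `sdnn`. 85% of the variance is
#' carried by the sinusoidal modulators and 15% by the AR(1) component
#' (autocorrelation 0.2), so the band-power ratio of the resulting tachogram
#' stays close to the target.
#'
#' @param params A [class_params()] object (only the RR fields are used).
#' @param duration Segment duration in seconds (> 2 * `mean_rr`).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return A tibble with columns `t_seconds` (beat time, cumulative sum of
#'   intervals) and `rr_seconds`; the realized parameters are attached as the
#'   `"params"` attribute.
#' @examples
#' rr <- generate_rr_series(class_params(mean_rr = 0.8, sdnn = 0.05), 60, seed = 1)
#' mean(rr$rr_seconds)
#' @export
generate_rr_series <- function(params, duration, seed = NULL) {
  stopifnot(inherits(params, "class_params"))
  if (!is.numeric(duration) || duration <= 0) {
    stop_invalid("`duration` must be positive.")
  }
  if (duration <= 2 * params$mean_rr) {
    stop_invalid("`duration` must exceed two mean RR intervals.")
  }
  with_seed_(seed, {
    sin_frac <- 0.85
    phi <- 0.2
    r <- params$lf_hf_ratio
    var_total <- params$sdnn^2
    sd_ar <- sqrt((1 - sin_frac) * var_total)
    # split the sinusoidal variance so that the TOTAL band powers (sinusoids
    # plus the AR(1) floor, whose one-sided spectrum is known analytically)
    # sit at the requested LF/HF ratio
    fb <- 1 / params$mean_rr # beat rate ~ sampling rate of the tachogram
    ar_band <- function(lo, hi) {
      f <- seq(lo, hi, length.out = 200)
      dens <- sd_ar^2 * (1 - phi^2) /
        (1 + phi^2 - 2 * phi * cos(2 * pi * f / fb)) * (2 / fb)
      trapz_(f, dens)
    }
    a_lf_floor <- ar_band(0.04, 0.15)
    a_hf_floor <- ar_band(0.15, 0.4)
    p_sin <- sin_frac * var_total
    h <- max((p_sin + a_lf_floor - r * a_hf_floor) / (1 + r), 0)
    l <- p_sin - h
    a_lf <- sqrt(2 * max(l, 0))
    a_hf <- sqrt(2 * h)
    f_lf <- 0.095
    f_hf <- 0.275
    ph <- runif(2, 0, 2 * pi)

    rr <- numeric(0)
    t_now <- 0
    i <- 0
    ar <- 0
    floor_rr <- 0.25 * params$mean_rr
    repeat {
      ar <- phi * ar + sqrt(1 - phi^2) * sd_ar * rnorm(1)
      # modulators advance on the nominal beat clock; sampling them at the
      # realized beat times would frequency-modulate the series and bias
      # the beat-averaged mean below mean_rr
      t_nom <- i * params$mean_rr
      mod <- a_lf * sin(2 * pi * f_lf * t_nom + ph[1]) +
        a_hf * sin(2 * pi * f_hf * t_nom + ph[2])
      x <- max(floor_rr, params$mean_rr + mod + ar)
      if (t_now + x > duration + 1e-9) break
      rr <- c(rr, x)
      t_now <- t_now + x
      i <- i + 1
    }
    out <- tibble(t_seconds = cumsum(rr), rr_seconds = rr)
    attr(out, "params") <- params
    out
  })
}

# PQRST template: sum of Gaussians, R apex amplitude 1 mV at offset 0.
pqrst_template <- function(offsets_s) {
  waves <- list(
    c(amp = 0.12, mu = -0.20, sigma = 0.025), # P
    c(amp = -0.10, mu = -0.030, sigma = 0.010), # Q
    c(amp = 1.00, mu = 0.000, sigma = 0.010), # R
    c(amp = -0.15, mu = 0.030, sigma = 0.010), # S
    c(amp = 0.30, mu = 0.25, sigma = 0.045) # T
  )
  out <- numeric(length(offsets_s))
  for (w in waves) {
    out <- out + w[["amp"]] * exp(-((offsets_s - w[["mu"]])^2) / (2 * w[["sigma"]]^2))
  }
  out
}

#' Synthesize an ECG signal from an RR-interval series
#'
#' Places a PQRST template (sum of Gaussians, 1 mV R apex) at each cumulative
#' RR time, snapped to the sample grid, and adds three noise components:
#' sinusoidal baseline wander (0.3 Hz), a powerline sinusoid (50 or 60 Hz)
#' and white broadband noise.
#'
#' @param rr RR intervals: a numeric vector of interval lengths (s) or the
#'   tibble returned by [generate_rr_series()].
#' @param fs Sampling rate in Hz (>= 100).
#' @param duration Optional total signal duration in seconds; defaults to
#'   the sum of the RR intervals. Beats beyond the duration are dropped.
#' @param noise List with elements `baseline_wander_amp`, `powerline_amp`
#'   and `broadband_sd` (mV); all default to 0.
#' @param powerline_hz Powerline frequency, 50 or 60 (default 60).
#' @param seed Optional integer seed.
#' @return A list with `signal` (tibble `t_seconds`, `value`) and
#'   `r_peak_times` (seconds, exactly the template R apexes).
#' @examples
#' ecg <- synthesize_ecg(rep(0.8, 10), fs = 250)
#' length(ecg$r_peak_times)
#' @export
synthesize_ecg <- function(rr, fs = 500,
                           noise = list(
                             baseline_wander_amp = 0,
                             powerline_amp = 0, broadband_sd = 0
                           ),
                           powerline_hz = 60, duration = NULL, seed = NULL) {
  if (is.data.frame(rr)) rr <- rr$rr_seconds
  rr <- as.numeric(rr)
  if (length(rr) == 0L) stop_invalid("RR interval list must not be empty.")
  if (any(rr <= 0)) stop_invalid("RR intervals must be positive.")
  if (fs < 100) stop_invalid("`fs` must be at least 100 Hz for ECG synthesis.")
  noise <- modifyList(
    list(baseline_wander_amp = 0, powerline_amp = 0, broadband_sd = 0),
    as.list(noise)
  )
  if (is.null(duration)) duration <- sum(rr)
  with_seed_(seed, {
    n <- round(duration * fs)
    beat_idx <- round(cumsum(rr) * fs) # 0-based sample indices
    beat_idx <- beat_idx[beat_idx <= n - 1L]
    x <- numeric(n)
    half <- round(0.45 * fs)
    offs <- seq(-half, half)
    tmpl <- pqrst_template(offs / fs)
    for (b in beat_idx) {
      idx <- b + offs + 1L
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + tmpl[ok]
    }
    tt <- (seq_len(n) - 1) / fs
    if (noise$baseline_wander_amp > 0) {
      x <- x + noise$baseline_wander_amp * sin(2 * pi * 0.3 * tt + runif(1, 0, 2 * pi))
    }
    if (noise$powerline_amp > 0) {
      x <- x + noise$powerline_amp * sin(2 * pi * powerline_hz * tt + runif(1, 0, 2 * pi))
    }
    if (noise$broadband_sd > 0) {
      x <- x + rnorm(n, 0, noise$broadband_sd)
    }
    list(
      signal = tibble(t_seconds = tt, value = x),
      r_peak_times = beat_idx / fs
    )
  })
}

#' Generate a train of SCR events
#'
#' Event times are drawn from a homogeneous Poisson process and then thinned
#' greedily so that successive events are at least `min_gap` seconds apart
#' (keeping the detected events resolvable after the 1 Hz low-pass of the
#' preprocessing chain). Amplitudes are log-normal with the requested mean.
#'
#' @param rate Event rate in events/minute (>= 0).
#' @param amp_mean Mean SCR amplitude in microsiemens.
#' @param duration Segment duration in seconds.
#' @param seed Optional integer seed.
#' @param min_gap Minimum inter-event gap in seconds (default 5).
#' @param amp_sdlog Log-scale SD of the amplitude distribution (default 0.4).
#' @return A tibble with columns `t_seconds` and `amplitude`; empty when
#'   `rate` is 0.
#' @examples
#' generate_scr_train(4, 0.5, 120, seed = 1)
#' @export
generate_scr_train <- function(rate, amp_mean, duration, seed = NULL,
                               min_gap = 5, amp_sdlog = 0.4) {
  if (rate < 0) stop_invalid("`rate` must be >= 0.")
  if (duration <= 0) stop_invalid("`duration` must be positive.")
  with_seed_(seed, {
    n <- rpois(1, rate * duration / 60)
    if (n == 0L || rate == 0) {
      return(tibble(t_seconds = numeric(0), amplitude = numeric(0)))
    }
    times <- sort(runif(n, 0, duration))
    keep <- logical(n)
    last <- -Inf
    for (i in seq_len(n)) {
      if (times[i] - last >= min_gap) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
    amps <- rlnorm(length(times),
      meanlog = log(amp_mean) - amp_sdlog^2 / 2,
      sdlog = amp_sdlog
    )
    tibble(t_seconds = times, amplitude = amps)
  })
}

#' Closed-form peak of the Bateman SCR shape
#'
#' The biexponential Bateman response `exp(-t/tau_d) - exp(-t/tau_r)` peaks
#' at `t* = tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param tau_r Rise time constant (s).
#' @param tau_d Decay time constant (s), strictly greater than `tau_r`.
#' @return Peak time (`bateman_peak_time`) or the unnormalized peak value
#'   (`bateman_peak_value`).
#' @export
bateman_peak_time <- function(tau_r = 0.75, tau_d = 2.0) {
  if (tau_r >= tau_d) stop_invalid("`tau_r` must be smaller than `tau_d`.")
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' @rdname bateman_peak_time
#' @export
bateman_peak_value <- function(tau_r = 0.75, tau_d = 2.0) {
  tstar <- bateman_peak_time(tau_r, tau_d)
  exp(-tstar / tau_d) - exp(-tstar / tau_r)
}

#' Synthesize a GSR signal from an SCR event train
#'
#' The signal is a slowly drifting tonic level plus one Bateman-shaped
#' (biexponential) response per event plus white noise. With
#' `normalize = TRUE` (default) each event's `amplitude` equals the peak rise
#' above the tonic level; with `normalize = FALSE` the amplitude is the raw
#' Bateman multiplier, so the peak rise equals
#' `amplitude * bateman_peak_value(tau_r, tau_d)`.
#'
#' @param events Tibble with `t_seconds` and `amplitude`
#'   (see [generate_scr_train()]), or an empty tibble.
#' @param duration Segment duration in seconds.
#' @param tonic List with `scl_level` (microsiemens) and `drift_amp`
#'   (amplitude of a 0.005 Hz sinusoidal tonic drift, microsiemens).
#' @param fs Sampling rate in Hz (>= 10).
#' @param noise_sd White noise SD in microsiemens.
#' @param tau_r,tau_d Bateman rise/decay time constants (s), `tau_r < tau_d`.
#' @param normalize Logical; see Description.
#' @param seed Optional integer seed.
#' @return A list with `signal` (tibble `t_seconds`, `value`) and
#'   `scr_event_times` (the input event times).
#' @examples
#' ev <- tibble::tibble(t_seconds = 10, amplitude = 0.5)
#' gsr <- synthesize_gsr(ev, duration = 30, fs = 50)
#' @export
synthesize_gsr <- function(events, duration,
                           tonic = list(scl_level = 5, drift_amp = 0),
                           fs = 500, noise_sd = 0,
                           tau_r = 0.75, tau_d = 2.0,
                           normalize = TRUE, seed = NULL) {
  if (fs < 10) stop_invalid("`fs` must be at least 10 Hz for GSR synthesis.")
  if (tau_r >= tau_d) stop_invalid("`tau_r` must be smaller than `tau_d`.")
  if (duration <= 0) stop_invalid("`duration` must be positive.")
  tonic <- modifyList(list(scl_level = 5, drift_amp = 0), as.list(tonic))
  with_seed_(seed, {
    n <- round(duration * fs)
    tt <- (seq_len(n) - 1) / fs
    x <- rep(tonic$scl_level, n)
    if (tonic$drift_amp > 0) {
      x <- x + tonic$drift_amp * sin(2 * pi * 0.005 * tt + runif(1, 0, 2 * pi))
    }
    bmax <- bateman_peak_value(tau_r, tau_d)
    if (nrow(events) > 0) {
      support <- min(duration, 10 * tau_d)
      for (i in seq_len(nrow(events))) {
        t0 <- events$t_seconds[i]
        a <- events$amplitude[i]
        if (normalize) a <- a / bmax
        i0 <- floor(t0 * fs) + 1L
        i1 <- min(n, ceiling((t0 + support) * fs) + 1L)
        if (i0 > n) next
        dt <- tt[i0:i1] - t0
        dt[dt < 0] <- 0
        x[i0:i1] <- x[i0:i1] + a * (exp(-dt / tau_d) - exp(-dt / tau_r))
      }
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    list(
      signal = tibble(t_seconds = tt, value = x),
      scr_event_times = events$t_seconds
    )
  })
}

#' Generate a synthetic two-class ECG+GSR cohort
#'
#' Produces one baseline and one task recording of ECG and GSR per subject,
#' with complete ground truth (R-peak times, SCR event times, realized
#' per-subject parameters). Per-subject parameters are jittered around the
#' class parameters; task segments use the `task_shift`-modified parameters
#' (see [class_params()]).
#'
#' @param n_expert,n_novice Number of subjects per class (>= 1).
#' @param expert_params,novice_params [class_params()] objects.
#' @param seed Optional integer seed; the whole cohort is deterministic
#'   given the seed.
#' @param baseline_duration,task_duration Segment durations in seconds
#'   (defaults 120 s baseline, 600 s task).
#' @param fs Sampling rate in Hz (default 500, shared by all four signals).
#' @param ecg_noise Noise list passed to [synthesize_ecg()].
#' @param gsr_noise_sd,gsr_drift_amp GSR white-noise SD and tonic drift
#'   amplitude (microsiemens).
#' @param jitter Relative SD of the per-subject parameter jitter
#'   (default 0.03).
#' @return A tibble of class `physio_cohort`, one row per subject, with
#'   columns `subject_id`, `label` and list-columns `ecg_baseline`,
#'   `ecg_task`, `gsr_baseline`, `gsr_task` (signal tibbles) and `truth`.
#'   The sampling rate is attached as attribute `"fs"`.
#' @examples
#' cohort <- generate_cohort(1, 1,
#'   seed = 1,
#'   baseline_duration = 30, task_duration = 60, fs = 250
#' )
#' cohort$subject_id
#' @export
generate_cohort <- function(n_expert = 5, n_novice = 5,
                            expert_params = expert_params_default(),
                            novice_params = novice_params_default(),
                            seed = NULL,
                            baseline_duration = 120, task_duration = 600,
                            fs = 500,
                            ecg_noise = list(
                              baseline_wander_amp = 0.1,
                              powerline_amp = 0.05,
                              broadband_sd = 0.05
                            ),
                            gsr_noise_sd = 0.02, gsr_drift_amp = 0.3,
                            jitter = 0.03) {
  if (n_expert < 1 || n_novice < 1) {
    stop_invalid("Need at least one subject per class.")
  }
  with_seed_(seed, {
    labels <- c(rep("expert", n_expert), rep("novice", n_novice))
    ids <- sprintf("S%02d", seq_along(labels))
    sub_seeds <- sample.int(.Machine$integer.max - 1L, length(labels))
    rows <- purrr::map(seq_along(labels), function(i) {
      base <- if (labels[i] == "expert") expert_params else novice_params
      with_seed_(sub_seeds[i], {
        jit <- function(v) max(v * (1 + rnorm(1, 0, jitter)), 1e-6)
        subj <- class_params(
          mean_rr = jit(base$mean_rr), sdnn = jit(base$sdnn),
          lf_hf_ratio = jit(base$lf_hf_ratio), scr_rate = jit(base$scr_rate),
          scr_amp_mean = jit(base$scr_amp_mean),
          scl_level = jit(base$scl_level), task_shift = base$task_shift
        )
        task <- shift_params(subj)
        seg <- function(p, dur) {
          rr <- generate_rr_series(p, dur)
          ecg <- synthesize_ecg(rr, fs = fs, noise = ecg_noise, duration = dur)
          ev <- generate_scr_train(p$scr_rate, p$scr_amp_mean, dur)
          gsr <- synthesize_gsr(ev,
            duration = dur,
            tonic = list(scl_level = p$scl_level, drift_amp = gsr_drift_amp),
            fs = fs, noise_sd = gsr_noise_sd
          )
          list(ecg = ecg, gsr = gsr)
        }
        b <- seg(subj, baseline_duration)
        tk <- seg(task, task_duration)
        tibble(
          subject_id = ids[i], label = labels[i],
          ecg_baseline = list(b$ecg$signal), ecg_task = list(tk$ecg$signal),
          gsr_baseline = list(b$gsr$signal), gsr_task = list(tk$gsr$signal),
          truth = list(list(
            r_peaks_baseline = b$ecg$r_peak_times,
            r_peaks_task = tk$ecg$r_peak_times,
            scr_baseline = b$gsr$scr_event_times,
            scr_task = tk$gsr$scr_event_times,
            params_baseline = subj, params_task = task
          ))
        )
      })
    })
    out <- bind_rows(rows)
    attr(out, "fs") <- fs
    class(out) <- c("physio_cohort", class(out))
    out
  })
}

#' @export
print.physio_cohort <- function(x, ...) {
  cat(sprintf(
    "<physio_cohort> %d subjects (%d expert, %d novice), fs = %g Hz\n",
    nrow(x), sum(x$label == "expert"), sum(x$label == "novice"),
    attr(x, "fs")
  ))
  NextMethod()
}
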