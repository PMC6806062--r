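test_that("zero-variance RR series is exactly periodic and fills the duration", {
  rr <- generate_rr_series(class_params(mean_rr = 0.8, sdnn = 0), 60, seed = 1)
  expect_equal(nrow(rr), 75)
  expect_true(all(rr$rr_seconds == 0.8))
  expect_lte(max(rr$t_seconds), 60)
})

test_that("RR generator recovers the programmed moments", {
  rr <- generate_rr_series(class_params(mean_rr = 0.8, sdnn = 0.05), 600, seed = 7)
  expect_lt(abs(mean(rr$rr_seconds) - 0.8), 0.01)
  expect_lt(abs(sd(rr$rr_seconds) - 0.05), 0.01)
})

test_that("RR generator hits the programmed LF/HF band-power ratio", {
  rr <- generate_rr_series(
    class_params(mean_rr = 0.8, sdnn = 0.05, lf_hf_ratio = 2), 600,
    seed = 7
  )
  bp <- lomb_band_powers(rr$t_seconds, rr$rr_seconds)
  expect_lt(abs(bp$LF / bp$HF - 2), 0.5)
})

test_that("RR moment recovery holds across seeds within Monte-Carlo error", {
  p <- class_params(mean_rr = 0.8, sdnn = 0.05)
  stats <- vapply(1:30, function(s) {
    rr <- generate_rr_series(p, 300, seed = s)
    c(mean(rr$rr_seconds), sd(rr$rr_seconds))
  }, numeric(2))
  se_mean <- sd(stats[1, ]) / sqrt(30)
  se_sd <- sd(stats[2, ]) / sqrt(30)
  expect_lt(abs(mean(stats[1, ]) - 0.8), 3 * se_mean + 1e-3)
  expect_lt(abs(mean(stats[2, ]) - 0.05), 3 * se_sd + 2e-3)
})

test_that("RR generator rejects invalid parameters", {
  expect_error(generate_rr_series(class_params(), -1), class = "physioload_invalid_parameter")
  expect_error(class_params(mean_rr = 0), class = "physioload_invalid_parameter")
  expect_error(class_params(task_shift = 0), class = "physioload_invalid_parameter")
})

test_that("noiseless ECG places signal maxima exactly at the R-peak times", {
  ecg <- synthesize_ecg(rep(0.8, 20), fs = 500)
  idx <- round(ecg$r_peak_times * 500) + 1
  # each R sample must dominate its neighbourhood
  for (i in idx) {
    lo <- max(1, i - 100)
    hi <- min(nrow(ecg$signal), i + 100)
    expect_equal(which.max(ecg$signal$value[lo:hi]) + lo - 1, i)
  }
})

test_that("ECG length arithmetic matches the RR sum", {
  ecg <- synthesize_ecg(rep(0.8, 75), fs = 500)
  expect_equal(nrow(ecg$signal), 30000)
  expect_lte(length(ecg$r_peak_times), 75)
  expect_gte(length(ecg$r_peak_times), 74)
})

test_that("ECG synthesis rejects empty or invalid RR input", {
  expect_error(synthesize_ecg(numeric(0)), class = "physioload_invalid_parameter")
  expect_error(synthesize_ecg(rep(0.8, 5), fs = 50), class = "physioload_invalid_parameter")
})

test_that("SCR train respects rate zero, minimum gap, and expected counts", {
  expect_equal(nrow(generate_scr_train(0, 0.5, 600, seed = 1)), 0)
  counts <- vapply(1:15, function(s) {
    ev <- generate_scr_train(4, 0.5, 600, seed = s)
    if (nrow(ev) > 1) expect_true(all(diff(ev$t_seconds) >= 5))
    nrow(ev)
  }, numeric(1))
  # gap thinning pulls the Poisson mean of 40 down toward ~30
  expect_gte(mean(counts), 25)
  expect_lte(mean(counts), 55)
  expect_gte(nrow(generate_scr_train(4, 0.5, 600, seed = 3)), 25)
  expect_lte(nrow(generate_scr_train(4, 0.5, 600, seed = 3)), 55)
})

test_that("GSR synthesis obeys the Bateman closed form and degenerate cases", {
  # no events, no drift, no noise: constant at the tonic level
  flat <- synthesize_gsr(
    tibble::tibble(t_seconds = numeric(0), amplitude = numeric(0)),
    duration = 20, tonic = list(scl_level = 5, drift_amp = 0), fs = 100
  )
  expect_true(all(flat$signal$value == 5))
  # raw-multiplier mode: peak rise equals A times the Bateman maximum
  g <- synthesize_gsr(
    tibble::tibble(t_seconds = 20, amplitude = 0.5),
    duration = 60, tonic = list(scl_level = 5, drift_amp = 0),
    fs = 500, normalize = FALSE
  )
  expect_equal(max(g$signal$value) - 5, 0.5 * bateman_peak_value(), tolerance = 1e-4)
  # peak-normalized mode: peak rise equals the amplitude parameter
  g2 <- synthesize_gsr(
    tibble::tibble(t_seconds = 20, amplitude = 0.5),
    duration = 60, tonic = list(scl_level = 5, drift_amp = 0), fs = 500
  )
  expect_equal(max(g2$signal$value) - 5, 0.5, tolerance = 1e-4)
  expect_error(
    synthesize_gsr(flat$signal[0, ], duration = 10, tau_r = 2, tau_d = 1),
    class = "physioload_invalid_parameter"
  )
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(1, 1, seed = 3, baseline_duration = 30, task_duration = 40, fs = 250)
  b <- generate_cohort(1, 1, seed = 3, baseline_duration = 30, task_duration = 40, fs = 250)
  expect_identical(a$ecg_task[[1]], b$ecg_task[[1]])
  expect_identical(a$gsr_baseline[[1]], b$gsr_baseline[[1]])
  expect_identical(a$truth[[1]]$r_peaks_task, b$truth[[1]]$r_peaks_task)
})

test_that("cohort ground truth lies inside the segments and is sorted", {
  cohort <- small_cohort()
  for (i in seq_len(nrow(cohort))) {
    truth <- cohort$truth[[i]]
    for (nm in c("r_peaks_baseline", "scr_baseline")) {
      expect_true(all(diff(truth[[nm]]) > 0))
      expect_true(all(truth[[nm]] <= 60 + 1e-9))
    }
    for (nm in c("r_peaks_task", "scr_task")) {
      expect_true(all(diff(truth[[nm]]) > 0))
      expect_true(all(truth[[nm]] <= 180 + 1e-9))
    }
  }
})

test_that("cohort generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(generate_cohort(1, 1, seed = 5, baseline_duration = 30, task_duration = 40, fs = 250))
  expect_identical(rnorm(1), before)
})
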