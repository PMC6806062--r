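test_that("filter chain maps zero and DC input to (near) zero output", {
  z <- pt_filter_chain(rep(0, 2000), fs = 500)
  expect_true(all(z$integrated == 0))
  dc <- pt_filter_chain(rep(2.5, 5000), fs = 500)
  warm <- 500:4500
  expect_lt(max(dc$integrated[warm]), 1e-6)
})

test_that("filter chain passes 10 Hz and rejects 50 Hz", {
  t <- (0:9999) / 500
  rms <- function(x) sqrt(mean(x^2))
  in50 <- pt_filter_chain(sin(2 * pi * 50 * t), fs = 500)
  in10 <- pt_filter_chain(sin(2 * pi * 10 * t), fs = 500)
  mid <- 2000:8000
  expect_lt(rms(in50$integrated[mid]), 0.1 * rms(in10$integrated[mid]))
})

test_that("filter chain rejects too-short input", {
  expect_error(pt_filter_chain(rep(0, 100), fs = 500), class = "physioload_too_short")
})

test_that("detector finds every beat of a noiseless recording within 10 ms", {
  ecg <- synthesize_ecg(rep(0.8, 60 / 0.8), fs = 500)
  peaks <- detect_r_peaks(pt_filter_chain(ecg$signal, 500), 500)
  expect_equal(length(peaks), length(ecg$r_peak_times))
  err <- vapply(peaks, function(p) min(abs(ecg$r_peak_times - p)), numeric(1))
  expect_lt(max(err), 0.010)
})

test_that("detector is perfect on noiseless variable-rate fixtures across seeds", {
  for (s in 1:5) {
    rr <- generate_rr_series(class_params(mean_rr = 0.8, sdnn = 0.05), 60, seed = s)
    ecg <- synthesize_ecg(rr, fs = 500)
    peaks <- detect_r_peaks(pt_filter_chain(ecg$signal, 500), 500)
    stats <- match_stats(peaks, ecg$r_peak_times, 0.05)
    expect_equal(unname(stats["sensitivity"]), 1)
    expect_equal(unname(stats["ppv"]), 1)
  }
})

test_that("flat input yields an empty peak list, not an error", {
  expect_length(detect_r_peaks(pt_filter_chain(rep(0, 5000), 500), 500), 0)
})

test_that("detection is invariant to global amplitude scaling", {
  ecg <- synthesize_ecg(rep(0.8, 40), fs = 500, noise = list(broadband_sd = 0.1), seed = 4)
  p1 <- detect_r_peaks(pt_filter_chain(ecg$signal, 500), 500)
  scaled <- ecg$signal
  scaled$value <- scaled$value * 37
  p2 <- detect_r_peaks(pt_filter_chain(scaled, 500), 500)
  expect_identical(p1, p2)
})

test_that("broadband noise never lifts sensitivity above the noiseless value", {
  for (s in 1:3) {
    rr <- generate_rr_series(class_params(mean_rr = 0.8, sdnn = 0.05), 30, seed = s)
    ecg0 <- synthesize_ecg(rr, fs = 500)
    ecgn <- synthesize_ecg(rr, fs = 500, noise = list(broadband_sd = 0.4), seed = s)
    se0 <- match_stats(
      detect_r_peaks(pt_filter_chain(ecg0$signal, 500), 500),
      ecg0$r_peak_times, 0.05
    )["sensitivity"]
    sen <- match_stats(
      detect_r_peaks(pt_filter_chain(ecgn$signal, 500), 500),
      ecgn$r_peak_times, 0.05
    )["sensitivity"]
    expect_lte(sen, se0)
  }
})

test_that("RR intervals are successive differences with plausibility flags", {
  rr <- compute_rr(c(1.0, 1.8, 2.6))
  expect_equal(rr$rr_seconds, c(0.8, 0.8))
  expect_false(any(rr$flagged))
  flagged <- compute_rr(c(0.0, 0.1))
  expect_true(flagged$flagged)
  expect_error(compute_rr(1.0), class = "physioload_insufficient_peaks")
})

test_that("fixed-rate synthetic ECG recovers the programmed RR mean", {
  ecg <- synthesize_ecg(rep(0.8, 75), fs = 500)
  rr <- process_ecg(ecg$signal, 500)
  expect_lt(abs(mean(rr$rr_seconds[!rr$flagged]) - 0.8), 0.005)
})
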