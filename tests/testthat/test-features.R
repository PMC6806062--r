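test_that("window counts follow the closed-form formula", {
  expect_equal(nrow(segment_windows(600, 10, 5)), 119)
  expect_equal(nrow(segment_windows(600, 30, 10)), 29)
  one <- segment_windows(10, 10, 5)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0, 10))
  expect_error(segment_windows(100, 10, 10), class = "physioload_invalid_parameter")
})

test_that("window counts match brute-force enumeration on random triples", {
  withr::with_seed(42, {
    for (i in 1:100) {
      window <- runif(1, 1, 50)
      overlap <- runif(1, 0, window * 0.95)
      duration <- window + runif(1, 0, 500)
      got <- nrow(segment_windows(duration, window, overlap))
      # brute force: walk the starts
      step <- window - overlap
      k <- 0
      while ((k + 1) * step + window <= duration + 1e-9) k <- k + 1
      expect_equal(got, k + 1)
    }
  })
})

test_that("time-domain HRV features match hand computation", {
  f <- ecg_time_features(c(0.80, 0.86, 0.90, 0.91))
  expect_equal(f$NN50, 1)
  expect_equal(f$PNN50, 100 / 3, tolerance = 1e-9)
  expect_equal(f$RR_diff, 0.11)
  expect_equal(f$RR_mean, mean(c(0.80, 0.86, 0.90, 0.91)))
  const <- ecg_time_features(rep(0.8, 3))
  expect_equal(const$RR_SD, 0)
  expect_equal(const$RR_CV, 0)
  expect_equal(const$SDSD, 0)
  expect_equal(const$NN50, 0)
  expect_equal(const$PNN50, 0)
  expect_true(all(is.na(unlist(ecg_time_features(c(0.8, 0.8))))))
})

test_that("RR order statistics are consistent on random windows", {
  withr::with_seed(7, {
    for (i in 1:20) {
      rr <- runif(sample(3:30, 1), 0.5, 1.2)
      f <- ecg_time_features(rr)
      expect_lte(f$RR_min, f$RR_mean)
      expect_lte(f$RR_mean, f$RR_max)
      expect_gte(f$PNN50, 0)
      expect_lte(f$PNN50, 100)
    }
  })
})

test_that("Lomb band powers vanish for constant series and localize a 0.1 Hz line", {
  t <- cumsum(rep(0.8, 64))
  expect_true(all(unlist(lomb_band_powers(t, rep(0.8, 64))) == 0))
  mod <- 0.8 + 0.05 * sin(2 * pi * 0.1 * t)
  bp <- lomb_band_powers(t, mod)
  expect_gt(bp$LF, 10 * bp$HF)
})

test_that("band powers are additive up to integration tolerance", {
  withr::with_seed(3, {
    for (i in 1:10) {
      t <- cumsum(runif(60, 0.6, 1.0))
      y <- 0.8 + 0.05 * sin(2 * pi * 0.1 * t) + rnorm(60, 0, 0.02)
      bp <- lomb_band_powers(t, y)
      expect_lte(bp$ULF + bp$VLF + bp$LF + bp$HF, bp$TP * 1.01 + 1e-12)
      expect_true(all(unlist(bp) >= 0))
    }
  })
})

test_that("Lomb band powers agree with an FFT periodogram on even sampling", {
  withr::with_seed(1, {
    dt <- 0.8
    n <- 1250
    t <- (0:(n - 1)) * dt
    ar <- as.numeric(stats::filter(rnorm(n, 0, 0.02), 0.7, method = "recursive"))
    y <- 0.8 + ar + rnorm(n, 0, 0.01)
    grid <- seq(0.001, 0.4, by = 0.001)
    bp <- unlist(lomb_band_powers(t, y, grid))
    yc <- y - mean(y)
    psd <- vapply(grid, function(f) {
      (2 * dt / n) * Mod(sum(yc * exp(-2i * pi * f * t)))^2
    }, numeric(1))
    bandint <- function(lo, hi) {
      s <- grid >= lo & grid <= hi
      sum(diff(grid[s]) * (psd[s][-1] + psd[s][-sum(s)]) / 2)
    }
    oracle <- c(
      bandint(0, 0.003), bandint(0.003, 0.04), bandint(0.04, 0.15),
      bandint(0.15, 0.4), bandint(0, 0.4)
    )
    expect_lt(max(abs(bp - oracle) / oracle), 0.05)
  })
})

test_that("frequency-feature ratios behave at their symmetry points", {
  t <- cumsum(rep(0.8, 80))
  f <- ecg_freq_features(t, 0.8 + 0.05 * sin(2 * pi * 0.1 * t))
  expect_equal(f$LF_norm + f$HF_norm, 100, tolerance = 1e-9)
  # MF is a sub-band of LF, so LMHF always dominates LF/HF
  expect_gte(f$LMHF, f$LF_HF)
  # constant input: zero bands, ratios missing
  fc <- ecg_freq_features(t, rep(0.8, 80))
  expect_equal(fc$TP, 0)
  expect_true(is.na(fc$LF_HF))
})

test_that("GSR window features handle constant, single-event and duplicate cases", {
  none <- detect_scr_events(filter_gsr(rep(4, 20 * 500), 500), 500)
  f <- gsr_window_features(rep(4, 15000), none, 500)
  expect_equal(f$SCL, 4)
  expect_equal(f$MAV1Diff_SCL, 0)
  expect_equal(f$MAV2Diff_SCL, 0)
  expect_lt(f$BP, 1e-12)
  expect_true(is.na(f$RT_mean))

  g <- synthesize_gsr(
    tibble::tibble(t_seconds = 10, amplitude = 0.5),
    duration = 30, tonic = list(scl_level = 5, drift_amp = 0), fs = 500
  )
  filt <- filter_gsr(g$signal, 500)
  ev <- detect_scr_events(filt, 500)
  f1 <- gsr_window_features(filt$value, ev, 500, 0, 30)
  expect_equal(f1$RT_mean, f1$RT_min)
  expect_equal(f1$RT_mean, f1$RT_max)
  expect_equal(f1$RT_SD, 0)
  expect_lt(abs(f1$RT_mean - bateman_peak_time()), 0.2)

  # two identical events: SD of every per-event feature is 0
  ev2 <- dplyr::bind_rows(ev, dplyr::mutate(ev, peak_t = peak_t + 1e-3))
  f2 <- gsr_window_features(filt$value, ev2, 500, 0, 30)
  for (nm in c("RT_SD", "HRT_SD", "Amp_SD", "Area_SD", "Prom_SD")) {
    expect_equal(f2[[nm]], 0)
  }
})

test_that("baseline normalization is an exact identity and guards zeros", {
  task <- tibble::tibble(RR_mean = 0.9, NN50 = 3, RR_SD = 0.05)
  base <- c(RR_mean = 0.75, NN50 = 0, RR_SD = 0.05)
  out <- baseline_normalize(task, base)
  expect_equal(out$RR_mean, 1.2)
  expect_true(is.na(out$NN50)) # zero baseline never becomes Inf
  expect_equal(out$RR_SD, 1)
  same <- baseline_normalize(task, c(RR_mean = 0.9, NN50 = 3, RR_SD = 0.05))
  expect_equal(unlist(same), c(RR_mean = 1, NN50 = 1, RR_SD = 1))
  expect_error(
    baseline_normalize(task, c(other = 1)),
    class = "physioload_schema_error"
  )
})

test_that("a baseline-equals-task ECG fixture normalizes to exactly one", {
  # strictly periodic RR pattern: every 10 s window sees the identical
  # interval sequence, so each window's features equal the baseline mean
  rr <- periodic_rr(24) # 120 s
  times <- cumsum(rr)
  wins <- segment_windows(120, 10, 5)
  rows <- purrr::pmap(wins, function(window_id, start, end) {
    sel <- times > start & times <= end
    tibble::as_tibble(c(
      ecg_time_features(rr[sel]),
      ecg_freq_features(times[sel], rr[sel])
    ))
  })
  feats <- dplyr::bind_rows(rows)
  base <- vapply(feats, mean, numeric(1))
  normalized <- baseline_normalize(feats, base)
  for (nm in names(normalized)) {
    expect_equal(normalized[[nm]], rep(1, nrow(normalized)),
      tolerance = 1e-12, label = nm
    )
  }
})

test_that("normalized RR_mean tracks the programmed task shift", {
  cohort <- small_cohort()
  feats <- small_features()
  for (i in seq_len(nrow(cohort))) {
    shift <- cohort$truth[[i]]$params_baseline$task_shift
    rows <- feats$ecg[feats$ecg$subject_id == cohort$subject_id[i], ]
    got <- mean(rows$RR_mean, na.rm = TRUE)
    expect_lt(abs(got - 1 / shift) / (1 / shift), 0.05)
  }
})

test_that("matrix assembly drops exactly the incomplete rows", {
  feats <- small_features()
  m <- suppressMessages(assemble_matrix(feats, "ecg"))
  expect_false(anyNA(m))
  # inject one missing cell: exactly one more row disappears
  broken <- feats
  complete_rows <- which(stats::complete.cases(broken$ecg))
  broken$ecg$RR_mean[complete_rows[1]] <- NA
  m2 <- suppressMessages(assemble_matrix(broken, "ecg"))
  expect_equal(nrow(m2), nrow(m) - 1)

  gsr <- suppressMessages(assemble_matrix(feats, "gsr"))
  multi <- suppressMessages(assemble_matrix(feats, "multimodal"))
  expect_lte(nrow(multi), nrow(feats$gsr))
  expect_equal(
    length(physioload:::feature_columns(multi)),
    length(physioload:::feature_columns(gsr)) + 18
  )
})
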