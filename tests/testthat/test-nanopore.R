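# nanopore sizing: baseline estimation, event detection, calibration
# mapping, polydispersity summaries, and the module's invariants

test_that("estimate_baseline is robust and tracks the filter's noise gain", {
  fs <- 200000
  # constant, zero-noise trace
  tr <- current_trace(rep(1000, fs / 10), fs)
  est <- estimate_baseline(tr)
  expect_equal(est$baseline_pa, 1000)
  expect_equal(est$sigma_pa, 0)
  # pure Gaussian noise: sigma within 10% of the post-filter theoretical sd
  set.seed(11)
  tr2 <- current_trace(1000 + rnorm(fs, sd = 10), fs)
  est2 <- estimate_baseline(tr2)
  theo <- 10 * lowpass_noise_gain(fs, 5000)
  expect_lt(abs(est2$sigma_pa - theo) / theo, 0.10)
  # 5% of samples in deep dips: baseline still within 1 pA
  x <- 1000 + rnorm(fs, sd = 2)
  dip <- seq_len(fs * 0.05)
  x[10000 + dip] <- x[10000 + dip] - 300
  est3 <- estimate_baseline(current_trace(x, fs))
  expect_lt(abs(est3$baseline_pa - 1000), 1)
  # too-short trace errors
  expect_error(estimate_baseline(current_trace(rep(1, 100), fs)), "10 ms")
})

test_that("detect_events finds injected events with faithful durations", {
  # flat noiseless trace: zero-noise sigma triggers the abs-floor rule
  flat <- current_trace(rep(1000, 20000), 200000)
  expect_error(detect_events(flat), "abs_floor_pa")
  ev0 <- detect_events(flat, detection_params(abs_floor_pa = 5))
  expect_identical(nrow(ev0), 0L)

  # 10 events, depths ~10 sigma (filtered), durations 100 us - 1 ms;
  # a 50 kHz analysis filter resolves these durations to +-2 samples
  fs <- 200000
  durs <- rep(c(100e-6, 250e-6, 500e-6, 750e-6, 1e-3), 2)
  onsets <- 0.05 + (seq_along(durs) - 1) * 0.05
  sig_f <- lowpass_noise_gain(fs, 50000)  # ~ filtered noise sd for sd = 1
  tr <- inject_trace(onsets, durs, depths_pa = rep(10 * sig_f * 5, 10),
                     noise_sd_pa = 1, duration_s = 0.55, seed = 13)
  ev <- detect_events(tr, detection_params(analysis_lowpass_hz = 50000))
  expect_identical(nrow(ev), 10L)
  expect_equal(ev$duration_s, durs, tolerance = 2.5 / fs / min(durs))
  expect_true(all(abs(ev$duration_s - durs) <= 2.5 / fs))
  expect_true(all(abs(ev$onset_s - onsets) <= 5 / fs))
  # areas match depth x duration within 5%
  expect_equal(ev$area_pa_s, rep(10 * sig_f * 5, 10) * durs, tolerance = 0.05)
})

test_that("the duration window excludes out-of-range events", {
  # unfiltered analysis path (analysis_lowpass = Inf) keeps durations exact:
  # 10 us and 3 ms are excluded, 30 us and 2 ms are retained
  durs <- c(10e-6, 30e-6, 2e-3, 3e-3)
  onsets <- c(0.05, 0.1, 0.15, 0.2)
  tr <- inject_trace(onsets, durs, depths_pa = rep(20, 4), noise_sd_pa = 1,
                     duration_s = 0.3, seed = 17)
  ev <- detect_events(tr, detection_params(analysis_lowpass_hz = Inf))
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$onset_s, onsets[2:3], tolerance = 1e-3)
  expect_equal(ev$duration_s, durs[2:3], tolerance = 0.05)
})

test_that("detection is invariant to a constant trace shift", {
  sp <- trace_spec(duration_s = 0.5, event_rate_hz = 30, seed = 21)
  g <- gen_trace(sp, test_calibration())
  ev1 <- detect_events(g$trace)
  tr2 <- g$trace
  tr2$samples <- tr2$samples + 500
  ev2 <- detect_events(tr2)
  expect_identical(nrow(ev1), nrow(ev2))
  expect_equal(ev1$duration_s, ev2$duration_s)
  expect_equal(ev1$area_pa_s, ev2$area_pa_s, tolerance = 1e-6)
})

test_that("concatenating traces yields the union of their events", {
  cal <- test_calibration()
  ga <- gen_trace(trace_spec(duration_s = 0.5, event_rate_hz = 30, seed = 31), cal)
  gb <- gen_trace(trace_spec(duration_s = 0.5, event_rate_hz = 30, seed = 32), cal)
  na <- nrow(detect_events(ga$trace))
  nb <- nrow(detect_events(gb$trace))
  tr <- current_trace(c(ga$trace$samples, gb$trace$samples), 200000)
  nab <- nrow(detect_events(tr))
  expect_lte(abs(nab - (na + nb)), 1)  # at most one seam artifact
})

test_that("map_mw interpolates log-log and flags out-of-range areas", {
  cal <- calibration_curve(c(0.01, 0.1, 1), c(100, 1000, 10000))
  # calibration node maps to its own MW
  ev <- data.frame(area_pa_s = c(0.1, sqrt(0.01 * 0.1), 0.005, 5))
  m <- map_mw(ev, cal)
  expect_equal(m$mw_kda[1L], 1000)
  # geometric mean of node areas -> geometric mean of node MWs
  expect_equal(m$mw_kda[2L], sqrt(100 * 1000))
  expect_identical(m$flag, c("ok", "ok", "below-calibration", "above-calibration"))
  expect_true(is.na(m$mw_kda[3L]))
  # clamping option
  mc <- map_mw(ev, cal, above_range = "clamp")
  expect_equal(mc$mw_kda[4L], 10000)
  # scaling both calibration areas and event areas leaves MWs unchanged
  cal2 <- calibration_curve(10 * c(0.01, 0.1, 1), c(100, 1000, 10000))
  m2 <- map_mw(data.frame(area_pa_s = 10 * ev$area_pa_s), cal2)
  expect_equal(m2$mw_kda, m$mw_kda)
})

test_that("calibration_curve enforces its invariants", {
  expect_error(calibration_curve(c(1, 0.5), c(100, 200)), "increasing")
  expect_error(calibration_curve(c(0.1), c(100)), ">= 2")
  expect_error(calibration_curve(c(0.01, 0.1), c(20, 200)), "50 kDa")
  # power-law form reproduces an exact power law
  cal <- synthetic_power_law_calibration(coef_pa_s = 2e-4, exponent = 1.3)
  calp <- calibration_curve(cal$points$area_pa_s, cal$points$mw_kda,
                            form = "powerlaw")
  a <- 0.37 * max(cal$points$area_pa_s)
  expect_equal(cocmatrix:::cal_area_to_mw(calp, a),
               (a / 2e-4)^(1 / 1.3), tolerance = 1e-6)
})

test_that("summarize_polydispersity computes Mw, fractions and QC", {
  # all events at 300 kDa: strict inequality keeps fraction_below(300) at 0
  r <- summarize_polydispersity(rep(300, 600))
  expect_equal(r$weighted_avg_mw_kda, 300)
  expect_equal(r$fraction_below[["300"]], 0)
  expect_true(r$qc_pass)
  # hand-computed mass weighting
  r2 <- summarize_polydispersity(c(100, 100, 400), min_events = 3)
  expect_equal(r2$number_avg_mw_kda, 200)
  expect_equal(r2$weighted_avg_mw_kda, 300)
  # 499 events fail QC at the default minimum of 500
  expect_false(summarize_polydispersity(rep(100, 499))$qc_pass)
  expect_true(summarize_polydispersity(rep(100, 500))$qc_pass)
  # histogram fractions sum to 1; Mw within the per-event range
  set.seed(3)
  mw <- exp(rnorm(800, log(300), 0.8))
  r3 <- summarize_polydispersity(mw)
  expect_equal(sum(r3$histogram$fraction), 1, tolerance = 1e-9)
  expect_gte(r3$weighted_avg_mw_kda, min(mw))
  expect_lte(r3$weighted_avg_mw_kda, max(mw))
  expect_equal(r3$weighted_avg_mw_kda, mass_weighted_mw(mw))
})

test_that("trace round-trips through raw and csv formats", {
  g <- gen_trace(trace_spec(duration_s = 0.05, event_rate_hz = 0, seed = 2),
                 test_calibration())
  stem <- file.path(withr::local_tempdir(), "tr")
  write_trace_raw(g$trace, stem)
  back <- read_trace_raw(stem)
  expect_equal(back$samples, g$trace$samples, tolerance = 1e-4)  # float32
  expect_equal(back$sampling_hz, g$trace$sampling_hz)
  write_trace_csv(g$trace, stem)
  back2 <- read_trace_csv(stem)
  expect_equal(back2$samples, g$trace$samples, tolerance = 1e-6)
})
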