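# Waveform characterization: period averaging, tau fitting, spectra.

test_that("waveform records enforce uniform sampling and finiteness", {
  expect_error(waveform_record(c(0, 0.1, 0.3), c(1, 2, 3)), "uniform")
  expect_error(waveform_record(c(0, 0.1, 0.2), c(1, NA, 3)), "finite")
  rec <- waveform_record(seq(0, 1, 0.01), rep(0.5, 101))
  expect_equal(rec$sample_rate_hz, 100)
})

test_that("period averaging reproduces a noiseless period exactly and counts periods", {
  t <- seq(0, 50, by = 0.05)
  rec <- waveform_record(t, 0.5 + 0.4 * sin(2 * pi * 0.1 * t))
  seg <- segment_and_average_periods(rec, expected_period = 10)
  expect_equal(seg$periods_used, 5)
  np <- length(seg$averaged$value)
  expect_lt(max(abs(seg$averaged$value - rec$value[1:np])), 1e-9)
  # auto period detection agrees
  seg_auto <- segment_and_average_periods(rec)
  expect_equal(seg_auto$period_s, 10, tolerance = 0.05)
  expect_error(segment_and_average_periods(
    waveform_record(seq(0, 12, 0.05), sin(2 * pi * 0.1 * seq(0, 12, 0.05))),
    expected_period = 10), "two periods")
})

test_that("period averaging suppresses i.i.d. noise by roughly 1/sqrt(N)", {
  t <- seq(0, 200, by = 0.05)     # 20 periods at 0.1 Hz
  clean <- 0.5 + 0.3 * sin(2 * pi * 0.1 * t)
  withr::with_seed(7, {
    rec <- waveform_record(t, clean + rnorm(length(t), sd = 0.1))
    seg <- segment_and_average_periods(rec, expected_period = 10)
    np <- length(seg$averaged$value)
    rmse <- sqrt(mean((seg$averaged$value - clean[1:np])^2))
    expect_lt(rmse, 0.1 / sqrt(20) * 1.5)
    expect_gte(seg$periods_used, 15)
  })
})

test_that("tau estimators recover the generating value, invariant to scale", {
  t <- seq(0, 3, by = 0.01)
  rec <- waveform_record(t, 1 - exp(-t / 0.316))
  fit <- fit_time_constant(rec)
  expect_equal(fit$tau_s, 0.316, tolerance = 0.002 / 0.316)
  expect_equal(fit$tau_lsq_s, 0.316, tolerance = 0.002 / 0.316)
  # crossing and LSQ agree within 1% on noiseless first-order data
  expect_equal(fit$tau_s, fit$tau_lsq_s, tolerance = 0.01)
  # scale and offset invariance
  fit_scaled <- fit_time_constant(
    waveform_record(t, 40 + 173 * (1 - exp(-t / 0.316))))
  expect_equal(fit_scaled$tau_s, fit$tau_s)
  expect_error(fit_time_constant(waveform_record(t, rep(1, length(t)))),
               "plateau")
})

test_that("least-squares tau survives additive noise within 5% (seeded Monte-Carlo)", {
  t <- seq(0, 3, by = 0.01)
  clean <- 1 - exp(-t / 0.316)
  errs <- vapply(1:25, function(seed) {
    withr::with_seed(seed, {
      rec <- waveform_record(t, clean + rnorm(length(t), sd = 0.02))
      abs(fit_time_constant(rec)$tau_lsq_s - 0.316) / 0.316
    })
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("a pre-step plateau anchors the baseline when the step time is known", {
  t <- seq(0, 5, by = 0.01)
  v <- ifelse(t < 1, 0.2, 0.2 + 0.6 * (1 - exp(-(t - 1) / 0.541)))
  fit <- fit_time_constant(waveform_record(t, v), step_time_s = 1)
  expect_equal(fit$tau_s, 0.541, tolerance = 0.005)
})

test_that("cut-off estimation chains from fitted tau", {
  t <- seq(0, 3, by = 0.01)
  fit <- fit_time_constant(waveform_record(t, 1 - exp(-t / 0.316)))
  expect_equal(estimate_cutoff(fit), 1 / (2 * pi * fit$tau_s))
  expect_equal(round(estimate_cutoff(0.541), 3), 0.294)
})

test_that("dominant frequency detection: sinusoid, square fundamental, degenerate flat", {
  t <- seq(0, 60, by = 0.1)
  rec <- waveform_record(t, sin(2 * pi * 0.1 * t))
  expect_equal(dominant_frequency(rec), 0.1, tolerance = 0.002 / 0.1)
  # the square fundamental (4/pi) dominates all harmonics
  sq <- waveform_record(t, as.numeric(((0.1 * t) %% 1) < 0.5))
  expect_equal(dominant_frequency(sq), 0.1, tolerance = 0.002 / 0.1)
  expect_error(dominant_frequency(waveform_record(t, rep(0.3, length(t)))),
               "flat")
})

test_that("empirical frequency response: identity system and first-order closed form", {
  t <- seq(0, 100, by = 0.05)
  mkpair <- function(f, gain = 1, phase = 0) {
    list(input = waveform_record(t, sin(2 * pi * f * t)),
         output = waveform_record(t, gain * sin(2 * pi * f * t + phase)),
         frequency = f)
  }
  ident <- empirical_frequency_response(
    lapply(c(0.05, 0.1, 0.2), mkpair))
  expect_equal(ident$gain, rep(1, 3), tolerance = 1e-6)
  # synthetic first-order system at fc/4, fc, 4 fc
  tau <- 0.5
  fc <- 1 / (2 * pi * tau)
  pairs <- lapply(c(fc / 4, fc, 4 * fc), function(f) {
    g <- lpf_gain(f, tau)
    mkpair(f, gain = g, phase = -atan(2 * pi * f * tau))
  })
  fr <- empirical_frequency_response(pairs)
  expect_equal(fr$gain[2], 1 / sqrt(2), tolerance = 0.01)
  expect_true(all(diff(fr$gain) < 0))
  expect_equal(fr$phase_rad[2], -pi / 4, tolerance = 0.01)
  # mismatched grids are rejected
  bad <- list(list(input = waveform_record(t, sin(t)),
                   output = waveform_record(t + 0.01, sin(t)),
                   frequency = 0.1))
  expect_error(empirical_frequency_response(bad), "grid")
})

test_that("parameter recovery closes the loop across all three filter chips", {
  # simulate step -> fit tau -> Eq for fc -> back-calculate C, within 2%
  tab <- filter_chip_table()
  out <- characterize_filter_chips(tab)
  expect_equal(out$tau_s, tab$tau_s, tolerance = 0.02)
  expect_equal(out$cutoff_hz, 1 / (2 * pi * tab$tau_s), tolerance = 0.02)
  expect_equal(out$capacitance_m3_per_pa, tab$capacitance_m3_per_pa,
               tolerance = 0.02)
})

test_that("rise/fall asymmetry distinguishes sawtooth from symmetric shapes", {
  t <- seq(0, 9.99, by = 0.01)
  saw <- waveform_record(t, (0.1 * t) %% 1)
  tri <- waveform_record(t, waveform_value(
    target_waveform("triangle", frequency = 0.1, duration = 10), t))
  expect_lt(rise_fall_ratio(saw), 0.01)
  expect_equal(rise_fall_ratio(tri), 1, tolerance = 0.01)
})
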