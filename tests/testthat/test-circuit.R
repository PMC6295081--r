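# Lumped-element circuit simulation.

test_that("withdrawal constraint holds at every step to solver tolerance", {
  cfg <- demo_system_config("RC2")
  w <- target_waveform("sinusoid", frequency = 0.1, duration = 30)
  sim <- simulate_circuit(cfg, encode_pwm(w, 0.5), dt = 0.01)
  resid <- abs(sim$q_ii + sim$q_iii - cfg$withdrawal_rate)
  expect_lt(max(resid), 1e-9 * cfg$withdrawal_rate)
  expect_equal(sim$q_iv, rep(cfg$withdrawal_rate, length(sim$time_s)))
})

test_that("valve held LOW settles to the even flow split at half stock concentration", {
  cfg <- demo_system_config("RC2")
  ss <- steady_state(cfg, duty = 0)
  expect_equal(ss$q_ii, cfg$withdrawal_rate / 2)
  expect_equal(ss$q_iii, cfg$withdrawal_rate / 2)
  expect_equal(ss$c_out, 0.5)
  # the simulator finds the same operating point dynamically
  const0 <- target_waveform("samples", duration = 10,
                            samples = data.frame(time_s = c(0, 10),
                                                 value = c(0, 0)))
  sim <- simulate_circuit(cfg, encode_pwm(const0, 0.5), dt = 0.005,
                          include_mixer = FALSE, p_cap0 = 0)
  n <- length(sim$time_s)
  expect_equal(sim$q_ii[n], cfg$withdrawal_rate / 2, tolerance = 1e-6)
  expect_equal(sim$c_iv[n], 0.5, tolerance = 1e-6)
})

test_that("zero height differential produces a constant output regardless of schedule", {
  cfg <- demo_system_config("RC2")
  cfg$high_reservoir$height <- cfg$low_reservoir$height + 1e-12
  w <- target_waveform("sinusoid", frequency = 0.1, duration = 30)
  sim <- simulate_circuit(cfg, encode_pwm(w, 0.5), dt = 0.01,
                          include_mixer = FALSE)
  expect_lt(diff(range(sim$c_iv)), 1e-9)
})

test_that("capacitor response to a valve step matches the closed-form first-order rise", {
  cfg <- isolated_filter_config("RC2", rb_factor = 1e6)
  tau <- with(cfg, filter_resistor$resistance *
                filter_capacitor$capacitance)
  sim <- step_response(cfg, duration = 8 * tau, dt = tau / 50)
  p0 <- sim$p_cap_pa[1]
  p_inf <- steady_state(cfg, duty = 1)$p_cap_pa
  tau_eff <- sim$tau_eff_s
  analytic <- p_inf + (p0 - p_inf) * exp(-sim$time_s / tau_eff)
  expect_lt(max(abs(sim$p_cap_pa - analytic)) / abs(p_inf - p0), 1e-3)
  expect_equal(tau_eff, tau, tolerance = 2e-6)  # R_b >> R_f limit
})

test_that("fitted step-response time constant tracks R*C, doubling with C", {
  cfg <- isolated_filter_config("RC2")
  p <- rc_params("RC2")
  sim <- step_response(cfg, dt = p$tau_s / 100)
  fit <- fit_time_constant(waveform_record(sim$time_s, sim$p_cap_pa))
  expect_equal(fit$tau_s, p$tau_s, tolerance = 0.02)
  # 63.2% of the final value is reached at t ~= tau
  span <- sim$p_cap_pa[length(sim$p_cap_pa)] - sim$p_cap_pa[1]
  level <- sim$p_cap_pa[1] + (1 - exp(-1)) * span
  t_cross <- stats::approx(sim$p_cap_pa, sim$time_s, xout = level)$y
  expect_equal(t_cross, p$tau_s, tolerance = 0.02)
  # doubling the capacitance doubles the fitted tau
  cfg2 <- cfg
  cfg2$filter_capacitor$capacitance <- 2 * cfg$filter_capacitor$capacitance
  sim2 <- step_response(cfg2, dt = p$tau_s / 100)
  fit2 <- fit_time_constant(waveform_record(sim2$time_s, sim2$p_cap_pa))
  expect_equal(fit2$tau_s / fit$tau_s, 2, tolerance = 0.02)
})

test_that("concentrations stay within [0, c_stock] for every waveform shape", {
  cfg <- demo_system_config("RC2")
  for (shape in c("sinusoid", "triangle", "sawtooth", "square")) {
    w <- target_waveform(shape, frequency = 0.1, duration = 30)
    sim <- simulate_circuit(cfg, encode_pwm(w, 0.5), dt = 0.01)
    expect_true(all(sim$c_iv >= 0 & sim$c_iv <= 1), label = shape)
    expect_true(all(sim$c_junction >= 0 & sim$c_junction <= 1),
                label = shape)
  }
})

test_that("extreme settings produce a backflow flag rather than silent clipping", {
  # tiny withdrawal rate: the high-pressure state pushes analyte back up
  # the buffer branch
  cfg <- demo_system_config("RC2", withdrawal_rate = 2.5e-12)
  w <- target_waveform("square", frequency = 0.1, duration = 20)
  sim <- simulate_circuit(cfg, encode_pwm(w, 0.5), dt = 0.01,
                          include_mixer = FALSE)
  expect_true(sim$backflow)
  expect_true(any(sim$q_iii < 0))
  expect_true(all(sim$c_iv <= 1))
  cfg_ok <- demo_system_config("RC2")
  sim_ok <- simulate_circuit(cfg_ok, encode_pwm(w, 0.5), dt = 0.01,
                             include_mixer = FALSE)
  expect_false(sim_ok$backflow)
})

test_that("time step validation enforces resolving the RC dynamics", {
  cfg <- demo_system_config("RC2")
  w <- target_waveform("sinusoid", frequency = 0.1, duration = 10)
  expect_error(simulate_circuit(cfg, encode_pwm(w, 0.5), dt = 0.1),
               "tau/20")
})

test_that("simulated frequency response behaves as a first-order low-pass filter", {
  # DC limit and monotone roll-off on the full demo system
  cfg <- demo_system_config("RC2", mixer = NULL)
  fr <- frequency_response(cfg, c(0.01, 0.1, 0.4), signal = "conc")
  expect_gt(fr$gain[1], 0.98)
  expect_true(all(diff(fr$gain) < 0))
  # |H| = 1/sqrt(2) at the cut-off in the isolated first-order limit
  cfg_iso <- isolated_filter_config("RC2", rb_factor = 1e3)
  tau_eff <- with(cfg_iso, filter_capacitor$capacitance /
                    (1 / filter_resistor$resistance +
                       1 / buffer_resistor$resistance))
  fr_fc <- frequency_response(cfg_iso, cutoff_frequency(tau_eff),
                              signal = "pressure", carrier_period = 0.04,
                              dt = 0.004)
  expect_equal(fr_fc$gain, 1 / sqrt(2), tolerance = 0.05)
})

test_that("system configuration invariants are enforced", {
  lo <- reservoir(0.05, concentration = 1)
  hi <- reservoir(0.10, concentration = 1)
  buf <- reservoir(0.05, concentration = 0)
  r <- fluidic_resistor(2e13)
  cap <- fluidic_capacitor(1.5e-14)
  expect_error(system_config(lo, hi, buf, r, cap, r,
                             withdrawal_rate = 1e-11), "above")
  expect_error(system_config(hi, reservoir(0.05, concentration = 0.5),
                             buf, r, cap, r, withdrawal_rate = 1e-11),
               "same concentration")
  expect_error(system_config(hi, lo, reservoir(0.05, concentration = 0.2),
                             r, cap, r, withdrawal_rate = 1e-11),
               "buffer")
  expect_error(system_config(hi, lo, buf, r, cap, r,
                             withdrawal_rate = 0), "positive")
})

test_that("system configs round-trip through JSON with strict key checking", {
  cfg <- demo_system_config("RC3")
  path <- withr::local_tempfile(fileext = ".json")
  write_system_config(cfg, path)
  back <- read_system_config(path)
  expect_equal(back$filter_resistor$resistance,
               cfg$filter_resistor$resistance)
  expect_equal(back$filter_capacitor$capacitance,
               cfg$filter_capacitor$capacitance)
  expect_equal(back$mixer$length, cfg$mixer$length)
  expect_equal(back$withdrawal_rate, cfg$withdrawal_rate)
  # identical simulations from the round-tripped config
  w <- target_waveform("sinusoid", frequency = 0.1, duration = 10)
  s <- encode_pwm(w, 0.5)
  expect_equal(simulate_circuit(back, s, dt = 0.01)$c_iv,
               simulate_circuit(cfg, s, dt = 0.01)$c_iv)
  # unknown keys are rejected
  x <- jsonlite::read_json(path)
  x$extra_knob <- 1
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(x, bad, auto_unbox = TRUE)
  expect_error(read_system_config(bad), "unknown key")
})
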