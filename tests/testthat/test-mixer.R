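# Mixer chip: axial dispersion low-pass model and transverse FWHM mixing.

herringbone3 <- function(u = 6.25e-4, ...)
  mixer_spec("herringbone", cycles = 3, mean_velocity = u, ...)

test_that("herringbone geometry follows the per-cycle length rule", {
  expect_equal(mixer_spec("herringbone", cycles = 3)$length, 6.9e-3)
  expect_equal(mixer_spec("herringbone", cycles = 1)$length, 2.3e-3)
  expect_error(mixer_spec("herringbone", cycles = 3, length = 5e-3),
               "inconsistent")
  expect_error(mixer_spec("plain"), "length")
})

test_that("axial transfer: delay scales with length, dispersion shrinks with mixing enhancement", {
  u <- 6.25e-4
  yhm <- mixer_transfer(herringbone3(u))
  yom <- mixer_transfer(mixer_spec("obstacle", length = 38.3e-3,
                                   mean_velocity = u))
  expect_equal(yom$transit_delay_s / yhm$transit_delay_s, 38.3 / 6.9,
               tolerance = 1e-9)
  expect_equal(yom$transit_delay_s / yhm$transit_delay_s, 5.55,
               tolerance = 0.001)
  # near-zero length: delay and variance vanish
  tiny <- mixer_transfer(mixer_spec("plain", length = 1e-9,
                                    mean_velocity = u))
  expect_lt(tiny$transit_delay_s, 1e-5)
  expect_lt(tiny$dispersion_variance_s2, 1e-5)
  # stronger mixing suppresses Taylor dispersion (same geometry)
  v1 <- mixer_transfer(herringbone3(u, mixing_enhancement = 1.8))
  v2 <- mixer_transfer(herringbone3(u, mixing_enhancement = 5))
  expect_lt(v2$dispersion_variance_s2, v1$dispersion_variance_s2)
  # all characteristics strictly increasing in length
  lens <- c(2.3e-3, 6.9e-3, 38.3e-3)
  tr <- lapply(lens, function(L)
    mixer_transfer(mixer_spec("plain", length = L, mean_velocity = u)))
  expect_true(all(diff(sapply(tr, `[[`, "transit_delay_s")) > 0))
  expect_true(all(diff(sapply(tr, `[[`, "dispersion_variance_s2")) > 0))
  expect_true(all(diff(sapply(tr, `[[`, "time_constant_s")) > 0))
  expect_error(mixer_transfer(mixer_spec("plain", length = 1e-3)),
               "mean_velocity")
})

test_that("default mixer surrogates land in the tens-of-mHz cut-off band", {
  u <- 2.5e-11 / (200e-6 * 200e-6)   # demo withdrawal rate over mixer section
  for (spec in list(herringbone3(u),
                    mixer_spec("obstacle", length = 38.3e-3,
                               mean_velocity = u))) {
    fc <- cutoff_frequency(mixer_transfer(spec)$time_constant_s)
    expect_gt(fc, 0.015)
    expect_lt(fc, 0.070 * 1.001)
  }
})

test_that("waveforms pass the mixer with DC transparency and frequency-dependent attenuation", {
  spec <- herringbone3()
  dt <- 0.01
  t <- seq(0, 200, by = dt)
  # constant input is untouched
  expect_equal(apply_mixer(rep(0.7, length(t)), spec, dt),
               rep(0.7, length(t)))
  # periodic mean is conserved (interior window, transient discarded)
  amp_after <- function(f) {
    x <- 0.5 + 0.3 * sin(2 * pi * f * t)
    y <- apply_mixer(x, spec, dt)
    win <- t >= 100 & t < 100 + 2 / f
    c(mean = mean(y[win]), amp = (max(y[win]) - min(y[win])) / 2)
  }
  a01 <- amp_after(0.1)
  a04 <- amp_after(0.4)
  expect_equal(unname(a01["mean"]), 0.5, tolerance = 1e-6)
  expect_lt(a04["amp"], a01["amp"])
  expect_lt(a01["amp"], 0.3)            # attenuation, not amplification
})

test_that("an impulse broadens by the dispersion variance plus the filter contribution", {
  spec <- herringbone3()
  tr <- mixer_transfer(spec)
  dt <- 0.01
  t <- seq(0, 150, by = dt)
  x <- numeric(length(t))
  x[t == 30] <- 1
  y <- apply_mixer(x, spec, dt)
  wgt <- y / sum(y)
  mu <- sum(t * wgt)
  v_out <- sum((t - mu)^2 * wgt)
  # Gaussian kernel contributes sigma^2, first-order filter tau^2 = sigma^2
  expect_equal(v_out, tr$dispersion_variance_s2 + tr$time_constant_s^2,
               tolerance = 0.02)
  expect_equal(mu, 30 + tr$transit_delay_s + tr$time_constant_s,
               tolerance = 0.01)
})

test_that("transverse cosine-series profile matches an explicit finite-difference oracle", {
  spec <- herringbone3()
  prof <- simulate_cross_profile(spec, n_points = 101)
  t_tilde <- spec$molecular_diffusivity * spec$mixing_enhancement *
    (spec$length / spec$mean_velocity) / spec$width^2
  oracle <- fd_half_step_profile(t_tilde, 101)
  expect_lt(max(abs(prof$intensity - oracle)), 1e-3)
  # transverse mass conservation at equal inlet flows
  expect_equal(mean(prof$intensity), 0.5, tolerance = 1e-6)
})

test_that("cross-profile limits: unmixed half-step and fully mixed uniform", {
  u <- 6.25e-4
  # short plain channel: transit time << diffusion time across the width
  short <- simulate_cross_profile(mixer_spec("plain", length = 1e-5,
                                             mean_velocity = u),
                                  n_points = 201)
  expect_lt(max(abs(short$intensity[short$positions < 0.45] - 1)), 0.01)
  expect_lt(max(abs(short$intensity[short$positions > 0.55])), 0.01)
  expect_equal(fwhm(short), 0.5, tolerance = 0.01)
  # enormous enhancement: uniform at 0.5
  mixed <- simulate_cross_profile(mixer_spec("plain", length = 38.3e-3,
                                             mean_velocity = u,
                                             mixing_enhancement = 1e4),
                                  n_points = 101)
  expect_equal(mixed$intensity, rep(0.5, 101), tolerance = 1e-6)
  expect_equal(fwhm(mixed), 1.0)
})

test_that("FWHM conventions: ideal geometries and monotone growth with mixing", {
  x <- seq(0, 1, length.out = 101)
  expect_equal(fwhm(cross_channel_profile(x, rep(0.5, 101))), 1.0)
  step <- cross_channel_profile(x, as.numeric(x <= 0.5))
  expect_equal(fwhm(step), 0.5, tolerance = 0.011)
  expect_error(fwhm(cross_channel_profile(x, rep(0, 101))), "zero")
  # FWHM non-decreasing with herringbone cycle count (improved mixing)
  u <- 6.25e-4
  widths <- vapply(1:5, function(cyc)
    fwhm(simulate_cross_profile(mixer_spec("herringbone", cycles = cyc,
                                           mean_velocity = u))),
    numeric(1))
  expect_true(all(diff(widths) >= 0))
  # and saturating toward full width by three cycles and beyond
  expect_gt(widths[3], 0.9 * widths[5])
})

test_that("cross-channel profiles round-trip through delimited text", {
  prof <- simulate_cross_profile(herringbone3(), n_points = 33)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cross_profile(prof, path)
  back <- read_cross_profile(path)
  expect_equal(back$positions, prof$positions)
  expect_equal(back$intensity, prof$intensity, tolerance = 1e-12)
})
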