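# Lumped-element simulation of the full waveform-generator circuit:
# valve-selected gravity source -> filter resistor -> capacitor node ->
# Y-junction <- buffer resistor <- buffer reservoir, with an ideal
# syringe pump withdrawing at constant rate from the junction.
#
# Between valve edges the network is linear with a single state (the
# capacitor pressure), so the integrator uses the exact exponential
# update of that state, stepping exactly onto valve-switch times.

#' Full system configuration
#'
#' The complete hydraulic circuit: two analyte reservoirs (same
#' concentration, different heights) feeding the filter chip through the
#' selection valve, a buffer reservoir feeding the resistor chip, both
#' merging at the Y-junction of the mixer chip, from which an ideal
#' syringe pump withdraws at constant rate.
#'
#' @param high_reservoir,low_reservoir Analyte [reservoir()]s; the high
#'   reservoir must sit strictly above the low one and both must carry
#'   the same concentration.
#' @param buffer_reservoir Buffer [reservoir()]; concentration must be 0.
#' @param filter_resistor,buffer_resistor [fluidic_resistor()]s of the
#'   filter chip and the resistor chip.
#' @param filter_capacitor The filter chip's [fluidic_capacitor()].
#' @param mixer A [mixer_spec()], or `NULL` for no mixer stage. Its
#'   `mean_velocity` is derived from the withdrawal rate and the mixer
#'   cross-section if unset.
#' @param withdrawal_rate Syringe pump withdrawal rate in m^3/s.
#' @param constants A [physical_constants()] object.
#' @return An object of class `system_config`.
#' @export
system_config <- function(high_reservoir, low_reservoir, buffer_reservoir,
                          filter_resistor, filter_capacitor,
                          buffer_resistor, mixer = NULL,
                          withdrawal_rate, constants = physical_constants()) {
  stopifnot(inherits(high_reservoir, "reservoir"),
            inherits(low_reservoir, "reservoir"),
            inherits(buffer_reservoir, "reservoir"),
            inherits(filter_resistor, "fluidic_resistor"),
            inherits(filter_capacitor, "fluidic_capacitor"),
            inherits(buffer_resistor, "fluidic_resistor"))
  if (high_reservoir$height <= low_reservoir$height)
    stop("the high-pressure reservoir must sit above the low-pressure one",
         call. = FALSE)
  if (abs(high_reservoir$concentration - low_reservoir$concentration) > 1e-12)
    stop("both analyte reservoirs must hold the same concentration",
         call. = FALSE)
  if (buffer_reservoir$concentration != 0)
    stop("the buffer reservoir concentration must be 0", call. = FALSE)
  if (!is.finite(withdrawal_rate) || withdrawal_rate <= 0)
    stop("`withdrawal_rate` must be positive", call. = FALSE)
  if (!is.null(mixer)) {
    stopifnot(inherits(mixer, "mixer_spec"))
    if (is.null(mixer$mean_velocity))
      mixer$mean_velocity <- withdrawal_rate / (mixer$width * mixer$depth)
  }
  structure(list(high_reservoir = high_reservoir,
                 low_reservoir = low_reservoir,
                 buffer_reservoir = buffer_reservoir,
                 filter_resistor = filter_resistor,
                 filter_capacitor = filter_capacitor,
                 buffer_resistor = buffer_resistor,
                 mixer = mixer,
                 withdrawal_rate = withdrawal_rate,
                 constants = constants),
            class = "system_config")
}

#' @export
print.system_config <- function(x, ...) {
  cat("<system_config>\n")
  cat(sprintf("  heights (m): high %.3g / low %.3g / buffer %.3g\n",
              x$high_reservoir$height, x$low_reservoir$height,
              x$buffer_reservoir$height))
  cat(sprintf("  R_f = %.4g, R_b = %.4g Pa*s/m^3, C = %.4g m^3/Pa\n",
              x$filter_resistor$resistance, x$buffer_resistor$resistance,
              x$filter_capacitor$capacitance))
  cat(sprintf("  filter tau = %.4g s, withdrawal %.4g m^3/s, mixer: %s\n",
              time_constant(x$filter_resistor, x$filter_capacitor),
              x$withdrawal_rate,
              if (is.null(x$mixer)) "none" else x$mixer$kind))
  invisible(x)
}

#' Demonstration system configurations (RC2 / RC3 / RC4 filter chips)
#'
#' Builds a ready-to-run [system_config()] around one of the three
#' characterized filter chips. Chip resistances are inferred from the
#' measured time constant and capacitance of each chip (`R = tau / C`);
#' the buffer resistor chip matches the filter resistance and the low
#' analyte and buffer reservoirs share the same height, so the circuit
#' satisfies the even-split condition: with the valve held LOW the flow
#' divides equally between the analyte and buffer branches and the outlet
#' sits at half the stock concentration.
#'
#' @param chip `"RC2"`, `"RC3"` or `"RC4"` (membrane cavity diameters 2,
#'   3, 4 mm).
#' @param mixer A [mixer_spec()] (default the three-cycle herringbone) or
#'   `NULL`.
#' @param height_high,height_low Analyte reservoir heights in metres. The
#'   buffer reservoir height equals `height_low`.
#' @param withdrawal_rate Pump rate in m^3/s (default 2.5e-11, i.e.
#'   1.5 uL/min).
#' @return A `system_config`.
#' @export
#' @examples
#' demo_system_config("RC2")
demo_system_config <- function(chip = c("RC2", "RC3", "RC4"),
                               mixer = mixer_spec("herringbone", cycles = 3),
                               height_high = 0.10, height_low = 0.05,
                               withdrawal_rate = 2.5e-11) {
  chip <- match.arg(chip)
  p <- filter_chip_table()[chip, ]
  r_chip <- p$tau_s / p$capacitance_m3_per_pa
  system_config(
    high_reservoir = reservoir(height_high, concentration = 1,
                               label = "high-pressure analyte"),
    low_reservoir = reservoir(height_low, concentration = 1,
                              label = "low-pressure analyte"),
    buffer_reservoir = reservoir(height_low, concentration = 0,
                                 label = "buffer"),
    filter_resistor = fluidic_resistor(r_chip, label = chip),
    filter_capacitor = fluidic_capacitor(p$capacitance_m3_per_pa,
                                         cavity_diameter = p$diameter_m,
                                         label = chip),
    buffer_resistor = fluidic_resistor(r_chip, label = "resistor chip"),
    mixer = mixer,
    withdrawal_rate = withdrawal_rate)
}

#' Measured filter-chip parameter table
#'
#' The three characterized filter chips: membrane cavity diameter,
#' measured step-response time constant, and the capacitance
#' back-calculated from `C = tau / R` with the gravity-flow resistance
#' measurement.
#'
#' @return A data frame with rows `RC2`, `RC3`, `RC4` and columns
#'   `diameter_m`, `tau_s`, `capacitance_m3_per_pa`.
#' @export
filter_chip_table <- function() {
  data.frame(row.names = c("RC2", "RC3", "RC4"),
             diameter_m = c(2e-3, 3e-3, 4e-3),
             tau_s = c(0.316, 0.541, 0.687),
             capacitance_m3_per_pa = c(1.449e-14, 1.693e-14, 2.150e-14))
}

# Linear-network coefficients. With the capacitor node pressure P as the
# single state and the junction collapsed onto it (the filter-to-junction
# segment is lumped into R_f):
#   C dP/dt = (P_s - P)/R_f + (P_buf - P)/R_b - Q_total
# so P relaxes toward P_inf(P_s) with rate k_sum = 1/R_f + 1/R_b.
circuit_coeffs <- function(config) {
  list(p_high = gravity_pressure(config$high_reservoir, config$constants),
       p_low = gravity_pressure(config$low_reservoir, config$constants),
       p_buf = gravity_pressure(config$buffer_reservoir, config$constants),
       r_f = config$filter_resistor$resistance,
       r_b = config$buffer_resistor$resistance,
       cap = config$filter_capacitor$capacitance,
       q_tot = config$withdrawal_rate,
       c_stock = config$high_reservoir$concentration)
}

#' Closed-form steady state of the circuit
#'
#' Steady operating point for a fixed duty cycle `d` (the valve's
#' long-run HIGH fraction; 0 = held LOW, 1 = held HIGH). The effective
#' source pressure is the duty-weighted mean of the two reservoir
#' pressures, and the capacitor pressure, branch flows and outlet
#' concentration follow algebraically.
#'
#' @param config A [system_config()].
#' @param duty Duty cycle in `[0, 1]`.
#' @return A list with `p_cap_pa`, `q_ii`, `q_iii` (m^3/s) and `c_out`
#'   (normalized outlet concentration before mixer smoothing).
#' @export
steady_state <- function(config, duty = 0) {
  cc <- circuit_coeffs(config)
  p_s <- duty * cc$p_high + (1 - duty) * cc$p_low
  k_sum <- 1 / cc$r_f + 1 / cc$r_b
  p_cap <- (p_s / cc$r_f + cc$p_buf / cc$r_b - cc$q_tot) / k_sum
  q_iii <- (cc$p_buf - p_cap) / cc$r_b
  q_ii <- cc$q_tot - q_iii
  c_out <- junction_concentration(q_ii, q_iii, cc$q_tot, cc$c_stock)
  list(p_cap_pa = p_cap, q_ii = q_ii, q_iii = q_iii, c_out = c_out)
}

# Perfect-mixing junction mass balance. When a branch back-flows
# (negative inflow) only the incoming streams set the concentration.
junction_concentration <- function(q_ii, q_iii, q_tot, c_stock) {
  c_out <- c_stock * q_ii / q_tot
  c_out[q_iii < 0] <- c_stock
  c_out[q_ii < 0] <- 0
  pmin(pmax(c_out, 0), c_stock)
}

#' Simulate the hydraulic circuit driven by a PWM schedule
#'
#' Integrates the single-state network over the schedule: the selection
#' valve sets the source pressure to the high- or low-reservoir
#' hydrostatic head; the capacitor pressure obeys
#' `C dP/dt = (P_s - P)/R_f + (P_buf - P)/R_b - Q_total`; branch flows
#' and the junction concentration follow algebraically, enforcing the
#' withdrawal constraint `Q_ii + Q_iii = Q_total` exactly. Between valve
#' edges the system is linear time-invariant, so each step uses the exact
#' exponential update, and the time grid is augmented with every valve
#' switch time (no switching-time aliasing). Node-iv concentration is the
#' junction mass balance passed through [apply_mixer()] when a mixer is
#' configured.
#'
#' @param config A [system_config()].
#' @param schedule A `pwm_schedule` from [encode_pwm()].
#' @param dt Output time step in seconds; must resolve the filter RC
#'   dynamics (`dt <= tau / 20`). Default `tau / 40`.
#' @param include_mixer Apply the mixer stage to the node-iv series
#'   (default `TRUE` when a mixer is configured).
#' @param p_cap0 Initial capacitor pressure in Pa; default the steady
#'   state for the schedule's initial valve state.
#' @return An object of class `simulation_result`: uniform `time_s` plus
#'   per-node flow (`q_i`, `q_ii`, `q_iii`, `q_iv` in m^3/s) and
#'   concentration (`c_i` .. `c_iv`, normalized) series, the capacitor
#'   pressure `p_cap_pa`, and a `backflow` flag set if any branch flow
#'   went negative (simulated faithfully, not clipped).
#' @export
simulate_circuit <- function(config, schedule, dt = NULL,
                             include_mixer = !is.null(config$mixer),
                             p_cap0 = NULL) {
  stopifnot(inherits(config, "system_config"),
            inherits(schedule, "pwm_schedule"))
  cc <- circuit_coeffs(config)
  tau_filter <- cc$r_f * cc$cap
  if (is.null(dt)) dt <- tau_filter / 40
  if (dt > tau_filter / 20 + 1e-12)
    stop(sprintf("dt = %g s too coarse: must be <= tau/20 = %g s",
                 dt, tau_filter / 20), call. = FALSE)
  duration <- schedule$total_duration_s
  if (duration < dt)
    stop("schedule shorter than one time step", call. = FALSE)
  grid <- seq(0, duration, by = dt)
  switches <- schedule$states$start_s
  tt <- sort(unique(c(grid, switches[switches > 0 & switches < duration])))
  on_grid <- tt %in% grid
  state_tt <- valve_state(schedule, tt)    # state over [tt_i, tt_{i+1})
  p_src <- ifelse(state_tt == 1L, cc$p_high, cc$p_low)
  k_sum <- 1 / cc$r_f + 1 / cc$r_b
  tau_eff <- cc$cap / k_sum
  p_inf <- (p_src / cc$r_f + cc$p_buf / cc$r_b - cc$q_tot) / k_sum
  if (is.null(p_cap0)) p_cap0 <- p_inf[1]
  n <- length(tt)
  p_cap <- numeric(n)
  p_cap[1] <- p_cap0
  decay <- exp(-diff(tt) / tau_eff)
  for (i in seq_len(n - 1L)) {
    p_cap[i + 1L] <- p_inf[i] + (p_cap[i] - p_inf[i]) * decay[i]
  }
  q_iii <- (cc$p_buf - p_cap) / cc$r_b
  q_ii <- cc$q_tot - q_iii
  q_i <- (p_src - p_cap) / cc$r_f
  c_pre <- junction_concentration(q_ii, q_iii, cc$q_tot, cc$c_stock)
  # restrict to the uniform output grid
  p_cap_g <- p_cap[on_grid]; q_i_g <- q_i[on_grid]
  q_ii_g <- q_ii[on_grid]; q_iii_g <- q_iii[on_grid]
  c_pre_g <- c_pre[on_grid]
  c_iv <- if (include_mixer && !is.null(config$mixer)) {
    apply_mixer(c_pre_g, config$mixer, dt)
  } else c_pre_g
  structure(list(
    time_s = grid,
    q_i = q_i_g, c_i = rep(cc$c_stock, length(grid)),
    q_ii = q_ii_g, c_ii = rep(cc$c_stock, length(grid)),
    q_iii = q_iii_g, c_iii = rep(0, length(grid)),
    q_iv = rep(cc$q_tot, length(grid)), c_iv = c_iv,
    c_junction = c_pre_g,
    p_cap_pa = p_cap_g,
    backflow = any(q_iii < 0) || any(q_ii < 0),
    dt = dt, config = config, tau_eff_s = tau_eff),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(paste0("<simulation_result> %d steps of %.4g s (%.4g s),",
                     " c_iv in [%.3f, %.3f]%s\n"),
              length(x$time_s), x$dt, max(x$time_s),
              min(x$c_iv), max(x$c_iv),
              if (x$backflow) " [backflow flagged]" else ""))
  invisible(x)
}

#' @export
as.data.frame.simulation_result <- function(x, ...) {
  data.frame(time_s = x$time_s,
             Q_i = x$q_i, c_i = x$c_i,
             Q_ii = x$q_ii, c_ii = x$c_ii,
             Q_iii = x$q_iii, c_iii = x$c_iii,
             Q_iv = x$q_iv, c_iv = x$c_iv,
             P_cap_Pa = x$p_cap_pa)
}

#' Simulate the step response of the configured filter
#'
#' Starts the circuit at the valve-LOW steady state and applies a single
#' LOW-to-HIGH valve transition at `t = 0` (the step extracted from a
#' square-wave drive), producing a record suitable for
#' [fit_time_constant()].
#'
#' @param config A [system_config()].
#' @param duration Simulation length in seconds (default 10 filter time
#'   constants).
#' @param dt Time step in seconds (see [simulate_circuit()]).
#' @param include_mixer Apply the mixer stage (default `FALSE`: the bench
#'   characterization observes the filter output directly).
#' @return A `simulation_result` (see [simulate_circuit()]).
#' @export
step_response <- function(config, duration = NULL, dt = NULL,
                          include_mixer = FALSE) {
  cc <- circuit_coeffs(config)
  tau_filter <- cc$r_f * cc$cap
  if (is.null(duration)) duration <- 10 * tau_filter
  sched <- new_pwm_schedule(
    carrier_period = duration, total_duration = duration,
    states = data.frame(start_s = 0, end_s = duration, state = 1L),
    duty = 1)
  simulate_circuit(config, sched, dt = dt, include_mixer = include_mixer,
                   p_cap0 = steady_state(config, duty = 0)$p_cap_pa)
}

#' Simulated frequency response of the generator
#'
#' Drives the circuit with PWM-encoded full-scale sinusoidal targets at
#' each requested frequency, discards the start-up transient, and
#' measures the gain as the fundamental output amplitude (single-bin
#' Fourier projection) normalized by the DC-limit amplitude computed from
#' the closed-form steady states at duty 0 and duty 1.
#'
#' @param config A [system_config()].
#' @param frequencies Drive frequencies in Hz.
#' @param signal Which output to measure: `"conc"` (node-iv
#'   concentration, the system output) or `"pressure"` (capacitor
#'   pressure, the filter-stage observable).
#' @param n_periods Number of steady periods measured per frequency.
#' @param carrier_period PWM carrier period in seconds, or `NULL` for
#'   `min(0.5, 1 / (20 f))` per frequency.
#' @param dt Time step (see [simulate_circuit()]).
#' @param include_mixer Apply the mixer stage to the concentration output.
#' @return A data frame with columns `frequency_hz`, `gain`, `phase_rad`.
#'   Gain approaches 1 at low frequency and decreases monotonically.
#' @export
frequency_response <- function(config, frequencies,
                               signal = c("conc", "pressure"),
                               n_periods = 6L, carrier_period = NULL,
                               dt = NULL, include_mixer = FALSE) {
  signal <- match.arg(signal)
  cc <- circuit_coeffs(config)
  ss0 <- steady_state(config, 0)
  ss1 <- steady_state(config, 1)
  dc_amp <- switch(signal,
    conc = (ss1$c_out - ss0$c_out) / 2,
    pressure = (ss1$p_cap_pa - ss0$p_cap_pa) / 2)
  mixer_lag <- if (include_mixer && !is.null(config$mixer)) {
    tr <- mixer_transfer(config$mixer)
    tr$transit_delay_s + 5 * tr$time_constant_s
  } else 0
  rows <- lapply(frequencies, function(f) {
    carrier <- if (is.null(carrier_period)) min(0.5, 1 / (20 * f))
               else carrier_period
    tau_eff <- cc$cap / (1 / cc$r_f + 1 / cc$r_b)
    transient <- ceiling((8 * tau_eff + mixer_lag) * f) / f
    duration <- transient + n_periods / f
    w <- target_waveform("sinusoid", frequency = f, duration = duration)
    sim <- simulate_circuit(config, encode_pwm(w, carrier), dt = dt,
                            include_mixer = include_mixer)
    y <- switch(signal, conc = sim$c_iv, pressure = sim$p_cap_pa)
    keep <- sim$time_s >= transient - 1e-9
    t <- sim$time_s[keep]
    z_out <- fourier_projection(y[keep], t, f)
    z_ref <- fourier_projection(waveform_value(w, t), t, f)
    data.frame(frequency_hz = f, gain = Mod(z_out) / abs(dc_amp),
               phase_rad = Arg(z_out / z_ref))
  })
  do.call(rbind, rows)
}

#' Characterize filter chips by simulated step response
#'
#' Replays the bench characterization workflow for a set of filter chips:
#' simulate the step response of each chip in an isolation configuration
#' (buffer branch resistance made 1000x the filter resistance so junction
#' loading is negligible), fit the time constant from the capacitor
#' pressure record, derive the cut-off frequency `1 / (2 pi tau)`, and
#' back-calculate the capacitance `C = tau / R`.
#'
#' @param chips A data frame like [filter_chip_table()]: one row per
#'   chip with columns `diameter_m`, `tau_s`, `capacitance_m3_per_pa`
#'   (the designed/assumed element values; resistances are inferred as
#'   `tau / C`).
#' @param dt Time step in seconds, or `NULL` for `tau / 100` per chip.
#' @return A data frame with one row per chip: `chip`, `diameter_mm`,
#'   `tau_s` (fitted), `cutoff_hz`, `capacitance_m3_per_pa`
#'   (back-calculated).
#' @export
characterize_filter_chips <- function(chips = filter_chip_table(),
                                      dt = NULL) {
  rows <- lapply(rownames(chips), function(nm) {
    p <- chips[nm, ]
    r_chip <- p$tau_s / p$capacitance_m3_per_pa
    cfg <- system_config(
      high_reservoir = reservoir(0.10, concentration = 1),
      low_reservoir = reservoir(0.05, concentration = 1),
      buffer_reservoir = reservoir(0.05, concentration = 0),
      filter_resistor = fluidic_resistor(r_chip, label = nm),
      filter_capacitor = fluidic_capacitor(p$capacitance_m3_per_pa,
                                           cavity_diameter = p$diameter_m),
      buffer_resistor = fluidic_resistor(1e3 * r_chip),
      mixer = NULL,
      withdrawal_rate = 2.5e-11)
    dt_chip <- if (is.null(dt)) p$tau_s / 100 else dt
    sim <- step_response(cfg, duration = 10 * p$tau_s, dt = dt_chip)
    fit <- fit_time_constant(waveform_record(sim$time_s, sim$p_cap_pa))
    data.frame(chip = nm,
               diameter_mm = p$diameter_m * 1e3,
               tau_s = fit$tau_s,
               cutoff_hz = cutoff_frequency(fit$tau_s),
               capacitance_m3_per_pa =
                 capacitance_from_time_constant(fit$tau_s, r_chip))
  })
  do.call(rbind, rows)
}
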