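# fluidpwm

Design, simulation and analysis toolkit for **pulse-width-modulated
(PWM) microfluidic concentration waveform generators** — lab-on-chip
instruments that deliver arbitrary time-varying concentrations of a
soluble factor (drug, dye, cytokine) at a *constant* total flow rate.
It is aimed at microfluidics researchers who want to size such a system
(filter chips, resistor chips, mixers, reservoir heights) before
fabricating it, and at anyone analysing the waveforms such a system
produces.

## The model in brief

Under the electronic-hydraulic analogy (pressure ↔ voltage, volumetric
flow ↔ current), the instrument is a lumped circuit. An electrically
actuated valve selects between two analyte reservoirs of equal
concentration at different heights, producing a pressure pulse train

- ΔP = ρ·g·h (hydrostatic source),
- ΔP = R_H·Q (hydraulic Ohm's law),

that a fluidic first-order RC low-pass filter (serpentine channel
resistor + membrane-capped cavity capacitor) demodulates:

- τ = R·C, f_c = 1/(2πτ).

The filtered analyte stream meets a buffer stream at a Y-junction; a
syringe pump withdraws at constant rate Q_tot, so Q_ii + Q_iii = Q_tot
and the outlet concentration is c = c_stock·Q_ii/Q_tot. The mixer
channel is modelled twice: axially as transit delay + Taylor–Aris
dispersion + a first-order low-pass surrogate acting on the waveform,
and transversely as 1-D diffusion of the junction half-step, scored by
full-width-at-half-maximum (FWHM) mixing analysis. Encoding a target
waveform into valve duty cycles (window-mean PWM), integrating the
circuit (exact exponential updates of the single capacitor state), and
re-measuring the result (period averaging, 63.2% step crossing,
periodogram peaks, Fourier-projection gains) are all first-class,
separately tested operations.

See `vignettes/waveform-generator-model.Rmd` for the full account of
the model, defaults and limitations.

## Worked example

Drive the RC2 demo system (τ = 0.316 s filter, three-cycle herringbone
mixer) with a 100 mHz sinusoidal target:

```r
library(fluidpwm)

cfg <- demo_system_config("RC2")
cfg
#> <system_config>
#>   heights (m): high 0.1 / low 0.05 / buffer 0.05
#>   R_f = 2.181e+13, R_b = 2.181e+13 Pa*s/m^3, C = 1.449e-14 m^3/Pa
#>   filter tau = 0.316 s, withdrawal 2.5e-11 m^3/s, mixer: herringbone

w     <- target_waveform("sinusoid", frequency = 0.1, duration = 60)
sched <- encode_pwm(w, carrier_period = 0.5)
sched
#> <pwm_schedule> carrier 0.5 s, duration 60 s, 120 periods, 240 intervals
#>   duty cycle: mean 0.500, range [0.008, 0.992]

sim <- simulate_circuit(cfg, sched, dt = 0.01)
sim
#> <simulation_result> 6001 steps of 0.01 s (60 s), c_iv in [0.627, 0.950]

keep <- sim$time_s >= 20                      # discard start-up transient
rec  <- waveform_record(sim$time_s[keep], sim$c_iv[keep])
dominant_frequency(rec)
#> [1] 0.1000032
```

The 120 duty cycles average to 0.5 (a full-scale sinusoid), the outlet
concentration swings between ~0.63 and ~0.95 of stock around the
even-split baseline of 0.5, and the delivered waveform's dominant
frequency is the programmed 100 mHz.

Replaying the chip characterization workflow — simulate each chip's
step response, fit τ from the 63.2% crossing, derive f_c and
back-calculate C:

```r
characterize_filter_chips()
#>   chip diameter_mm     tau_s cutoff_hz capacitance_m3_per_pa
#> 1  RC2           2 0.3156459 0.5042199          1.447376e-14
#> 2  RC3           3 0.5403937 0.2945166          1.691103e-14
#> 3  RC4           4 0.6862301 0.2319265          2.147591e-14
```

which recovers the configured chip table (τ = 0.316/0.541/0.687 s,
f_c = 0.504/0.294/0.232 Hz) to well under 2%.

A thin command-line wrapper (`inst/cli/fluidpwm`) exposes the same
pipeline as `design`, `simulate`, `analyze` and `characterize`
subcommands operating on JSON configs (see
`inst/extdata/rc2_system.json`) and delimited time-series files; every
run writes a `.meta.json` sidecar with the resolved parameters.

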