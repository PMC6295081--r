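---
title: "Modelling a PWM microfluidic concentration waveform generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a PWM microfluidic concentration waveform generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidpwm)
```

## The system being modelled

`fluidpwm` models a class of lab-on-chip instruments that deliver
*time-varying* concentrations of a soluble factor (drug, cytokine, dye)
to a downstream culture or sensor while holding the total flow rate
constant. The trick is borrowed from electronics: pulse width modulation
(PWM). A solenoid selection valve toggles between two reservoirs of the
*same* analyte solution held at *different* heights, so the analyte
enters the chip as a train of fast/slow flow pulses. A fluidic
first-order RC low-pass filter (a serpentine resistor channel plus an
elastic-membrane capacitor cavity) averages the pulse train into a
smooth flow-rate signal, which is then titrated into a buffer stream at
a Y-junction and homogenized by a micro-textured mixer channel. A
syringe pump withdraws from the mixer outlet at a constant rate, so
whatever the analyte branch does not supply, the buffer branch does:
flow is constant, concentration follows the programmed duty cycle.

The package implements this chain as composable, separately testable
stages: hydraulic primitives, PWM encoding/decoding, the lumped-element
circuit integrator, the mixer model, the waveform-characterization
estimators, and a synthetic fluorescence readout.

## The electronic-hydraulic analogy

Pressure maps to voltage, volumetric flow to current. Four relations
carry the whole lumped model:

* hydrostatic source: $\Delta P = \rho g h$ (`gravity_pressure()`),
* hydraulic Ohm's law: $\Delta P = R_H Q$ (`flow_from_pressure()`,
  `resistance_from_gravity_flow()`),
* first-order time constant: $\tau = R C$ (`time_constant()`),
* cut-off frequency: $f_c = 1/(2\pi\tau)$ (`cutoff_frequency()`).

Chip resistances are, in practice, measured by gravity-induced flow and
capacitances back-calculated as $C = \tau / R$ from a measured step
response; `filter_chip_table()` records the three reference filter chips
(2, 3, 4 mm membrane cavities, denoted RC2/RC3/RC4) used throughout the
examples, with time constants 0.316, 0.541 and 0.687 s and cut-offs
0.504, 0.294 and 0.232 Hz. Note that the three chips' implied
resistances $\tau/C$ are *not* identical (about $2.18\times10^{13}$ for
RC2 versus $3.20\times10^{13}$ Pa·s/m³ for RC3/RC4); the package
treats resistance as a per-chip quantity and does not force them equal.

For design work, `rectangular_channel_resistance()` provides the
classical Fourier-series Poiseuille resistance of a rectangular duct,
truncated at the eleventh odd term ($n = 21$), which is accurate to well
below 0.01% at every aspect ratio; the test suite cross-checks it
against an independent finite-difference solution of the cross-section
flow to 1%. The default working fluid is water at room temperature
($\rho = 1000$ kg/m³, $\mu = 10^{-3}$ Pa·s), since the intended analyte
is dilute fluorescein in DI water; concentrations are handled throughout
as normalized fractions of the stock solution (0.05 mM fluorescein
$\equiv$ 1.0).

`membrane_capacitance()` implements the clamped-circular-plate
compliance $C = \pi D^6 (1-\nu^2)/(1024 E t^3)$ only as a monotonicity
aid — it explains why capacitance grows steeply with cavity diameter —
and is deliberately not used as ground truth, because fabricated PDMS
membranes are pre-stressed and thickness-variable. Measured
capacitances are supplied as lumped parameters.

## PWM encoding

`encode_pwm()` uses uniform-sampling (window-mean) modulation: the duty
cycle of each carrier period equals the exact analytic mean of the
normalized target over that window, and the HIGH interval leads each
period (single-edge modulation). This choice — rather than
natural-sampling comparison against a triangle carrier — is
deterministic and exactly testable: the duty sequence is checked against
adaptive-quadrature window means to $10^{-9}$.

The carrier must run at least $10\times$ faster than the signal
(violations are rejected with an error); the default carrier period is
0.5 s, i.e. $20\times$ a 100 mHz signal and roughly $4$–$6\times$ above
the filter cut-offs, so carrier ripple lands well into the filter
stop-band. The experimental carrier rate of such instruments is rarely
reported; 0.5 s is this package's documented default, not a measured
value. Valve switching is treated as instantaneous.

`decode_pwm()` is the verification inverse: a sliding-window HIGH-time
fraction, computed exactly from the piecewise-linear cumulative HIGH
time. Its reconstruction RMSE decreases monotonically with carrier rate,
which the suite asserts over a $1.0 \to 0.125$ s carrier sweep.

## The circuit model and its integrator

The simulated network is the minimal one consistent with the hardware
topology: valve-selected pressure source $\to R_f \to$ capacitor node
$\to$ junction; buffer reservoir $\to R_b \to$ junction; junction
$\to$ ideal flow sink $Q_{tot}$. The short filter-to-junction segment is
lumped into $R_f$, and tubing is assumed rigid (parasitic compliance
zero by default). The capacitor pressure $P$ is then the only state:

$$C \frac{dP}{dt} = \frac{P_s(t) - P}{R_f} + \frac{P_{buf} - P}{R_b}
  - Q_{tot},$$

with $P_s(t) \in \{\rho g h_{high}, \rho g h_{low}\}$ set by the valve.
Between valve edges this is linear time-invariant, so
`simulate_circuit()` advances the state with the *exact* exponential
update over each interval, and the time grid is augmented with every
valve switch time. The integrator is therefore unconditionally stable
and machine-accurate against the closed form (asserted to $10^{-3}$ of
the step span, observed near machine precision); the `dt` argument only
controls output resolution, with a guard `dt <= tau/20` so records
resolve the RC dynamics. The withdrawal constraint
$Q_{ii} + Q_{iii} = Q_{tot}$ is enforced algebraically, so flow
conservation holds to rounding error at every step.

Outlet concentration before mixing is the perfect-mixing junction
balance $c = c_{stock} Q_{ii} / Q_{tot}$. Extreme settings can push the
buffer branch negative (analyte flowing *up* the resistor chip); this is
simulated faithfully — the junction then carries undiluted stock — and
flagged on the result (`backflow`) rather than silently clipped.

### Default operating point

Reservoir heights and pump rates of the reference instrument are not
published, so the demo configuration chooses a realistic bench setup
once: high reservoir at 0.10 m, low and buffer reservoirs at 0.05 m,
buffer resistor equal to the filter resistor, withdrawal at
$2.5\times10^{-11}$ m³/s (1.5 µL/min — a typical syringe-pump rate
giving a 0.625 mm/s mean velocity in the 200 µm mixer channel). Equal
low/buffer heights with equal branch resistances realize the even-split
condition: with the valve held LOW, flow divides equally and the outlet
sits at half the stock concentration; duty 1 drives it to ~0.95. Because
absolute amplitudes depend on these unpublished choices, amplitude is
never an acceptance surface — shape, frequency content and time
constants are.

## The mixer model

Axially, the mixer acts on the concentration waveform as a transit
delay $L/U$, Gaussian spreading by Taylor–Aris dispersion, and a
first-order low-pass surrogate. The effective axial diffusivity uses
the rectangular-channel Taylor–Aris form with the transverse mixing
acceleration folded in:

$$D_{eff} = D_m + \frac{U^2 w^2}{210\, D_m\, \eta},$$

where $\eta \ge 1$ is the *mixing enhancement*: chaotic advection from
herringbone grooves or obstacles homogenizes the cross-section faster,
which simultaneously *suppresses* axial Taylor dispersion. The temporal
dispersion variance over the transit is $\sigma^2 = 2 D_{eff} t/U^2$ and
the surrogate filter time constant is taken as $\tau_{mix} = \sigma$
(`mixer_transfer()`; the mapping is exposed and overridable via
`mixing_enhancement`).

$\eta$ is a per-design calibration scalar, not a CFD result. The
defaults (herringbone 1.8, obstacle 1.4, plain 1) were fixed once so
that, at the demo operating point, both reference mixers' surrogate
cut-offs land inside the tens-of-mHz band reported for such mixer chips
(15–70 mHz: the three-cycle herringbone comes out at ~68 mHz, the
38.3 mm obstacle design at ~25 mHz) while preserving the observed
ordering of mixing quality (obstacle $\ge$ 3-cycle herringbone $\gg$
equivalent plain channels). These are calibrated, documented constants —
not measurements.

Transversely, `simulate_cross_profile()` solves 1-D diffusion of the
Y-junction half-step across the width with diffusivity $D_m \eta$ over
the transit time, by a no-flux cosine eigenfunction series (checked
against an explicit finite-difference oracle to $10^{-3}$). The
`fwhm()` score — the interpolated width of the region above half the
profile maximum, with 1.0 for profiles that never dip below half-max —
reproduces the canonical anchors: 0.5 for the unmixed half-step, 1.0
when fully mixed, monotone in cycle count with saturation by about
three herringbone cycles. The 1-D treatment deliberately ignores depth
variation and secondary-flow geometry: it is sufficient for FWHM
ordering, which is the metric of interest, and no attempt is made to
reproduce measured profile curves point-for-point.

## Waveform characterization

`segment_and_average_periods()` implements template period averaging:
the first period is the template, normalized cross-correlation against
the record locates matching sections, and accepted sections are averaged
pointwise. The acceptance threshold (0.7) and minimum peak separation
(0.8 template lengths) are engineering defaults — the underlying
procedure is usually described without thresholds — and both are
arguments. Averaging N periods suppresses i.i.d. noise by about
$1/\sqrt{N}$, which the suite verifies under a fixed seed.

`fit_time_constant()` reports two estimators: the bench definition
(time of the 63.2% crossing of the initial-to-final span, linearly
interpolated) and a least-squares fit of $1 - e^{-t/\tau}$. The final
plateau is the median of the last 10% of samples. For the initial
level, a pre-step plateau median is used when the step time is supplied;
when the record starts at the step (the common simulated case) the first
sample anchors the baseline — a windowed median there would be biased by
the rise itself. On noiseless first-order data the two estimators agree
within 1%; under noise the least-squares estimate is the robust one.

`dominant_frequency()` applies a Hann window before the periodogram and
refines the peak by parabolic interpolation of log power, giving a few
tenths of a bin accuracy; `empirical_frequency_response()` uses
single-bin complex Fourier projections of input and output after
transient removal.

One qualitative behaviour is made quantitative through
`rise_fall_ratio()`: as the drive frequency of a sawtooth rises, the
low-pass stages erode its reset discontinuity and the fall-to-rise time
ratio of the averaged output period climbs toward 1 — the sawtooth
morphs into a triangle. The suite asserts this on the *filter-stage*
output (0.1 vs 0.4 Hz): at the demo operating point the mixer surrogate
attenuates 0.4 Hz so strongly that the post-mixer waveform carries
almost no fundamental to score, which itself reflects the reported
band-limiting role of the mixer.

## Synthetic readout

`concentration_to_grayscale()` emulates the fluorescence-microscope
observation chain: linear calibration (default slope 200, offset 10 —
keeping full scale inside 8-bit range), optional linear drift, seeded
Gaussian noise, clipping and integer quantization (255 by default;
supply `saturation = 65535` for 16-bit). All randomness flows through
the seed in `noise_model()`, restoring the caller's RNG state, so
identical configurations are byte-reproducible. The model does not
attempt 2-D image formation, optics, or shot-noise statistics: it
exists so the analysis chain can be exercised end-to-end (encode →
simulate → grayscale → invert → analyze), and passing those tests
demonstrates estimator correctness under idealized noise, not camera
realism.

## Problem sizes and numerical choices

Simulations in the examples and tests use `dt = 0.005`–`0.01` s
(well under $\tau/20$ for every chip), 20–80 s records, and discard
20 s (about two mixer delays plus several filter time constants) before
spectral analysis, analysing an integer number of periods. The
cross-profile series keeps 100 odd modes; the exact step is returned at
zero diffusion time where the series would Gibbs-ring. Gaussian mixer
kernels are truncated at $4\sigma$ and renormalized; the recursive
low-pass update uses the exact zero-order-hold coefficient
$e^{-dt/\tau}$.

## Known limitations

* Absolute output amplitudes depend on unpublished bench parameters
  (heights, rates, tubing) and are configuration-dependent here.
* The mixer surrogate composes a Gaussian kernel *and* a first-order
  filter of matched width; its total smoothing (variance
  $2\sigma^2$) is a modelling convention, calibrated only through the
  cut-off band.
* No pump pulsation, valve transients, tubing compliance,
  non-Newtonian or inertial effects; membranes are linear lumped
  capacitors.
* The transverse mixer model is 1-D and cannot resolve the 3-D groove
  vortices it parameterizes.
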