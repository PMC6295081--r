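Package: fluidpwm
Title: Pulse-Width-Modulated Microfluidic Concentration Waveform Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design and analysis toolkit for electrically controlled
    microfluidic concentration waveform generators based on pulse width
    modulation (PWM). Encodes target concentration waveforms (sinusoid,
    triangle, sawtooth, square, arbitrary samples) into binary valve
    schedules, simulates the lumped-element hydraulic circuit (gravity-fed
    reservoirs, selection valve, first-order RC low-pass filter chip,
    resistor chip, Y-junction mixer, constant-rate syringe withdrawal)
    using the electronic-hydraulic analogy, models the mixer chip both as
    a Taylor-dispersion low-pass filter and as a transverse diffusion
    problem scored by full-width-at-half-maximum mixing analysis, and
    provides the waveform characterization procedures used for such
    devices: cross-correlation period averaging, step-response time
    constant extraction, cut-off frequency estimation, and empirical
    frequency response. A synthetic-data module emulates the fluorescence
    microscope grayscale readout so the full pipeline can be exercised
    without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
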