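# Synthetic fluorescence-microscope readout: calibration between
# normalized concentration and grayscale intensity, additive noise and
# drift, and 8-bit quantization, so the analysis pipeline can be
# exercised end-to-end without instruments.

#' Concentration-to-grayscale calibration curve
#'
#' Linear calibration between normalized fluorescein concentration and
#' camera grayscale value: `gray = offset + slope * c`, clipped to
#' `[0, saturation]`.
#'
#' @param slope Grayscale units per unit normalized concentration.
#' @param offset Background grayscale level.
#' @param saturation Maximum representable grayscale (default 255, 8-bit
#'   ImageJ convention; use 65535 for 16-bit).
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope = 200, offset = 10, saturation = 255) {
  if (!is.finite(slope) || slope <= 0)
    stop("`slope` must be positive", call. = FALSE)
  if (!is.finite(offset) || offset < 0)
    stop("`offset` must be non-negative", call. = FALSE)
  if (offset + slope > saturation)
    stop("invalid calibration: offset + slope exceeds saturation",
         call. = FALSE)
  structure(list(slope = slope, offset = offset, saturation = saturation),
            class = "calibration_curve")
}

#' Camera noise model
#'
#' @param gaussian_sigma Standard deviation of additive Gaussian noise,
#'   in grayscale units.
#' @param drift_rate Linear drift in grayscale units per second
#'   (photobleaching-like; default 0).
#' @param seed Integer seed; all synthetic randomness flows through it.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 0, drift_rate = 0, seed = 1L) {
  if (!is.finite(gaussian_sigma) || gaussian_sigma < 0)
    stop("`gaussian_sigma` must be non-negative", call. = FALSE)
  structure(list(gaussian_sigma = gaussian_sigma, drift_rate = drift_rate,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Run code under a set seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Render a concentration series as a grayscale record
#'
#' Emulates the fluorescence readout: applies the calibration curve, adds
#' drift and seeded Gaussian noise, clips to the sensor range and rounds
#' to integer grayscale levels.
#'
#' @param time_s Uniform time grid in seconds.
#' @param concentration Normalized concentrations in `[0, 1]`.
#' @param cal A [calibration_curve()].
#' @param noise A [noise_model()].
#' @return A [waveform_record()] of integer grayscale values.
#' @export
concentration_to_grayscale <- function(time_s, concentration,
                                       cal = calibration_curve(),
                                       noise = noise_model()) {
  stopifnot(inherits(cal, "calibration_curve"),
            inherits(noise, "noise_model"))
  if (any(concentration < -1e-9) || any(concentration > 1 + 1e-9))
    stop("`concentration` must lie in [0, 1]", call. = FALSE)
  eps <- if (noise$gaussian_sigma > 0) {
    with_local_seed(noise$seed,
                    stats::rnorm(length(concentration),
                                 sd = noise$gaussian_sigma))
  } else 0
  drift <- noise$drift_rate * (time_s - time_s[1])
  gray <- cal$offset + cal$slope * concentration + drift + eps
  gray <- round(pmin(pmax(gray, 0), cal$saturation))
  waveform_record(time_s, gray, label = "grayscale")
}

#' Invert the calibration: grayscale back to concentration
#'
#' `c = (gray - offset) / slope`, clipped to `[0, 1]`.
#'
#' @param rec A grayscale [waveform_record()].
#' @param cal A [calibration_curve()].
#' @return A [waveform_record()] of normalized concentrations.
#' @export
grayscale_to_concentration <- function(rec, cal = calibration_curve()) {
  stopifnot(inherits(rec, "waveform_record"),
            inherits(cal, "calibration_curve"))
  conc <- pmin(pmax((rec$value - cal$offset) / cal$slope, 0), 1)
  waveform_record(rec$time_s, conc, label = "recovered concentration")
}

#' Synthetic cross-channel profile fixtures
#'
#' Canonical transverse profiles for exercising the FWHM mixing analysis:
#' the unmixed Y-junction half-step, a partially diffused step, and the
#' fully mixed uniform profile, with optional seeded noise.
#'
#' @param kind `"step"`, `"partial"` or `"uniform"`.
#' @param noise_sigma Standard deviation of additive intensity noise
#'   (clipped back into `[0, 1]`).
#' @param n_points Number of transverse positions (>= 16).
#' @param seed Integer seed for the noise.
#' @param smoothing For `"partial"`: dimensionless diffusion time of the
#'   half-step (larger = better mixed); profiles with increasing
#'   `smoothing` form a monotone FWHM sequence.
#' @return A [cross_channel_profile()].
#' @export
make_profile_fixture <- function(kind = c("step", "partial", "uniform"),
                                 noise_sigma = 0, n_points = 64L,
                                 seed = 1L, smoothing = 0.02) {
  kind <- match.arg(kind)
  if (n_points < 16L) stop("`n_points` must be >= 16", call. = FALSE)
  base <- switch(kind,
    step = half_step_profile(0, n_points),
    partial = half_step_profile(smoothing, n_points),
    uniform = cross_channel_profile(seq(0, 1, length.out = n_points),
                                    rep(0.5, n_points)))
  v <- base$intensity
  if (noise_sigma > 0) {
    v <- v + with_local_seed(seed,
                             stats::rnorm(n_points, sd = noise_sigma))
    v <- pmin(pmax(v, 0), 1)
  }
  cross_channel_profile(base$positions, v)
}
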