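# Waveform characterization procedures: cross-correlation period
# segmentation and averaging, step-response time-constant extraction,
# cut-off estimation, dominant-frequency detection, and empirical
# frequency response.

#' Uniformly sampled waveform record
#'
#' The basic container for a recorded or simulated signal: a uniform time
#' grid plus values (normalized concentration, grayscale intensity, flow,
#' pressure, ...).
#'
#' @param time_s Strictly increasing, uniformly spaced times in seconds
#'   (relative jitter below 1e-6 of the step).
#' @param value Finite numeric values, one per time.
#' @param label Optional text label.
#' @return An object of class `waveform_record` with derived field
#'   `sample_rate_hz`.
#' @export
waveform_record <- function(time_s, value, label = "") {
  if (length(time_s) != length(value))
    stop("`time_s` and `value` must have equal length", call. = FALSE)
  if (length(time_s) < 2L)
    stop("a record needs at least two samples", call. = FALSE)
  steps <- diff(time_s)
  dt <- stats::median(steps)
  if (dt <= 0 || any(abs(steps - dt) > 1e-6 * dt))
    stop("`time_s` must be a uniform, increasing grid", call. = FALSE)
  if (any(!is.finite(value)))
    stop("`value` must be finite", call. = FALSE)
  structure(list(time_s = time_s, value = value,
                 sample_rate_hz = 1 / dt, label = label),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record%s> %d samples @ %.4g Hz, %.4g s span\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              length(x$value), x$sample_rate_hz,
              x$time_s[length(x$time_s)] - x$time_s[1]))
  invisible(x)
}

# Normalized cross-correlation of a (zero-mean) template against every lag
# of x, computed via FFT convolution and running window sums.
ncc_against_template <- function(x, template) {
  np <- length(template)
  nl <- length(x) - np + 1L
  tc <- template - mean(template)
  tnorm <- sqrt(sum(tc^2))
  if (tnorm == 0) stop("flat template", call. = FALSE)
  m <- stats::nextn(length(x) + np)
  fx <- stats::fft(c(x, numeric(m - length(x))))
  ft <- stats::fft(c(tc, numeric(m - np)))
  num <- Re(stats::fft(fx * Conj(ft), inverse = TRUE))[1:nl] / m
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  wsum <- cs[(np + 1L):(np + nl)] - cs[1:nl]
  wss <- cs2[(np + 1L):(np + nl)] - cs2[1:nl] - wsum^2 / np
  wss[wss < 0] <- 0
  den <- sqrt(wss) * tnorm
  r <- num / den
  r[den < .Machine$double.eps * np] <- 0
  r
}

#' Segment a periodic record and average its periods
#'
#' Implements template cross-correlation period averaging: the first
#' period of the record is the template; its normalized cross-correlation
#' against the whole record locates the starts of well-matched sections
#' (correlation peaks above `cc_threshold`, separated by at least
#' `min_sep_frac` of a period); the sections are then averaged pointwise
#' to suppress uncorrelated noise.
#'
#' @param rec A [waveform_record()] spanning at least two periods.
#' @param expected_period Period in seconds, or `NULL` to detect it via
#'   [dominant_frequency()].
#' @param cc_threshold Minimum normalized cross-correlation for a section
#'   to be accepted (default 0.7).
#' @param min_sep_frac Minimum peak separation as a fraction of the
#'   template length (default 0.8).
#' @return A list with `averaged` (a one-period [waveform_record()]),
#'   `periods_used`, `period_s` and the accepted `lags_s`.
#' @export
segment_and_average_periods <- function(rec, expected_period = NULL,
                                        cc_threshold = 0.7,
                                        min_sep_frac = 0.8) {
  stopifnot(inherits(rec, "waveform_record"))
  fs <- rec$sample_rate_hz
  if (is.null(expected_period))
    expected_period <- 1 / dominant_frequency(rec)
  np <- round(expected_period * fs)
  n <- length(rec$value)
  if (n < 2L * np)
    stop("record must span at least two periods", call. = FALSE)
  template <- rec$value[1:np]
  r <- ncc_against_template(rec$value, template)
  # local maxima above threshold
  cand <- which(r >= cc_threshold)
  is_peak <- cand[vapply(cand, function(i) {
    (i == 1L || r[i] >= r[i - 1L]) &&
      (i == length(r) || r[i] >= r[i + 1L])
  }, logical(1))]
  # greedy selection by correlation height with minimum separation
  min_sep <- floor(min_sep_frac * np)
  sel <- integer(0)
  for (i in is_peak[order(r[is_peak], decreasing = TRUE)]) {
    if (all(abs(i - sel) >= min_sep)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  sel <- sel[sel + np - 1L <= n]
  if (length(sel) < 2L)
    stop("fewer than two matching periods detected", call. = FALSE)
  sections <- vapply(sel, function(i) rec$value[i:(i + np - 1L)],
                     numeric(np))
  avg <- rowMeans(sections)
  list(averaged = waveform_record((seq_len(np) - 1) / fs, avg,
                                  label = "averaged period"),
       periods_used = length(sel),
       period_s = np / fs,
       lags_s = (sel - 1L) / fs)
}

#' Fit the time constant of a first-order step response
#'
#' Two estimators of `tau` from a rise toward a plateau, mirroring the
#' bench definition: the primary estimate is the time (after the step) at
#' which the signal first crosses 63.2% of the initial-to-final span
#' (linear interpolation between samples); a least-squares fit of
#' `1 - exp(-t / tau)` to the normalized rise is reported alongside. The
#' final plateau is the median of the last 10% of samples. If
#' `step_time_s` is given, the record is assumed to contain a pre-step
#' plateau whose median anchors the initial level (robust to noise);
#' otherwise the step is taken to occur at the first sample, whose value
#' anchors the initial level. Both estimators are invariant to scale and
#' offset.
#'
#' @param step A [waveform_record()] containing a rise toward a plateau.
#' @param step_time_s Time at which the step was applied, or `NULL`
#'   (default) if the record starts at the step.
#' @return An object of class `tau_fit`: list with `tau_s` (63.2%
#'   crossing), `tau_lsq_s` (least squares), `initial`, `final`.
#' @export
fit_time_constant <- function(step, step_time_s = NULL) {
  stopifnot(inherits(step, "waveform_record"))
  n10 <- max(2L, floor(length(step$value) / 10))
  if (is.null(step_time_s)) {
    p0 <- step$value[1]
    t0 <- step$time_s[1]
  } else {
    pre <- step$value[step$time_s < step_time_s]
    p0 <- if (length(pre) >= 2L) stats::median(pre) else step$value[1]
    t0 <- step_time_s
  }
  keep <- step$time_s >= t0
  v <- step$value[keep]
  t <- step$time_s[keep] - t0
  n <- length(v)
  p1 <- stats::median(v[(n - n10 + 1L):n])
  if (abs(p1 - p0) < .Machine$double.eps * max(abs(p0), abs(p1), 1))
    stop("no step found: initial and final plateaus coincide", call. = FALSE)
  y <- (v - p0) / (p1 - p0)
  target <- 1 - exp(-1)          # 0.6321206
  idx <- which(y >= target)
  if (length(idx) == 0L)
    stop("response never crosses 63.2% of its final value", call. = FALSE)
  i <- idx[1]
  tau_cross <- if (i == 1L) t[1] else {
    t[i - 1L] + (target - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 - exp(-t / tau),
                      start = list(tau = max(tau_cross, t[2])),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  tau_lsq <- if (is.null(fit)) NA_real_ else stats::coef(fit)[["tau"]]
  structure(list(tau_s = tau_cross, tau_lsq_s = tau_lsq,
                 initial = p0, final = p1),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("<tau_fit> tau = %.4g s (63.2%% crossing), %.4g s (LSQ)\n",
              x$tau_s, x$tau_lsq_s))
  invisible(x)
}

#' Cut-off frequency from a time constant or step fit
#'
#' Convenience wrapper around [cutoff_frequency()] accepting either a
#' numeric `tau` or a [fit_time_constant()] result.
#'
#' @param tau Time constant in seconds, or a `tau_fit` object.
#' @return Cut-off frequency in Hz.
#' @export
estimate_cutoff <- function(tau) {
  if (inherits(tau, "tau_fit")) tau <- tau$tau_s
  cutoff_frequency(tau)
}

#' Dominant frequency of a record
#'
#' Frequency of the largest nonzero-frequency periodogram peak after mean
#' removal, Hann windowing, and quadratic (parabolic) interpolation of the
#' log-power peak across its neighbouring bins.
#'
#' @param rec A [waveform_record()] spanning at least a few cycles of the
#'   frequency of interest.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(rec) {
  stopifnot(inherits(rec, "waveform_record"))
  x <- rec$value - mean(rec$value)
  if (stats::sd(x) < .Machine$double.eps * (abs(mean(rec$value)) + 1))
    stop("flat signal has no dominant frequency", call. = FALSE)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  X <- stats::fft(x * w)
  half <- floor(n / 2)
  p <- Mod(X[2:(half + 1L)])^2
  k <- which.max(p)
  fs <- rec$sample_rate_hz
  # parabolic refinement on log power (exact for a Gaussian-shaped peak)
  delta <- 0
  if (k > 1L && k < half) {
    lp <- log(pmax(p[(k - 1L):(k + 1L)], .Machine$double.xmin))
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (denom < 0) delta <- 0.5 * (lp[1] - lp[3]) / denom
  }
  (k + delta) * fs / n
}

#' Empirical frequency response from input/output record pairs
#'
#' For each pair, projects both records onto the complex exponential at
#' the stated frequency (single-bin Fourier projection after mean removal
#' and optional transient trimming) and reports the amplitude ratio and
#' phase lag.
#'
#' @param pairs A list of lists, each with elements `input`, `output`
#'   (two [waveform_record()]s on the same grid) and `frequency` (Hz).
#' @param transient_s Leading time to drop from both records before
#'   projecting.
#' @return A data frame with columns `frequency_hz`, `gain`, `phase_rad`.
#' @export
empirical_frequency_response <- function(pairs, transient_s = 0) {
  rows <- lapply(pairs, function(p) {
    inp <- p$input; out <- p$output; f <- p$frequency
    if (length(inp$time_s) != length(out$time_s) ||
        any(abs(inp$time_s - out$time_s) > 1e-9))
      stop("input and output records must share a time grid", call. = FALSE)
    keep <- inp$time_s >= inp$time_s[1] + transient_s
    t <- inp$time_s[keep]
    zi <- fourier_projection(inp$value[keep], t, f)
    zo <- fourier_projection(out$value[keep], t, f)
    data.frame(frequency_hz = f, gain = Mod(zo) / Mod(zi),
               phase_rad = Arg(zo / zi))
  })
  do.call(rbind, rows)
}

# Complex single-bin Fourier projection: 2/N * sum x e^{-i 2 pi f t},
# after mean removal. |.| is the fundamental amplitude for a sinusoid.
fourier_projection <- function(x, t, f) {
  x <- x - mean(x)
  2 * mean(x * exp(-2i * pi * f * t))
}

#' Fall-to-rise time ratio of an averaged period
#'
#' Shape-asymmetry metric for one period of a waveform: the rise time is
#' the (cyclic) time from the minimum to the maximum, the fall time is the
#' remainder of the period, and the ratio `fall / rise` is returned. An
#' ideal sawtooth (slow ramp up, instant reset) gives a ratio near 0; a
#' symmetric triangle or sinusoid gives 1. Useful for quantifying how
#' low-pass filtering morphs a sawtooth toward a triangle as the signal
#' frequency rises.
#'
#' @param rec A one-period [waveform_record()], e.g. the `averaged`
#'   output of [segment_and_average_periods()].
#' @return The dimensionless ratio `fall_time / rise_time`.
#' @export
rise_fall_ratio <- function(rec) {
  stopifnot(inherits(rec, "waveform_record"))
  n <- length(rec$value)
  period <- n / rec$sample_rate_hz
  i_min <- which.min(rec$value)
  i_max <- which.max(rec$value)
  rise <- ((i_max - i_min) %% n) / rec$sample_rate_hz
  if (rise == 0) stop("degenerate period: no distinct extrema", call. = FALSE)
  (period - rise) / rise
}
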