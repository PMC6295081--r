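# PWM encoding of target concentration waveforms into binary valve
# schedules, plus the moving-average decoder used to verify them.

#' Target concentration waveform
#'
#' Describes the analog concentration signal the generator should produce,
#' either as a named parametric shape or as arbitrary (time, value)
#' samples interpolated linearly.
#'
#' @param shape One of `"sinusoid"`, `"triangle"`, `"sawtooth"`,
#'   `"square"`, `"samples"`.
#' @param frequency Signal frequency in Hz (required for parametric
#'   shapes).
#' @param amplitude_low,amplitude_high Normalized concentration bounds,
#'   `0 <= low <= high <= 1`.
#' @param duration Total duration in seconds; must cover at least one full
#'   period for parametric shapes.
#' @param samples For `shape = "samples"`: a data frame with columns
#'   `time_s` and `value` (normalized 0-1), strictly increasing in time.
#' @return An object of class `target_waveform`.
#' @details Shape conventions: the sinusoid starts at its midpoint rising;
#'   the triangle starts at `amplitude_low`, peaks at half period; the
#'   sawtooth ramps linearly from low to high over each period and resets;
#'   the square is high for the first half period (50% duty).
#' @export
#' @examples
#' target_waveform("sinusoid", frequency = 0.1, duration = 60)
target_waveform <- function(shape = c("sinusoid", "triangle", "sawtooth",
                                      "square", "samples"),
                            frequency = NULL, amplitude_low = 0,
                            amplitude_high = 1, duration, samples = NULL) {
  shape <- match.arg(shape)
  if (!is.finite(amplitude_low) || !is.finite(amplitude_high) ||
      amplitude_low < 0 || amplitude_high > 1 ||
      amplitude_low > amplitude_high)
    stop("require 0 <= amplitude_low <= amplitude_high <= 1", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  if (shape == "samples") {
    if (is.null(samples) || !all(c("time_s", "value") %in% names(samples)))
      stop("`samples` must have columns time_s and value", call. = FALSE)
    if (any(diff(samples$time_s) <= 0))
      stop("sample times must be strictly increasing", call. = FALSE)
    if (any(samples$value < 0) || any(samples$value > 1))
      stop("sample values must lie in [0, 1]", call. = FALSE)
    frequency <- NULL
  } else {
    if (is.null(frequency) || !is.finite(frequency) || frequency <= 0)
      stop("parametric shapes require `frequency` > 0", call. = FALSE)
    if (duration < 1 / frequency)
      stop("`duration` must cover at least one full period", call. = FALSE)
  }
  structure(list(shape = shape, frequency = frequency,
                 amplitude_low = amplitude_low,
                 amplitude_high = amplitude_high,
                 duration = duration, samples = samples),
            class = "target_waveform")
}

#' Evaluate a target waveform
#'
#' @param w A [target_waveform()].
#' @param t Times in seconds, each within `[0, duration]`.
#' @return Normalized values in `[0, 1]`, vectorized over `t`.
#' @export
waveform_value <- function(w, t) {
  stopifnot(inherits(w, "target_waveform"))
  if (any(t < -1e-12) || any(t > w$duration + 1e-12))
    stop("`t` outside [0, duration]", call. = FALSE)
  lo <- w$amplitude_low
  span <- w$amplitude_high - w$amplitude_low
  mid <- (w$amplitude_low + w$amplitude_high) / 2
  if (w$shape == "samples") {
    return(stats::approx(w$samples$time_s, w$samples$value, xout = t,
                         rule = 2)$y)
  }
  p <- (w$frequency * t) %% 1
  switch(w$shape,
    sinusoid = mid + span / 2 * sin(2 * pi * w$frequency * t),
    triangle = lo + span * ifelse(p < 0.5, 2 * p, 2 * (1 - p)),
    sawtooth = lo + span * p,
    square   = ifelse(p < 0.5, w$amplitude_high, lo)
  )
}

# Exact mean of the waveform over [a, b]. Parametric shapes integrate in
# closed form (the piecewise-linear ones by splitting at half-period
# breakpoints, where each piece is linear so the midpoint rule is exact).
waveform_window_mean <- function(w, a, b) {
  stopifnot(b > a)
  if (w$shape == "sinusoid") {
    lo <- w$amplitude_low
    span <- w$amplitude_high - lo
    mid <- (lo + w$amplitude_high) / 2
    f <- w$frequency
    return(mid + span / 2 *
             (cos(2 * pi * f * a) - cos(2 * pi * f * b)) /
             (2 * pi * f * (b - a)))
  }
  if (w$shape == "samples") {
    knots <- w$samples$time_s
  } else {
    half <- 1 / (2 * w$frequency)
    knots <- seq(ceiling(a / half), floor(b / half)) * half
  }
  breaks <- sort(unique(c(a, b, knots[knots > a & knots < b])))
  widths <- diff(breaks)
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  sum(widths * waveform_value(w, mids)) / (b - a)
}

new_pwm_schedule <- function(carrier_period, total_duration, states, duty) {
  structure(list(carrier_period_s = carrier_period,
                 total_duration_s = total_duration,
                 states = states, duty = duty),
            class = "pwm_schedule")
}

#' Encode a target waveform as a PWM valve schedule
#'
#' Uniform-sampling (window-mean) pulse width modulation: each carrier
#' period `[kT, (k+1)T)` gets a duty cycle equal to the exact mean of the
#' normalized target over that window; the valve is HIGH for the first
#' `duty * T` seconds of the period and LOW for the rest. Low-pass
#' filtering such a schedule recovers the target.
#'
#' @param w A [target_waveform()]. The normalized target used for the duty
#'   cycle is the waveform value itself (already 0-1).
#' @param carrier_period PWM carrier period in seconds. For parametric
#'   shapes it must satisfy `carrier_period <= 1 / (10 * frequency)`: the
#'   carrier must run at least 10x faster than the signal so that the
#'   ripple is separable from the baseband.
#' @return A `pwm_schedule`: carrier period, total duration, an ordered
#'   data frame of `(start_s, end_s, state)` intervals (state 1 = HIGH
#'   valve position selecting the high-pressure reservoir), and the duty
#'   cycle sequence.
#' @export
#' @examples
#' w <- target_waveform("sinusoid", frequency = 0.1, duration = 10)
#' encode_pwm(w, carrier_period = 0.5)
encode_pwm <- function(w, carrier_period = 0.5) {
  stopifnot(inherits(w, "target_waveform"))
  if (!is.finite(carrier_period) || carrier_period <= 0)
    stop("`carrier_period` must be positive", call. = FALSE)
  if (!is.null(w$frequency) &&
      carrier_period > 1 / (10 * w$frequency) + 1e-12)
    stop(sprintf(paste0("carrier too slow: carrier_period = %g s violates",
                        " the 10x rule (must be <= %g s for a %g Hz",
                        " signal)"),
                 carrier_period, 1 / (10 * w$frequency), w$frequency),
         call. = FALSE)
  n <- ceiling(w$duration / carrier_period - 1e-9)
  starts <- (seq_len(n) - 1) * carrier_period
  ends <- pmin(starts + carrier_period, w$duration)
  duty <- vapply(seq_len(n), function(k)
    waveform_window_mean(w, starts[k], ends[k]), numeric(1))
  duty <- pmin(pmax(duty, 0), 1)
  seg_start <- seg_end <- seg_state <- vector("list", n)
  for (k in seq_len(n)) {
    t0 <- starts[k]; t1 <- ends[k]
    t_switch <- t0 + duty[k] * (t1 - t0)
    if (duty[k] >= 1) {
      seg_start[[k]] <- t0; seg_end[[k]] <- t1; seg_state[[k]] <- 1
    } else if (duty[k] <= 0) {
      seg_start[[k]] <- t0; seg_end[[k]] <- t1; seg_state[[k]] <- 0
    } else {
      seg_start[[k]] <- c(t0, t_switch)
      seg_end[[k]] <- c(t_switch, t1)
      seg_state[[k]] <- c(1, 0)
    }
  }
  states <- data.frame(start_s = unlist(seg_start),
                       end_s = unlist(seg_end),
                       state = as.integer(unlist(seg_state)))
  # merge adjacent intervals with equal state so the schedule is minimal
  keep <- c(TRUE, states$state[-1] != states$state[-nrow(states)])
  merged <- states[keep, , drop = FALSE]
  merged$end_s <- c(states$start_s[which(keep)[-1]], w$duration)
  rownames(merged) <- NULL
  new_pwm_schedule(carrier_period, w$duration, merged, duty)
}

#' Valve state of a schedule at given times
#'
#' @param s A `pwm_schedule`.
#' @param t Times in seconds within `[0, total_duration]`.
#' @return Integer vector of 0 (LOW) / 1 (HIGH) states.
#' @export
valve_state <- function(s, t) {
  stopifnot(inherits(s, "pwm_schedule"))
  idx <- findInterval(pmin(pmax(t, 0), s$total_duration_s - 1e-12),
                      s$states$start_s)
  idx[idx < 1L] <- 1L
  s$states$state[idx]
}

# Cumulative HIGH-time function H(t): piecewise linear with slope 1 inside
# HIGH intervals. Evaluated by linear interpolation on the interval knots.
cumulative_high_time <- function(s) {
  b <- c(s$states$start_s, s$total_duration_s)
  dur <- diff(b)
  H <- c(0, cumsum(dur * s$states$state))
  function(t) stats::approx(b, H, xout = t, rule = 2)$y
}

#' Decode a PWM schedule by moving-average demodulation
#'
#' Computes the fraction of HIGH time inside a sliding window centred at
#' each sample time (clipped at the schedule boundaries). As the carrier
#' period shrinks relative to the signal period, this recovers the encoded
#' target waveform.
#'
#' @param s A `pwm_schedule`.
#' @param window Averaging window length in seconds; must be at least one
#'   carrier period.
#' @param sample_rate Output sampling rate in Hz.
#' @return A [waveform_record()] of duty fraction (0-1) vs time.
#' @export
decode_pwm <- function(s, window, sample_rate = NULL) {
  stopifnot(inherits(s, "pwm_schedule"))
  if (window < s$carrier_period_s - 1e-12)
    stop("`window` must be >= the carrier period", call. = FALSE)
  if (is.null(sample_rate)) sample_rate <- 20 / s$carrier_period_s
  H <- cumulative_high_time(s)
  t <- seq(0, s$total_duration_s, by = 1 / sample_rate)
  a <- pmax(t - window / 2, 0)
  b <- pmin(t + window / 2, s$total_duration_s)
  frac <- (H(b) - H(a)) / (b - a)
  waveform_record(t, frac, label = "decoded duty")
}

#' @export
print.pwm_schedule <- function(x, ...) {
  cat(sprintf(paste0("<pwm_schedule> carrier %.3g s, duration %.4g s,",
                     " %d periods, %d intervals\n"),
              x$carrier_period_s, x$total_duration_s, length(x$duty),
              nrow(x$states)))
  cat(sprintf("  duty cycle: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$duty), min(x$duty), max(x$duty)))
  invisible(x)
}

#' Write / read a PWM schedule
#'
#' The text format is a two-column tab-delimited file (`time_s`, `state`)
#' listing the start time of each valve interval, directly usable as a
#' digital waveform-generator program; carrier period and total duration
#' are carried in `#`-prefixed header lines. The JSON format round-trips
#' the full object.
#'
#' @param s A `pwm_schedule`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"` (default guessed from the file
#'   extension).
#' @return `write_pwm_schedule()` returns `path` invisibly;
#'   `read_pwm_schedule()` returns a `pwm_schedule`.
#' @export
write_pwm_schedule <- function(s, path, format = NULL) {
  stopifnot(inherits(s, "pwm_schedule"))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    jsonlite::write_json(
      list(carrier_period_s = s$carrier_period_s,
           total_duration_s = s$total_duration_s,
           states = s$states, duty = s$duty),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# carrier_period_s\t%.15g", s$carrier_period_s),
                 sprintf("# total_duration_s\t%.15g", s$total_duration_s),
                 "time_s\tstate"), con)
    utils::write.table(data.frame(time_s = s$states$start_s,
                                  state = s$states$state),
                       con, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_pwm_schedule
#' @export
read_pwm_schedule <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    states <- as.data.frame(x$states)
    states$state <- as.integer(states$state)
    return(new_pwm_schedule(x$carrier_period_s, x$total_duration_s,
                            states, as.numeric(x$duty)))
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(key) {
    ln <- hdr[grepl(key, hdr, fixed = TRUE)]
    if (length(ln) != 1L) stop("missing header line: ", key, call. = FALSE)
    as.numeric(sub(".*\t", "", ln))
  }
  carrier <- get_hdr("carrier_period_s")
  total <- get_hdr("total_duration_s")
  body <- utils::read.delim(textConnection(
    lines[!startsWith(lines, "#")]), sep = "\t")
  states <- data.frame(start_s = body$time_s,
                       end_s = c(body$time_s[-1], total),
                       state = as.integer(body$state))
  # duty per carrier period, reconstructed from the interval list
  n <- ceiling(total / carrier - 1e-9)
  H <- cumulative_high_time(
    new_pwm_schedule(carrier, total, states, numeric(0)))
  starts <- (seq_len(n) - 1) * carrier
  ends <- pmin(starts + carrier, total)
  duty <- (H(ends) - H(starts)) / (ends - starts)
  new_pwm_schedule(carrier, total, states, duty)
}
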