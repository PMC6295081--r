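# Lumped hydraulic elements under the electronic-hydraulic analogy:
# pressure <-> voltage, volumetric flow <-> current, channel <-> resistor,
# membrane-capped cavity <-> capacitor.

#' Physical constants for hydraulic calculations
#'
#' @param g Gravitational acceleration in m/s^2.
#' @param viscosity Dynamic viscosity in Pa*s. The default is water at
#'   about 20 degrees C, appropriate for dilute fluorescein in DI water.
#' @return An object of class `physical_constants`.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function(g = 9.81, viscosity = 1.0e-3) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
    stop("`g` must be a single positive number", call. = FALSE)
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0)
    stop("`viscosity` must be a single positive number", call. = FALSE)
  structure(list(g = g, viscosity = viscosity), class = "physical_constants")
}

#' Fluidic resistor element
#'
#' A microfluidic channel restricting flow, characterized by its hydraulic
#' resistance (pressure drop per unit volumetric flow). The resistance can
#' be supplied directly (e.g. measured by gravity-induced flow) or computed
#' from a rectangular channel geometry via
#' [rectangular_channel_resistance()]. If both are supplied they must agree.
#'
#' @param resistance Hydraulic resistance in Pa*s/m^3, or `NULL` to compute
#'   it from the geometry.
#' @param length,width,depth Optional channel geometry in metres.
#' @param viscosity Dynamic viscosity in Pa*s used when computing the
#'   resistance from geometry.
#' @param label Optional text label.
#' @param tol Relative tolerance for the supplied-vs-geometry consistency
#'   check.
#' @return An object of class `fluidic_resistor` with fields `resistance`
#'   (Pa*s/m^3), `geometry` (list or `NULL`) and `label`.
#' @export
#' @examples
#' # serpentine resistor channel, 100 um square cross-section
#' fluidic_resistor(length = 0.05, width = 100e-6, depth = 100e-6)
fluidic_resistor <- function(resistance = NULL, length = NULL, width = NULL,
                             depth = NULL, viscosity = 1.0e-3, label = "",
                             tol = 1e-6) {
  geometry <- NULL
  if (!is.null(length) || !is.null(width) || !is.null(depth)) {
    if (is.null(length) || is.null(width) || is.null(depth))
      stop("geometry requires all of `length`, `width`, `depth`",
           call. = FALSE)
    geometry <- list(length = length, width = width, depth = depth,
                     viscosity = viscosity)
    r_geom <- rectangular_channel_resistance(length, width, depth, viscosity)
    if (is.null(resistance)) {
      resistance <- r_geom
    } else if (abs(resistance - r_geom) > tol * r_geom) {
      stop(sprintf(paste0("supplied resistance %.6g Pa*s/m^3 is inconsistent",
                          " with geometry-derived value %.6g Pa*s/m^3"),
                   resistance, r_geom), call. = FALSE)
    }
  }
  if (is.null(resistance))
    stop("either `resistance` or a full channel geometry is required",
         call. = FALSE)
  if (!is.finite(resistance) || resistance <= 0)
    stop("`resistance` must be positive and finite", call. = FALSE)
  structure(list(resistance = resistance, geometry = geometry, label = label),
            class = "fluidic_resistor")
}

#' Fluidic capacitor element
#'
#' A flexible-membrane-capped cavity that stores liquid volume in
#' proportion to pressure. The capacitance is a supplied lumped parameter
#' (in practice back-calculated from a measured time constant); the cavity
#' diameter is carried as metadata because capacitance grows with it.
#'
#' @param capacitance Fluidic capacitance in m^3/Pa.
#' @param cavity_diameter Optional membrane-covered hole diameter in metres.
#' @param label Optional text label.
#' @return An object of class `fluidic_capacitor`.
#' @export
fluidic_capacitor <- function(capacitance, cavity_diameter = NULL,
                              label = "") {
  if (!is.numeric(capacitance) || length(capacitance) != 1L ||
      !is.finite(capacitance) || capacitance <= 0)
    stop("`capacitance` must be a single positive number", call. = FALSE)
  if (!is.null(cavity_diameter) && (!is.finite(cavity_diameter) ||
                                    cavity_diameter <= 0))
    stop("`cavity_diameter` must be positive", call. = FALSE)
  structure(list(capacitance = capacitance,
                 cavity_diameter = cavity_diameter, label = label),
            class = "fluidic_capacitor")
}

#' Gravity-fed reservoir
#'
#' @param height Liquid height above the chip inlet, in metres.
#' @param density Fluid density in kg/m^3.
#' @param concentration Analyte concentration as a normalized 0-1 fraction
#'   of the stock solution (1 corresponds to the undiluted stock, e.g.
#'   0.05 mM fluorescein).
#' @param label Optional text label.
#' @return An object of class `reservoir`.
#' @export
reservoir <- function(height, density = 1000, concentration = 0, label = "") {
  if (!is.finite(height) || height < 0)
    stop("`height` must be non-negative", call. = FALSE)
  if (!is.finite(density) || density <= 0)
    stop("`density` must be positive", call. = FALSE)
  if (!is.finite(concentration) || concentration < 0 || concentration > 1)
    stop("`concentration` must lie in [0, 1]", call. = FALSE)
  structure(list(height = height, density = density,
                 concentration = concentration, label = label),
            class = "reservoir")
}

#' Hydrostatic pressure of a reservoir
#'
#' Pressure drop available from a reservoir placed at height `h` above the
#' chip inlet: `P = rho * g * h`.
#'
#' @param res A [reservoir()].
#' @param consts A [physical_constants()] object.
#' @return Pressure in Pa.
#' @export
#' @examples
#' gravity_pressure(reservoir(height = 0.05))  # 490.5 Pa
gravity_pressure <- function(res, consts = physical_constants()) {
  stopifnot(inherits(res, "reservoir"), inherits(consts, "physical_constants"))
  res$density * consts$g * res$height
}

#' Volumetric flow through a resistor under a pressure drop
#'
#' Hydraulic Ohm's law: `Q = dP / R_H`.
#'
#' @param delta_p Pressure drop in Pa (may be negative; the flow direction
#'   follows the sign).
#' @param r A [fluidic_resistor()].
#' @return Volumetric flow rate in m^3/s.
#' @export
flow_from_pressure <- function(delta_p, r) {
  stopifnot(inherits(r, "fluidic_resistor"))
  if (r$resistance <= 0)
    stop("ill-posed element: resistance must be positive", call. = FALSE)
  delta_p / r$resistance
}

#' Channel resistance from a gravity-induced flow measurement
#'
#' Combines hydrostatic pressure and hydraulic Ohm's law: with a reservoir
#' of density `rho` at height `h`, a measured flow `Q` implies
#' `R_H = rho * g * h / Q`. This is the standard bench measurement of chip
#' resistance.
#'
#' @param res A [reservoir()] at the measurement height.
#' @param measured_q Measured volumetric flow in m^3/s; must be positive.
#' @param consts A [physical_constants()] object.
#' @return Hydraulic resistance in Pa*s/m^3.
#' @export
resistance_from_gravity_flow <- function(res, measured_q,
                                         consts = physical_constants()) {
  if (!is.finite(measured_q) || measured_q <= 0)
    stop("no flow means an unmeasurable resistance: `measured_q` must be > 0",
         call. = FALSE)
  if (res$height <= 0)
    stop("`res$height` must be positive for a gravity-flow measurement",
         call. = FALSE)
  gravity_pressure(res, consts) / measured_q
}

#' Poiseuille resistance of a rectangular microchannel
#'
#' Laminar, fully developed flow resistance of a rectangular duct of length
#' `L`, width `w` and depth `h`, from the classical Fourier-series solution
#' \deqn{R = \frac{12 \mu L}{w h^3}\left[1 - \sum_{n\ odd}
#'   \frac{192 h}{\pi^5 w}\frac{\tanh(n \pi w / 2h)}{n^5}\right]^{-1}}
#' truncated at n = 21 (accurate to well below 0.01% for all aspect
#' ratios). The convention `width >= depth` is applied internally; the
#' result is symmetric under swapping the two.
#'
#' @param length,width,depth Channel dimensions in metres; all positive.
#' @param viscosity Dynamic viscosity in Pa*s.
#' @param n_terms Number of odd series terms (default 11, i.e. n = 1..21).
#' @return Hydraulic resistance in Pa*s/m^3. Strictly decreasing in width
#'   and depth, linear in length and viscosity.
#' @export
#' @examples
#' rectangular_channel_resistance(0.01, 100e-6, 100e-6)
rectangular_channel_resistance <- function(length, width, depth,
                                           viscosity = 1.0e-3,
                                           n_terms = 11L) {
  vals <- c(length = length, width = width, depth = depth,
            viscosity = viscosity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all channel dimensions and the viscosity must be positive",
         call. = FALSE)
  if (depth > width) {          # formula assumes the wide dimension is `width`
    tmp <- width; width <- depth; depth <- tmp
  }
  n <- seq(1, by = 2, length.out = n_terms)
  series <- sum(tanh(n * pi * width / (2 * depth)) / n^5)
  shape <- 1 - (192 * depth / (pi^5 * width)) * series
  12 * viscosity * length / (width * depth^3 * shape)
}

#' RC time constant of a filter chip
#'
#' `tau = R * C`, the first-order low-pass time constant of a resistor
#' paired with a membrane capacitor.
#'
#' @param r A [fluidic_resistor()].
#' @param c A [fluidic_capacitor()].
#' @return Time constant in seconds.
#' @export
time_constant <- function(r, c) {
  stopifnot(inherits(r, "fluidic_resistor"), inherits(c, "fluidic_capacitor"))
  r$resistance * c$capacitance
}

#' Cut-off frequency of a first-order low-pass filter
#'
#' `f_c = 1 / (2 * pi * tau)`, the -3 dB point.
#'
#' @param tau Time constant in seconds; must be positive.
#' @return Cut-off frequency in Hz.
#' @export
#' @examples
#' cutoff_frequency(0.316)  # ~0.504 Hz
cutoff_frequency <- function(tau) {
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("`tau` must be positive", call. = FALSE)
  1 / (2 * pi * tau)
}

#' Capacitance from a measured time constant
#'
#' The bench route to the actual (as-fabricated) capacitance: measure the
#' chip resistance by gravity flow, measure the step-response time
#' constant, then `C = tau / R`.
#'
#' @param tau Measured time constant in seconds; positive.
#' @param resistance Measured hydraulic resistance in Pa*s/m^3; positive.
#' @return Capacitance in m^3/Pa.
#' @export
capacitance_from_time_constant <- function(tau, resistance) {
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("`tau` must be positive", call. = FALSE)
  if (any(!is.finite(resistance)) || any(resistance <= 0))
    stop("`resistance` must be positive", call. = FALSE)
  tau / resistance
}

#' Clamped circular-plate membrane capacitance model
#'
#' Small-deflection volume-per-pressure compliance of a clamped circular
#' elastic membrane of diameter `diameter` and thickness `thickness`:
#' `C = pi * D^6 * (1 - nu^2) / (1024 * E * t^3)`. This is provided as a
#' monotonicity aid (capacitance grows steeply with cavity diameter), not
#' as ground truth for fabricated chips, whose membranes are pre-stressed
#' and imperfect; measured capacitances should be supplied to
#' [fluidic_capacitor()] directly.
#'
#' @param diameter Cavity (membrane) diameter in metres.
#' @param youngs_modulus Membrane Young's modulus in Pa (default typical
#'   of PDMS, 1.5 MPa).
#' @param thickness Membrane thickness in metres.
#' @param poisson Poisson ratio (default 0.5, nearly incompressible
#'   elastomer).
#' @return Capacitance in m^3/Pa; strictly increasing in `diameter`.
#' @export
membrane_capacitance <- function(diameter, youngs_modulus = 1.5e6,
                                 thickness = 100e-6, poisson = 0.5) {
  if (any(diameter <= 0) || youngs_modulus <= 0 || thickness <= 0)
    stop("dimensions and modulus must be positive", call. = FALSE)
  pi * diameter^6 * (1 - poisson^2) / (1024 * youngs_modulus * thickness^3)
}

#' @export
print.fluidic_resistor <- function(x, ...) {
  cat(sprintf("<fluidic_resistor%s> R = %.4g Pa*s/m^3\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$resistance))
  if (!is.null(x$geometry))
    cat(sprintf("  geometry: L = %g m, w = %g m, h = %g m\n",
                x$geometry$length, x$geometry$width, x$geometry$depth))
  invisible(x)
}

#' @export
print.fluidic_capacitor <- function(x, ...) {
  cat(sprintf("<fluidic_capacitor%s> C = %.4g m^3/Pa%s\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$capacitance,
              if (!is.null(x$cavity_diameter))
                sprintf(", D0 = %g m", x$cavity_diameter) else ""))
  invisible(x)
}

#' @export
print.reservoir <- function(x, ...) {
  cat(sprintf("<reservoir%s> h = %g m, rho = %g kg/m^3, c = %g\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$height, x$density, x$concentration))
  invisible(x)
}
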