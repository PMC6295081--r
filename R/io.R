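# File interchange: JSON hardware configs (strictly validated, all
# physical quantities carrying explicit units in their key names),
# delimited node time series, and JSON analysis reports / metadata
# sidecars.

reservoir_to_json <- function(res) {
  list(height_m = res$height, density_kg_m3 = res$density,
       concentration_norm = res$concentration, label = res$label)
}

check_keys <- function(x, required, optional = character(0), where) {
  nm <- names(x)
  missing <- setdiff(required, nm)
  if (length(missing))
    stop(sprintf("config error in %s: missing key(s) %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(nm, c(required, optional))
  if (length(unknown))
    stop(sprintf("config error in %s: unknown key(s) %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  invisible(x)
}

reservoir_from_json <- function(x, where) {
  check_keys(x, c("height_m", "density_kg_m3", "concentration_norm"),
             optional = "label", where = where)
  reservoir(x$height_m, x$density_kg_m3, x$concentration_norm,
            label = x$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a system configuration as JSON
#'
#' The on-disk schema mirrors the hardware: reservoirs carry `height_m`,
#' `density_kg_m3`, `concentration_norm`; resistors carry
#' `resistance_pa_s_per_m3`; the capacitor carries
#' `capacitance_m3_per_pa` and optionally `cavity_diameter_m`; the mixer
#' block carries geometry and transport parameters; plus
#' `withdrawal_rate_m3_per_s` and a `constants` block. Unknown keys are
#' rejected.
#'
#' @param config A [system_config()].
#' @param path JSON file path.
#' @return `write_system_config()` returns `path` invisibly;
#'   `read_system_config()` returns a `system_config`.
#' @export
write_system_config <- function(config, path) {
  stopifnot(inherits(config, "system_config"))
  out <- list(
    high_reservoir = reservoir_to_json(config$high_reservoir),
    low_reservoir = reservoir_to_json(config$low_reservoir),
    buffer_reservoir = reservoir_to_json(config$buffer_reservoir),
    filter_resistor = list(
      resistance_pa_s_per_m3 = config$filter_resistor$resistance,
      label = config$filter_resistor$label),
    filter_capacitor = list(
      capacitance_m3_per_pa = config$filter_capacitor$capacitance,
      cavity_diameter_m = config$filter_capacitor$cavity_diameter,
      label = config$filter_capacitor$label),
    buffer_resistor = list(
      resistance_pa_s_per_m3 = config$buffer_resistor$resistance,
      label = config$buffer_resistor$label),
    withdrawal_rate_m3_per_s = config$withdrawal_rate,
    constants = list(g_m_per_s2 = config$constants$g,
                     viscosity_pa_s = config$constants$viscosity))
  if (!is.null(config$mixer)) {
    m <- config$mixer
    out$mixer <- list(kind = m$kind, cycles = m$cycles,
                      length_m = m$length, width_m = m$width,
                      depth_m = m$depth,
                      molecular_diffusivity_m2_per_s =
                        m$molecular_diffusivity,
                      mixing_enhancement = m$mixing_enhancement)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_system_config
#' @export
read_system_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(x, required = c("high_reservoir", "low_reservoir",
                             "buffer_reservoir", "filter_resistor",
                             "filter_capacitor", "buffer_resistor",
                             "withdrawal_rate_m3_per_s"),
             optional = c("mixer", "constants"), where = path)
  check_keys(x$filter_resistor, "resistance_pa_s_per_m3",
             optional = "label", where = "filter_resistor")
  check_keys(x$filter_capacitor, "capacitance_m3_per_pa",
             optional = c("cavity_diameter_m", "label"),
             where = "filter_capacitor")
  check_keys(x$buffer_resistor, "resistance_pa_s_per_m3",
             optional = "label", where = "buffer_resistor")
  consts <- if (is.null(x$constants)) physical_constants() else {
    check_keys(x$constants, character(0),
               optional = c("g_m_per_s2", "viscosity_pa_s"),
               where = "constants")
    physical_constants(g = x$constants$g_m_per_s2 %||% 9.81,
                       viscosity = x$constants$viscosity_pa_s %||% 1e-3)
  }
  mixer <- NULL
  if (!is.null(x$mixer)) {
    check_keys(x$mixer, "kind",
               optional = c("cycles", "length_m", "width_m", "depth_m",
                            "molecular_diffusivity_m2_per_s",
                            "mixing_enhancement"),
               where = "mixer")
    mixer <- mixer_spec(
      kind = x$mixer$kind, cycles = x$mixer$cycles,
      length = x$mixer$length_m,
      width = x$mixer$width_m %||% 200e-6,
      depth = x$mixer$depth_m %||% 200e-6,
      molecular_diffusivity =
        x$mixer$molecular_diffusivity_m2_per_s %||% 4.25e-10,
      mixing_enhancement = x$mixer$mixing_enhancement)
  }
  system_config(
    high_reservoir = reservoir_from_json(x$high_reservoir, "high_reservoir"),
    low_reservoir = reservoir_from_json(x$low_reservoir, "low_reservoir"),
    buffer_reservoir = reservoir_from_json(x$buffer_reservoir,
                                           "buffer_reservoir"),
    filter_resistor = fluidic_resistor(
      x$filter_resistor$resistance_pa_s_per_m3,
      label = x$filter_resistor$label %||% ""),
    filter_capacitor = fluidic_capacitor(
      x$filter_capacitor$capacitance_m3_per_pa,
      cavity_diameter = x$filter_capacitor$cavity_diameter_m,
      label = x$filter_capacitor$label %||% ""),
    buffer_resistor = fluidic_resistor(
      x$buffer_resistor$resistance_pa_s_per_m3,
      label = x$buffer_resistor$label %||% ""),
    mixer = mixer,
    withdrawal_rate = x$withdrawal_rate_m3_per_s,
    constants = consts)
}

#' Write / read simulated node time series
#'
#' Tab-delimited text with a header line and columns `time_s`, `Q_i`,
#' `c_i`, `Q_ii`, `c_ii`, `Q_iii`, `c_iii`, `Q_iv`, `c_iv`, `P_cap_Pa`
#' (flows in m^3/s, concentrations normalized, pressure in Pa).
#'
#' @param sim A `simulation_result` from [simulate_circuit()].
#' @param path Output file path.
#' @param nodes Optional subset of nodes to write, e.g. `c("ii", "iv")`;
#'   `time_s` is always included.
#' @return `write_simulation_result()` returns `path` invisibly;
#'   `read_timeseries()` returns a data frame.
#' @export
write_simulation_result <- function(sim, path, nodes = NULL) {
  d <- as.data.frame(sim)
  if (!is.null(nodes)) {
    keep <- c("time_s",
              unlist(lapply(nodes, function(nd)
                c(paste0("Q_", nd), paste0("c_", nd)))),
              if ("iv" %in% nodes || is.null(nodes)) "P_cap_Pa")
    keep <- intersect(keep, names(d))
    d <- d[, keep, drop = FALSE]
  }
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_simulation_result
#' @param ... Passed to [utils::read.delim()].
#' @export
read_timeseries <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#", ...)
}

# Metadata sidecar written next to every CLI output: the fully resolved
# parameters, seed, package version and timestamp.
write_metadata_sidecar <- function(path, params, seed = NULL) {
  meta <- list(
    tool = "fluidpwm",
    version = as.character(utils::packageVersion("fluidpwm")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(meta)
}
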