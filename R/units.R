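# Unit systems and temperature <-> coldness conversion.
#
# All rate-law arithmetic works in "coldness" beta = 1/(kB*T), stored in
# reciprocal energy units.  The unit system fixes the energy unit and the
# matching value of the Boltzmann constant, so that T (K) and beta
# round-trip exactly.

.kB_values <- c(
  "kJ/mol"   = 0.0083144626,    # molar gas constant R in kJ/(mol K)
  "kcal/mol" = 0.0019872041,
  "eV"       = 8.617333262e-5,
  "kB.K"     = 1                # natural units: energies measured in kB*K
)

.normalize_energy_unit <- function(unit) {
  u <- gsub("\\s", "", tolower(unit))
  key <- switch(u,
    "kj/mol" = "kJ/mol",
    "kcal/mol" = "kcal/mol",
    "ev" = "eV",
    "kb.k" = , "kbk" = , "kb*k" = , "kbt" = "kB.K",
    NULL
  )
  if (is.null(key)) {
    tv_stop(sprintf(
      "unknown energy unit '%s' (use one of: %s)",
      unit, paste(names(.kB_values), collapse = ", ")
    ), "tv_invalid_parameter")
  }
  key
}

#' Define a unit system for rate data
#'
#' Fixes the energy unit used for activation energies and coldness
#' \eqn{\beta = 1/(k_B T)}, together with the corresponding value of the
#' Boltzmann constant per kelvin.  Temperatures are always in kelvin.
#'
#' @param energy_unit One of \code{"kJ/mol"}, \code{"kcal/mol"},
#'   \code{"eV"}, or \code{"kB.K"} (natural units, energies in units of
#'   \eqn{k_B} kelvin so that \eqn{k_B = 1}).
#' @return An object of class \code{"unit_system"}: a list with fields
#'   \code{energy_unit}, \code{temperature_unit} (\code{"K"}) and
#'   \code{boltzmann} (the value of \eqn{k_B} in \code{energy_unit} per K).
#' @examples
#' u <- unit_system("kJ/mol")
#' beta_from_temperature(300, u)
#' @export
unit_system <- function(energy_unit = "kJ/mol") {
  key <- .normalize_energy_unit(energy_unit)
  structure(
    list(
      energy_unit = key,
      temperature_unit = "K",
      boltzmann = unname(.kB_values[key])
    ),
    class = "unit_system"
  )
}

#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf("<unit_system> energy in %s, T in %s, kB = %.10g %s/K\n",
              x$energy_unit, x$temperature_unit, x$boltzmann, x$energy_unit))
  invisible(x)
}

.as_units <- function(units) {
  if (inherits(units, "unit_system")) return(units)
  if (is.character(units) && length(units) == 1) return(unit_system(units))
  if (is.null(units)) return(unit_system())
  tv_stop("'units' must be a unit_system object or an energy-unit string",
          "tv_invalid_parameter")
}

#' Convert temperature to coldness
#'
#' @param temperature Temperature(s) in kelvin, all > 0.
#' @param units A \code{\link{unit_system}} (or energy-unit string).
#' @return \eqn{\beta = 1/(k_B T)} in reciprocal energy units.
#' @export
beta_from_temperature <- function(temperature, units = unit_system()) {
  units <- .as_units(units)
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    tv_stop("temperatures must be finite and > 0 K", "tv_invalid_parameter")
  }
  1 / (units$boltzmann * temperature)
}

#' Convert coldness to temperature
#'
#' @param beta Coldness value(s), reciprocal energy, all > 0.
#' @inheritParams beta_from_temperature
#' @return Temperature in kelvin.
#' @export
temperature_from_beta <- function(beta, units = unit_system()) {
  units <- .as_units(units)
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    tv_stop("beta must be finite and > 0", "tv_invalid_parameter")
  }
  1 / (units$boltzmann * beta)
}
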