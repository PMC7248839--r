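# The empirical object both planes are built from: ordered (beta, k)
# observations with a unit system attached.

#' Construct a rate dataset
#'
#' An ordered set of (coldness, rate) observations.  Provide either
#' \code{beta} directly or \code{temperature} in kelvin (converted once
#' through the unit system).  Observations are sorted by increasing
#' \code{beta}; all rates must be strictly positive (fitting is done on
#' \eqn{\ln k}).
#'
#' @param beta Coldness values (reciprocal energy), strictly positive.
#' @param k Rate constants, strictly positive, any consistent rate unit.
#' @param temperature Alternative to \code{beta}: temperatures in K.
#' @param units A \code{\link{unit_system}}.
#' @param weights Optional positive weights for \eqn{\ln k} residuals.
#' @return An object of class \code{"rate_dataset"}.
#' @export
rate_dataset <- function(beta = NULL, k, temperature = NULL,
                         units = unit_system(), weights = NULL) {
  units <- .as_units(units)
  if (is.null(beta)) {
    if (is.null(temperature)) {
      tv_stop("provide either beta or temperature", "tv_input_error")
    }
    beta <- beta_from_temperature(temperature, units)
  }
  if (length(beta) != length(k)) {
    tv_stop("beta and k must have the same length", "tv_input_error")
  }
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    tv_stop("beta values must be finite and > 0", "tv_input_error")
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    tv_stop("all rate constants must be finite and > 0", "tv_input_error")
  }
  if (!is.null(weights)) {
    if (length(weights) != length(k) || any(weights <= 0)) {
      tv_stop("weights must be positive and match the data length",
              "tv_input_error")
    }
  }
  ord <- order(beta)
  if (anyDuplicated(beta)) {
    tv_stop("beta values must be distinct (average duplicates first, see read_rate_table)",
            "tv_input_error")
  }
  structure(list(
    beta = beta[ord],
    k = k[ord],
    weights = if (is.null(weights)) rep(1, length(k)) else weights[ord],
    units = units
  ), class = "rate_dataset")
}

#' @export
print.rate_dataset <- function(x, ...) {
  cat(sprintf(
    "<rate_dataset> %d points, beta in [%.5g, %.5g] (%s)^-1, T in [%.4g, %.4g] K\n",
    length(x$beta), min(x$beta), max(x$beta), x$units$energy_unit,
    temperature_from_beta(max(x$beta), x$units),
    temperature_from_beta(min(x$beta), x$units)))
  invisible(x)
}

#' @export
as.data.frame.rate_dataset <- function(x, ...) {
  data.frame(
    beta = x$beta,
    T_K = temperature_from_beta(x$beta, x$units),
    k = x$k,
    weight = x$weights
  )
}

#' @export
length.rate_dataset <- function(x) length(x$beta)
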