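# Closed-form rate laws k(beta), apparent activation energies Ea(beta) and
# transitivity functions gamma(beta) = 1/Ea(beta) for the Arrhenius,
# deformed-Arrhenius (Aquilanti-Mundim, AM), Vogel-Fulcher-Tammann (VFT)
# and Fowler-Guggenheim (FG) families, plus the generalized transitivity
# power law gamma(beta) = (1/eps)(1 - beta/beta_dagger)^zeta whose
# exponent zeta = 0, 1, 2 regenerates Arrhenius, AM and VFT.

.check_A <- function(A) {
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A) || A <= 0) {
    tv_stop("pre-exponential factor A must be a single finite value > 0",
            "tv_invalid_parameter")
  }
}

.check_beta <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    tv_stop("beta must be finite numeric", "tv_invalid_parameter")
  }
  if (any(beta < 0)) {
    tv_stop("beta must be >= 0 (coldness is non-negative)", "tv_domain_error")
  }
}

#' Arrhenius rate law
#'
#' \eqn{k(\beta) = A e^{-\epsilon^\ddagger \beta}} with constant apparent
#' activation energy \eqn{\epsilon^\ddagger}.
#'
#' @param beta Coldness \eqn{1/(k_B T)}, scalar or vector, >= 0.
#' @param A Pre-exponential factor, > 0, in any rate unit.
#' @param eps_act Activation energy \eqn{\epsilon^\ddagger} in the energy
#'   unit matching \code{beta}.
#' @return Rate constant(s), same length as \code{beta}.
#' @export
k_arrhenius <- function(beta, A, eps_act) {
  .check_A(A); .check_beta(beta)
  A * exp(-eps_act * beta)
}

#' Deformed-exponential (Aquilanti-Mundim) rate law
#'
#' \eqn{k(\beta) = A (1 - d\,\epsilon^\ddagger \beta)^{1/d}}.  The
#' deformation parameter \code{d} indexes the curvature of the Arrhenius
#' plot: \code{d < 0} concave (sub-Arrhenius, tunneling), \code{d > 0}
#' convex (super-Arrhenius, collective/classical), \code{d = 0} the exact
#' Arrhenius law.  For \code{d > 0} the law only exists below the thermal
#' limit \eqn{\beta^\dagger = 1/(d\,\epsilon^\ddagger)}; at
#' \eqn{\beta = \beta^\dagger} the continuous extension \eqn{k = 0} is
#' returned unless \code{strict = TRUE}.
#'
#' @inheritParams k_arrhenius
#' @param d Deformation parameter (dimensionless).
#' @param strict If \code{TRUE}, hitting the domain boundary exactly is an
#'   error rather than the continuous extension \code{k = 0}.
#' @return Rate constant(s).
#' @export
k_am <- function(beta, A, eps_act, d, strict = FALSE) {
  .check_A(A); .check_beta(beta)
  if (d == 0) return(k_arrhenius(beta, A, eps_act))
  u <- 1 - d * eps_act * beta
  if (any(u < 0) || (strict && any(u == 0))) {
    bd <- 1 / (d * eps_act)
    tv_stop(sprintf(
      "beta outside the AM domain: 1 - d*eps_act*beta <= 0 (thermal limit beta_dagger = %.10g)",
      bd), "tv_domain_error")
  }
  # log1p keeps full precision down to the Arrhenius limit d -> 0
  k <- A * exp(log1p(-d * eps_act * beta) / d)
  # continuous extension at the boundary for super-Arrhenius laws
  k[u == 0] <- if (1 / d > 0) 0 else Inf
  k
}

#' Vogel-Fulcher-Tammann rate law
#'
#' \eqn{k(\beta) = A \exp[-\epsilon^\ddagger \beta/(1 - \beta/\beta^\dagger)]},
#' the \eqn{\zeta = 2} member of the generalized transitivity family,
#' ubiquitous for transport coefficients near a glass transition.
#'
#' @inheritParams k_arrhenius
#' @param beta_dagger Divergence coldness \eqn{\beta^\dagger > 0}; the law
#'   is defined for \eqn{0 \le \beta < \beta^\dagger}.
#' @return Rate constant(s).
#' @export
k_vft <- function(beta, A, eps_act, beta_dagger) {
  .check_A(A); .check_beta(beta)
  if (!is.finite(beta_dagger) || beta_dagger <= 0) {
    tv_stop("beta_dagger must be finite and > 0", "tv_invalid_parameter")
  }
  if (any(beta >= beta_dagger)) {
    tv_stop(sprintf("beta must be < beta_dagger = %.10g for the VFT law",
                    beta_dagger), "tv_domain_error")
  }
  A * exp(-eps_act * beta / (1 - beta / beta_dagger))
}

.check_s <- function(s) {
  if (!is.numeric(s) || length(s) != 1 || !is.finite(s) || s < 1 ||
      s != round(s)) {
    tv_stop("s must be an integer >= 1 (internal degrees of freedom)",
            "tv_invalid_parameter")
  }
}

#' Fowler-Guggenheim unimolecular rate law (finite series form)
#'
#' Rate of a unimolecular process whose activation energy
#' \eqn{\epsilon^\ddagger} can be accumulated over \code{s} internal
#' oscillators:
#' \eqn{k(\beta) = A e^{-x} \sum_{r=0}^{s-1} x^r/r!} with
#' \eqn{x = \epsilon^\ddagger\beta}.  \code{s = 1} reduces to Arrhenius.
#'
#' @inheritParams k_arrhenius
#' @param s Integer >= 1, number of internal degrees of freedom.
#' @return Rate constant(s).
#' @export
k_fg_series <- function(beta, A, eps_act, s) {
  .check_A(A); .check_beta(beta); .check_s(s)
  x <- eps_act * beta
  r <- 0:(s - 1)
  vapply(x, function(xi) {
    # log-space terms; pmax keeps the r = 0 term finite at x = 0
    lx <- log(pmax(xi, .Machine$double.xmin))
    A * exp(-xi) * sum(exp(r * lx - lgamma(r + 1)))
  }, numeric(1))
}

#' Fowler-Guggenheim rate law (incomplete-gamma closed form)
#'
#' Identical to \code{\link{k_fg_series}} but through the upper incomplete
#' gamma function: \eqn{k(\beta) = A\,\Gamma(s, x)/\Gamma(s)},
#' \eqn{x = \epsilon^\ddagger\beta}, i.e. \code{A} times the regularized
#' upper incomplete gamma \eqn{Q(s, x)}.
#'
#' @inheritParams k_fg_series
#' @return Rate constant(s).
#' @export
k_fg_closed <- function(beta, A, eps_act, s) {
  .check_A(A); .check_beta(beta); .check_s(s)
  x <- eps_act * beta
  A * stats::pgamma(x, shape = s, lower.tail = FALSE)
}

#' Deformation parameter from small quantum tunneling
#'
#' For a parabolic barrier crossed with frequency \eqn{\nu^\ddagger}, mild
#' tunneling bends the Arrhenius plot with
#' \eqn{d = -\frac{1}{3}\left(\frac{h\nu^\ddagger}{2\epsilon^\ddagger}\right)^2},
#' always negative (sub-Arrhenius, quantum propensity).
#'
#' @param nu_dagger Barrier-crossing frequency (Hz), > 0.
#' @param eps_act Barrier height, > 0, in the chosen energy unit.
#' @param h Planck constant in (energy unit)*s per molecule or per mole so
#'   that \code{h * nu_dagger} is in the same unit as \code{eps_act}.
#'   Default: molar Planck constant in kJ s / mol.
#' @return Dimensionless deformation parameter \code{d} (< 0).
#' @export
d_from_tunneling <- function(nu_dagger, eps_act, h = 3.990312712e-13) {
  if (!is.finite(eps_act) || eps_act <= 0) {
    tv_stop("eps_act must be > 0 (a finite barrier is required)",
            "tv_invalid_parameter")
  }
  if (!is.finite(nu_dagger) || nu_dagger <= 0) {
    tv_stop("nu_dagger must be > 0", "tv_invalid_parameter")
  }
  -(1 / 3) * (h * nu_dagger / (2 * eps_act))^2
}

#' Thermal limits of a super-Arrhenius process
#'
#' For \code{d > 0} and \eqn{\epsilon^\ddagger > 0} the AM law shuts down
#' where \eqn{1 - d\,\epsilon^\ddagger\beta = 0}: a minimum operative
#' temperature \eqn{T^\dagger}, equivalently a thermal-energy threshold
#' \eqn{\epsilon^\dagger = d\,\epsilon^\ddagger = k_B T^\dagger}, or a
#' maximum coldness \eqn{\beta^\dagger = 1/(d\,\epsilon^\ddagger)}.
#'
#' @param eps_act Activation energy \eqn{\epsilon^\ddagger > 0}.
#' @param d Deformation parameter; must be > 0 (sub-Arrhenius laws have no
#'   finite lower thermal limit).
#' @param units A \code{\link{unit_system}} fixing \eqn{k_B}.
#' @return A list of class \code{"thermal_limits"} with fields
#'   \code{eps_dagger}, \code{T_dagger} (K), \code{beta_dagger}.
#' @export
thermal_limits <- function(eps_act, d, units = unit_system()) {
  units <- .as_units(units)
  if (!is.finite(d) || d <= 0 || !is.finite(eps_act) || eps_act <= 0) {
    tv_stop(paste("no finite thermal limit: a lower operative temperature",
                  "exists only for d > 0 with eps_act > 0 (super-Arrhenius)"),
            "tv_no_finite_limit")
  }
  eps_dagger <- d * eps_act
  structure(list(
    eps_dagger = eps_dagger,
    T_dagger = eps_dagger / units$boltzmann,
    beta_dagger = 1 / eps_dagger,
    units = units
  ), class = "thermal_limits")
}

#' @export
print.thermal_limits <- function(x, ...) {
  cat(sprintf(
    "<thermal_limits> eps_dagger = %.6g %s, T_dagger = %.6g K, beta_dagger = %.6g (%s)^-1\n",
    x$eps_dagger, x$units$energy_unit, x$T_dagger, x$beta_dagger,
    x$units$energy_unit))
  invisible(x)
}

#' Truncated expansion of the AM law about the Arrhenius exponential
#'
#' Expands \eqn{A(1-d\,\epsilon^\ddagger\beta)^{1/d}} as
#' \eqn{A e^{-x}[1 - \tfrac{1}{2} d x^2 - \tfrac{1}{3} d^2 x^3
#' - \tfrac{1}{8}(2d-1) d^2 x^4 + O(x^5)]}, \eqn{x = \epsilon^\ddagger\beta}.
#' The truncation error of the full (order 4) expansion is \eqn{O(x^5)}.
#'
#' @inheritParams k_am
#' @param order Highest power of \eqn{x} retained in the bracket (2--4).
#' @return Approximate rate constant(s).
#' @export
am_expansion <- function(beta, A, eps_act, d, order = 4) {
  .check_A(A); .check_beta(beta)
  if (!order %in% 2:4) {
    tv_stop("order must be 2, 3 or 4", "tv_invalid_parameter")
  }
  x <- eps_act * beta
  if (any(abs(d * x) >= 1)) {
    tv_stop("|d * eps_act * beta| must be < 1 for the expansion",
            "tv_domain_error")
  }
  bracket <- 1 - 0.5 * d * x^2
  if (order >= 3) bracket <- bracket - (1 / 3) * d^2 * x^3
  if (order >= 4) bracket <- bracket - (1 / 8) * (2 * d - 1) * d^2 * x^4
  A * exp(-x) * bracket
}

#' Approach to the Wigner power-law asymptote of the sub-Arrhenius AM law
#'
#' For \code{d < 0} the AM law flattens into a power law
#' \eqn{k \to A(|d|\epsilon^\ddagger)^{1/d}\beta^{1/d}} as
#' \eqn{\beta \to \infty}, the behavior expected from Wigner's threshold
#' law for thermoneutral reactions.  This diagnostic returns the ratio of
#' the exact law to that asymptote, which tends monotonically to 1.
#'
#' @inheritParams k_am
#' @return Dimensionless residual(s) \eqn{k_{AM}/k_{asymptote}}.
#' @export
wigner_asymptote_residual <- function(beta, A, eps_act, d) {
  .check_A(A)
  if (!is.finite(d) || d >= 0) {
    tv_stop("the Wigner power-law asymptote applies only to d < 0 (sub-Arrhenius)",
            "tv_not_applicable")
  }
  if (any(beta <= 0)) {
    tv_stop("beta must be > 0 for the asymptote diagnostic", "tv_domain_error")
  }
  k_am(beta, A, eps_act, d) / (A * (abs(d) * eps_act)^(1 / d) * beta^(1 / d))
}
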