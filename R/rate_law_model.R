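# Tagged rate-law model objects and the generics that connect the
# Arrhenius plane (ln k vs beta) to the transitivity plane (gamma vs
# beta): rate_constant(), activation_energy() and transitivity().

.law_tags <- c("arrhenius", "am", "vft", "fg", "zeta")

#' Construct a rate-law model
#'
#' Bundles a law tag with its parameters so the same object can be
#' evaluated in the Arrhenius plane (\code{\link{rate_constant}}), as an
#' apparent activation energy (\code{\link{activation_energy}}) or in the
#' transitivity plane (\code{\link{transitivity}}).
#'
#' @param law One of \code{"arrhenius"}, \code{"am"}, \code{"vft"},
#'   \code{"fg"}, \code{"zeta"} (generalized transitivity power law).
#' @param A Pre-exponential factor (> 0).
#' @param eps_act Activation energy \eqn{\epsilon^\ddagger}.
#' @param d Deformation parameter (AM law).
#' @param beta_dagger Limiting coldness (VFT and zeta laws).
#' @param s Integer number of internal degrees of freedom (FG law).
#' @param zeta Exponent of the generalized transitivity law
#'   \eqn{\gamma(\beta) = (1/\epsilon^\ddagger)(1-\beta/\beta^\dagger)^\zeta}.
#' @param units A \code{\link{unit_system}}.
#' @return An object of class \code{"rate_law"}.
#' @examples
#' m <- rate_law("am", A = 1e13, eps_act = 40, d = 0.05)
#' b <- beta_from_temperature(300)
#' rate_constant(m, b)
#' transitivity(m, b)   # 1/40 - 0.05 * b
#' @export
rate_law <- function(law, A = 1, eps_act = 1, d = NULL, beta_dagger = NULL,
                     s = NULL, zeta = NULL, units = unit_system()) {
  law <- match.arg(law, .law_tags)
  .check_A(A)
  units <- .as_units(units)
  pars <- list(A = A, eps_act = eps_act)
  switch(law,
    am = {
      if (is.null(d)) tv_stop("AM law requires 'd'", "tv_invalid_parameter")
      pars$d <- d
    },
    vft = {
      if (is.null(beta_dagger) || beta_dagger <= 0) {
        tv_stop("VFT law requires beta_dagger > 0", "tv_invalid_parameter")
      }
      pars$beta_dagger <- beta_dagger
    },
    fg = {
      .check_s(s)
      pars$s <- s
    },
    zeta = {
      if (is.null(zeta) || zeta < 0) {
        tv_stop("generalized law requires zeta >= 0", "tv_invalid_parameter")
      }
      if (zeta > 0 && (is.null(beta_dagger) || beta_dagger <= 0)) {
        tv_stop("generalized law with zeta > 0 requires beta_dagger > 0",
                "tv_invalid_parameter")
      }
      pars$zeta <- zeta
      pars$beta_dagger <- if (zeta > 0) beta_dagger else Inf
    }
  )
  structure(list(law = law, params = pars, units = units),
            class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  p <- x$params
  cat(sprintf("<rate_law: %s> %s\n", x$law,
              paste(names(p), signif(unlist(p), 6), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}

#' Evaluate a rate-law model
#'
#' @param model A \code{\link{rate_law}} object.
#' @param beta Coldness value(s) inside the model's domain.
#' @param ... Unused.
#' @return Rate constant(s) \eqn{k(\beta)}.
#' @export
rate_constant <- function(model, beta, ...) UseMethod("rate_constant")

#' @export
rate_constant.rate_law <- function(model, beta, ...) {
  p <- model$params
  switch(model$law,
    arrhenius = k_arrhenius(beta, p$A, p$eps_act),
    am = k_am(beta, p$A, p$eps_act, p$d),
    vft = k_vft(beta, p$A, p$eps_act, p$beta_dagger),
    fg = k_fg_closed(beta, p$A, p$eps_act, p$s),
    zeta = rate_from_transitivity(beta, p$A, p$eps_act, p$beta_dagger,
                                  p$zeta)
  )
}

#' Apparent (Tolman) activation energy of a model
#'
#' \eqn{E_a(\beta) = -\mathrm{d}\ln k/\mathrm{d}\beta}, evaluated in
#' closed form for every supported law: constant \eqn{\epsilon^\ddagger}
#' (Arrhenius), \eqn{\epsilon^\ddagger/(1-d\epsilon^\ddagger\beta)} (AM),
#' \eqn{\epsilon^\ddagger/(1-\beta/\beta^\dagger)^2} (VFT),
#' \eqn{\epsilon^\ddagger x^{s-1}e^{-x}/\Gamma(s,x)} (FG) and
#' \eqn{\epsilon^\ddagger(1-\beta/\beta^\dagger)^{-\zeta}} (generalized).
#'
#' @inheritParams rate_constant
#' @return Activation energy value(s), same unit as \code{eps_act}.
#' @export
activation_energy <- function(model, beta, ...) UseMethod("activation_energy")

#' @export
activation_energy.rate_law <- function(model, beta, ...) {
  .check_beta(beta)
  p <- model$params
  switch(model$law,
    arrhenius = rep(p$eps_act, length(beta)),
    am = {
      u <- 1 - p$d * p$eps_act * beta
      if (any(u <= 0)) {
        tv_stop("beta outside the AM domain for activation energy",
                "tv_domain_error")
      }
      p$eps_act / u
    },
    vft = {
      if (any(beta >= p$beta_dagger)) {
        tv_stop("beta outside the VFT domain", "tv_domain_error")
      }
      p$eps_act / (1 - beta / p$beta_dagger)^2
    },
    fg = {
      x <- p$eps_act * beta
      # upper incomplete gamma(s, x) = Gamma(s) * Q(s, x)
      lgam_upper <- stats::pgamma(x, p$s, lower.tail = FALSE, log.p = TRUE) +
        lgamma(p$s)
      lx <- log(pmax(x, .Machine$double.xmin))
      ea <- p$eps_act * exp((p$s - 1) * lx - x - lgam_upper)
      ea[x == 0 & p$s > 1] <- 0
      ea
    },
    zeta = {
      if (p$zeta == 0) {
        rep(p$eps_act, length(beta))
      } else {
        if (any(beta >= p$beta_dagger)) {
          tv_stop("beta outside the generalized-law domain", "tv_domain_error")
        }
        p$eps_act * (1 - beta / p$beta_dagger)^(-p$zeta)
      }
    }
  )
}

#' Transitivity function of a model
#'
#' \eqn{\gamma(\beta) = 1/E_a(\beta)}, the reciprocal apparent activation
#' energy, interpreted as the propensity of the process to proceed.  For
#' the AM law the transitivity is exactly linear:
#' \eqn{\gamma(\beta) = 1/\epsilon^\ddagger - d\,\beta}.
#'
#' @inheritParams rate_constant
#' @return Transitivity value(s), reciprocal energy.
#' @export
transitivity <- function(model, beta, ...) UseMethod("transitivity")

#' @export
transitivity.rate_law <- function(model, beta, ...) {
  if (model$law == "am") {
    .check_beta(beta)
    p <- model$params
    g <- 1 / p$eps_act - p$d * beta     # exact linear form
    if (any(g == 0)) {
      tv_stop("transitivity singular: Ea diverges at the thermal limit",
              "tv_singular_transitivity")
    }
    return(g)
  }
  ea <- activation_energy(model, beta)
  if (any(ea == 0)) {
    tv_stop("transitivity singular: activation energy is zero",
            "tv_singular_transitivity")
  }
  1 / ea
}

#' Rate law reconstructed from the generalized transitivity power law
#'
#' Given \eqn{\gamma(\beta) = (1/\epsilon^\ddagger)
#' (1 - \beta/\beta^\dagger)^\zeta}, recovers the rate constant by
#' integrating the defining relation \eqn{E_a = -\mathrm{d}\ln k /
#' \mathrm{d}\beta = 1/\gamma}:
#' \deqn{\ln k(\beta) = \ln A - \int_0^\beta \gamma(\beta')^{-1}
#' \mathrm{d}\beta'.}
#' Exponents 0, 1 and 2 use the Arrhenius, AM and VFT closed forms; other
#' exponents are evaluated by adaptive quadrature (and checked against the
#' analytic antiderivative available for all \eqn{\zeta \ne 1}).
#'
#' @inheritParams k_vft
#' @param zeta Exponent \eqn{\zeta \ge 0}.
#' @param method \code{"closed"} uses analytic forms where available,
#'   \code{"quadrature"} forces adaptive numerical integration.
#' @return Rate constant(s).
#' @export
rate_from_transitivity <- function(beta, A, eps_act, beta_dagger = Inf, zeta = 0,
                                   method = c("closed", "quadrature")) {
  method <- match.arg(method)
  .check_A(A); .check_beta(beta)
  if (zeta < 0) tv_stop("zeta must be >= 0", "tv_invalid_parameter")
  if (zeta == 0) {
    if (method == "closed") return(k_arrhenius(beta, A, eps_act))
  } else {
    if (!is.finite(beta_dagger) || beta_dagger <= 0) {
      tv_stop("beta_dagger must be finite and > 0 for zeta > 0",
              "tv_invalid_parameter")
    }
    if (any(beta >= beta_dagger)) {
      tv_stop(sprintf("beta must be < beta_dagger = %.10g", beta_dagger),
              "tv_domain_error")
    }
  }
  if (method == "closed") {
    if (zeta == 1) {
      return(k_am(beta, A, eps_act, d = 1 / (eps_act * beta_dagger)))
    }
    if (zeta == 2) return(k_vft(beta, A, eps_act, beta_dagger))
  }
  # ln k = ln A - eps_act * int_0^beta (1 - u/beta_dagger)^(-zeta) du
  integrand <- function(u) (1 - u / beta_dagger)^(-zeta)
  vapply(beta, function(b) {
    if (b == 0) return(A)
    q <- stats::integrate(integrand, 0, b, rel.tol = 1e-10, abs.tol = 1e-10,
                          subdivisions = 500L)
    if (q$message != "OK") {
      tv_stop(sprintf("quadrature failed: %s", q$message), "tv_numerical_error")
    }
    A * exp(-eps_act * q$value)
  }, numeric(1))
}
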