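# Seeded synthetic rate data with known ground truth: every recovery,
# selection and crossover test in the package runs against data built
# here, so the generator is first-class, validated code.

#' Specify a synthetic rate dataset
#'
#' Describes how to generate noisy rate data from a known law: the law
#' and its parameters, a temperature window, grid type, a multiplicative
#' lognormal noise level and a seed.  Validation checks that the whole
#' grid lies strictly inside the law's domain (e.g. above the thermal
#' limit \eqn{T^\dagger} of a super-Arrhenius law).
#'
#' @param model A \code{\link{rate_law}} object (the ground truth).
#' @param T_min,T_max Temperature window in kelvin, \code{T_min < T_max}.
#' @param n Number of points (>= 3).
#' @param grid \code{"T"} for points equispaced in temperature,
#'   \code{"beta"} for equispaced coldness.
#' @param sigma Relative noise level: rates are multiplied by
#'   \eqn{e^{\sigma z}}, \eqn{z} standard normal (so \code{sigma} is the
#'   standard deviation of \eqn{\ln k} residuals).  \code{0} = noiseless.
#' @param seed Integer seed for the noise generator.
#' @return An object of class \code{"synthetic_spec"}.
#' @examples
#' sp <- synthetic_spec(rate_law("am", A = 1e13, eps_act = 40, d = 0.05),
#'                      T_min = 250, T_max = 400, n = 30)
#' ds <- generate_rate_data(sp)
#' @export
synthetic_spec <- function(model, T_min, T_max, n = 30, grid = c("T", "beta"),
                           sigma = 0, seed = 1L) {
  grid <- match.arg(grid)
  if (!inherits(model, "rate_law")) {
    tv_stop("model must be a rate_law object", "tv_invalid_spec")
  }
  if (!is.finite(T_min) || !is.finite(T_max) || T_min <= 0 ||
      T_min >= T_max) {
    tv_stop("need 0 < T_min < T_max", "tv_invalid_spec")
  }
  if (n < 3) tv_stop("n must be >= 3", "tv_invalid_spec")
  if (sigma < 0) tv_stop("sigma must be >= 0", "tv_invalid_spec")
  spec <- structure(list(
    model = model, T_min = T_min, T_max = T_max, n = as.integer(n),
    grid = grid, sigma = sigma, seed = as.integer(seed)
  ), class = "synthetic_spec")
  .check_grid_in_domain(spec)
  spec
}

.spec_beta_grid <- function(spec) {
  u <- spec$model$units
  if (spec$grid == "T") {
    beta_from_temperature(seq(spec$T_min, spec$T_max, length.out = spec$n), u)
  } else {
    b_lo <- beta_from_temperature(spec$T_max, u)
    b_hi <- beta_from_temperature(spec$T_min, u)
    seq(b_lo, b_hi, length.out = spec$n)
  }
}

.check_grid_in_domain <- function(spec) {
  beta <- .spec_beta_grid(spec)
  p <- spec$model$params
  bd <- switch(spec$model$law,
    am = if (!is.null(p$d) && p$d > 0 && p$eps_act > 0)
      1 / (p$d * p$eps_act) else Inf,
    vft = p$beta_dagger,
    zeta = if (p$zeta > 0) p$beta_dagger else Inf,
    Inf
  )
  if (any(beta >= bd)) {
    bad <- temperature_from_beta(beta[beta >= bd], spec$model$units)
    tv_stop(sprintf(
      "temperature grid crosses the thermal limit (T_dagger = %.4g K): offending T = %s K",
      temperature_from_beta(bd, spec$model$units),
      paste(signif(sort(bad), 5), collapse = ", ")), "tv_domain_error")
  }
  invisible(TRUE)
}

#' Generate a synthetic rate dataset
#'
#' Evaluates the ground-truth law on the grid and applies seeded
#' multiplicative lognormal noise.  The same spec and seed always return
#' a bit-identical dataset; the global RNG state is left untouched.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A \code{\link{rate_dataset}} with the spec attached as
#'   attribute \code{"ground_truth"}.
#' @export
generate_rate_data <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    tv_stop("spec must be a synthetic_spec", "tv_invalid_spec")
  }
  beta <- .spec_beta_grid(spec)
  k <- rate_constant(spec$model, beta)
  if (spec$sigma > 0) {
    z <- .with_seed(spec$seed, stats::rnorm(spec$n))
    k <- k * exp(spec$sigma * z)
  }
  ds <- rate_dataset(beta = beta, k = k, units = spec$model$units)
  attr(ds, "ground_truth") <- spec
  ds
}

# Run expr under a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Two-regime (crossover) synthetic dataset
#'
#' Builds a piecewise rate law from two AM segments whose transitivity
#' lines intersect at the crossover coldness \code{beta_c}: gamma is
#' continuous (kinked) at \code{beta_c} and \eqn{\ln k} is matched there,
#' emulating a process that switches mechanism at a crossover
#' temperature.  Both segment models must be AM laws whose transitivity
#' lines actually meet at \code{beta_c} (within 1e-8 relative).
#'
#' @param model_a AM \code{\link{rate_law}} operative for
#'   \code{beta <= beta_c} (high temperature).
#' @param model_b AM \code{\link{rate_law}} operative for
#'   \code{beta >= beta_c}; its pre-exponential factor is overridden to
#'   make \eqn{\ln k} continuous.
#' @param beta_c Crossover coldness.
#' @param T_min,T_max,n,grid,sigma,seed As in
#'   \code{\link{synthetic_spec}}.  The grid should straddle
#'   \code{beta_c}.
#' @return A \code{\link{rate_dataset}} with attribute
#'   \code{"ground_truth"} describing both segments and \code{beta_c}.
#' @seealso \code{\link{am_segment_through}} to construct a second
#'   segment intersecting the first at \code{beta_c}.
#' @export
generate_two_regime <- function(model_a, model_b, beta_c, T_min, T_max,
                                n = 21, grid = c("beta", "T"), sigma = 0,
                                seed = 1L) {
  grid <- match.arg(grid)
  if (!inherits(model_a, "rate_law") || model_a$law != "am" ||
      !inherits(model_b, "rate_law") || model_b$law != "am") {
    tv_stop("both segment models must be AM rate laws", "tv_invalid_spec")
  }
  ga <- transitivity(model_a, beta_c)
  gb <- transitivity(model_b, beta_c)
  if (abs(ga - gb) > 1e-8 * max(abs(ga), abs(gb))) {
    tv_stop(sprintf(
      "segment transitivity lines do not intersect at beta_c: gamma_a = %.10g, gamma_b = %.10g",
      ga, gb), "tv_invalid_spec")
  }
  units <- model_a$units
  spec <- synthetic_spec(model_a, T_min, T_max, n = n, grid = grid,
                         sigma = sigma, seed = seed)
  beta <- .spec_beta_grid(spec)
  pa <- model_a$params; pb <- model_b$params
  # match ln k at the crossover by overriding B's pre-exponential factor
  k_join <- rate_constant(model_a, beta_c)
  logA_b <- log(k_join) - log(k_am(beta_c, 1, pb$eps_act, pb$d))
  k <- ifelse(beta <= beta_c,
              rate_constant(model_a, beta),
              exp(logA_b) * k_am(beta, 1, pb$eps_act, pb$d))
  if (sigma > 0) {
    z <- .with_seed(seed, stats::rnorm(length(beta)))
    k <- k * exp(sigma * z)
  }
  ds <- rate_dataset(beta = beta, k = k, units = units)
  attr(ds, "ground_truth") <- list(
    model_a = model_a, model_b = model_b, beta_c = beta_c,
    A_b_matched = exp(logA_b), sigma = sigma, seed = seed
  )
  ds
}

#' AM segment through a given transitivity point
#'
#' Returns the AM law with deformation \code{d} whose transitivity line
#' passes through \eqn{(\beta_c, \gamma_c)}: its activation energy is
#' \eqn{1/(\gamma_c + d\,\beta_c)}.  Convenience for building
#' two-regime datasets with a continuous transitivity kink.
#'
#' @param d Deformation parameter of the new segment.
#' @param beta_c,gamma_c The point the transitivity line must pass
#'   through (\code{gamma_c + d*beta_c} must be > 0).
#' @param A Pre-exponential placeholder (overridden when joining).
#' @param units Unit system.
#' @return An AM \code{\link{rate_law}}.
#' @export
am_segment_through <- function(d, beta_c, gamma_c, A = 1,
                               units = unit_system()) {
  intercept <- gamma_c + d * beta_c   # gamma(0) = 1/eps_act
  if (intercept <= 0) {
    tv_stop("segment would have non-positive transitivity intercept",
            "tv_invalid_spec")
  }
  rate_law("am", A = A, eps_act = 1 / intercept, d = d, units = units)
}
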