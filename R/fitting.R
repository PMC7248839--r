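# Estimation: rate-law fits in the Arrhenius plane (ln k vs beta),
# construction of the empirical transitivity curve, selection of the
# universality exponent zeta in the transitivity plane, and crossover
# (breakpoint) detection between two AM regimes.
#
# All objectives are least squares on ln k or on gamma; rate data span
# orders of magnitude, so log-space residuals are the only sane choice.

# ---- fit_result ------------------------------------------------------

.new_fit_result <- function(law, par, se, rss, aicc, n, units,
                            zeta = NULL, breakpoint = NULL,
                            converged = TRUE, config = list()) {
  structure(list(
    law = law, par = par, se = se, rss = rss, aicc = aicc, n = n,
    zeta = zeta, breakpoint = breakpoint, converged = converged,
    units = units, config = config
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s>%s  n = %d, RSS = %.6g, AICc = %.6g\n",
              x$law,
              if (!is.null(x$zeta)) sprintf(" zeta = %g,", x$zeta) else "",
              x$n, x$rss, x$aicc))
  est <- data.frame(estimate = x$par,
                    std_error = x$se[names(x$par)],
                    row.names = names(x$par))
  print(signif(est, 6))
  if (!is.null(x$breakpoint)) {
    bp <- x$breakpoint
    cat(sprintf("  crossover at beta_c = %.6g (T_c = %.5g K)\n",
                bp$beta_c, bp$T_c))
  }
  invisible(x)
}

# Small-sample-corrected information criterion on least-squares
# residuals; p = number of fitted mean parameters (sigma adds one).
.aicc <- function(rss, n, p) {
  k <- p + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Near-zero RSS values (noiseless synthetic data) are floored at a
# resolution-scale value so that information criteria compare parameter
# counts rather than log(rounding noise).
.floor_rss <- function(rss, scale, n) {
  max(rss, n * (1e-10 * max(scale, .Machine$double.xmin))^2)
}

# Finite-difference Jacobian of a residual function at par.
.num_jacobian <- function(fn, par) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- max(1e-8, 1e-7 * abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

.se_from_resid <- function(fn, par, rss, n) {
  p <- length(par)
  se <- rep(NA_real_, p)
  if (n > p) {
    J <- .num_jacobian(fn, par)
    jtj <- crossprod(J)
    cv <- try(solve(jtj) * rss / (n - p), silent = TRUE)
    if (!inherits(cv, "try-error")) se <- sqrt(pmax(diag(cv), 0))
  }
  names(se) <- names(par)
  se
}

# ---- Arrhenius-plane fits --------------------------------------------

# Residual builders: sqrt(w) * (ln k - model ln k).  Domain violations
# are clamped so the predicted ln k collapses and the optimizer is
# pushed back inside.
.lnk_model <- function(law, beta, par, s = NULL) {
  switch(law,
    arrhenius = par[["logA"]] - par[["eps_act"]] * beta,
    am = {
      d <- par[["d"]]
      if (abs(d) < 1e-12) {
        par[["logA"]] - par[["eps_act"]] * beta
      } else {
        v <- pmin(d * par[["eps_act"]] * beta, 1 - 1e-15)
        par[["logA"]] + log1p(-v) / d
      }
    },
    vft = {
      u <- pmax(1 - beta / par[["beta_dagger"]], 1e-12)
      par[["logA"]] - par[["eps_act"]] * beta / u
    },
    fg = {
      q <- stats::pgamma(pmax(par[["eps_act"]], 0) * beta, shape = s,
                         lower.tail = FALSE, log.p = TRUE)
      par[["logA"]] + q
    }
  )
}

.run_lm <- function(resid_fn, starts) {
  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  best
}

#' Fit a rate law in the Arrhenius plane
#'
#' Weighted least squares on \eqn{\ln k} versus \eqn{\beta} for the
#' Arrhenius, AM, VFT or FG law.  Initialization comes from the ordinary
#' Arrhenius line fit; the AM deformation uses multi-start over
#' \code{d} in \{-0.1, -0.01, 0, 0.01, 0.1\} and the VFT divergence
#' starts at multiples of the largest observed \eqn{\beta}.  The FG
#' degrees-of-freedom \code{s} is profiled over 1..\code{s_max}.
#'
#' @param data A \code{\link{rate_dataset}} with >= 3 points.
#' @param law One of \code{"arrhenius"}, \code{"am"}, \code{"vft"},
#'   \code{"fg"}.
#' @param init Optional named list of starting values
#'   (\code{logA}, \code{eps_act}, and \code{d} / \code{beta_dagger}
#'   as applicable), used in addition to the built-in starts.
#' @param s_max Largest FG \code{s} profiled (default 30).
#' @return A \code{\link[=print.fit_result]{fit_result}} with estimates,
#'   standard errors, the residual sum of squares on \eqn{\ln k} and a
#'   small-sample-corrected information criterion.
#' @export
fit_arrhenius_plane <- function(data, law = c("arrhenius", "am", "vft", "fg"),
                                init = NULL, s_max = 30L) {
  law <- match.arg(law)
  if (!inherits(data, "rate_dataset")) {
    tv_stop("data must be a rate_dataset", "tv_input_error")
  }
  n <- length(data$beta)
  if (n < 3) tv_stop("need >= 3 points for any fit", "tv_input_error")
  beta <- data$beta; lnk <- log(data$k); sw <- sqrt(data$weights)

  line <- stats::lm.fit(cbind(1, beta) * sw, lnk * sw)
  logA0 <- line$coefficients[1]
  eps0 <- -line$coefficients[2]

  if (law == "arrhenius") {
    par <- c(logA = unname(logA0), eps_act = unname(eps0))
    fn <- function(p) sw * (lnk - .lnk_model("arrhenius", beta, p))
    rss <- sum(fn(par)^2)
    se <- .se_from_resid(fn, par, rss, n)
    return(.new_fit_result("arrhenius", par, se, rss,
                           .aicc(.floor_rss(rss, stats::sd(lnk), n), n, 2),
                           n, data$units))
  }

  if (law == "fg") {
    best <- NULL
    for (s in seq_len(s_max)) {
      fn <- function(p) sw * (lnk - .lnk_model("fg", beta, p, s = s))
      p0 <- c(logA = unname(logA0), eps_act = max(unname(eps0), 1e-8))
      if (!is.null(init)) p0[names(init)] <- unlist(init)[names(init)]
      cand <- .run_lm(fn, list(p0))
      if (is.null(cand)) next
      if (is.null(best) || cand$rss < best$rss - 1e-12 * best$rss) {
        best <- cand; best$s <- s; best$fn <- fn
      }
    }
    if (is.null(best)) tv_stop("FG fit failed for every s", "tv_fit_failure")
    par <- c(best$par, s = best$s)
    se <- c(.se_from_resid(best$fn, best$par, best$rss, n), s = NA_real_)
    return(.new_fit_result("fg", par, se, best$rss,
                           .aicc(.floor_rss(best$rss, stats::sd(lnk), n), n, 3),
                           n, data$units))
  }

  if (law == "am") {
    starts <- lapply(c(-0.1, -0.01, 1e-6, 0.01, 0.1), function(d0) {
      c(logA = unname(logA0), eps_act = unname(eps0), d = d0)
    })
  } else {
    bd0 <- max(beta) * c(1.2, 1.5, 3, 10)
    starts <- lapply(bd0, function(b0) {
      c(logA = unname(logA0), eps_act = unname(eps0), beta_dagger = b0)
    })
  }
  if (!is.null(init)) {
    p0 <- starts[[1]]
    p0[names(init)] <- unlist(init)[names(init)]
    starts <- c(list(p0), starts)
  }
  fn <- function(p) sw * (lnk - .lnk_model(law, beta, p))
  best <- .run_lm(fn, starts)
  if (is.null(best)) {
    tv_stop(sprintf("%s fit failed to converge from all starts", law),
            "tv_fit_failure")
  }
  par <- best$par
  rss <- sum(fn(par)^2)
  se <- .se_from_resid(fn, par, rss, n)
  .new_fit_result(law, par, se, rss,
                  .aicc(.floor_rss(rss, stats::sd(lnk), n), n, 3),
                  n, data$units)
}

# ---- empirical transitivity ------------------------------------------

#' Empirical transitivity curve from rate data
#'
#' Estimates the apparent activation energy
#' \eqn{E_a(\beta) = -\mathrm{d}\ln k/\mathrm{d}\beta} pointwise from the
#' data and inverts it to the transitivity \eqn{\gamma = 1/E_a}.  The
#' default derivative uses local quadratic stencils (three-point central
#' differences in the interior, one-sided at the ends), appropriate for
#' dense low-noise data; \code{method = "spline"} differentiates a
#' smoothing spline of \eqn{\ln k} chosen by generalized
#' cross-validation, appropriate for noisy data.  Points where
#' \eqn{|E_a|} falls below \code{ea_tol} are masked (gamma set to
#' \code{NA}), never inverted.
#'
#' @param data A \code{\link{rate_dataset}} with >= 5 points.
#' @param method \code{"central"} or \code{"spline"}.
#' @param ea_tol Masking tolerance on \eqn{|E_a|}; default
#'   \code{1e-8 * range(ln k)/range(beta)} with a machine-epsilon floor.
#' @return An object of class \code{"transitivity_curve"}: fields
#'   \code{beta}, \code{gamma} (NA where masked), \code{Ea},
#'   \code{masked}, \code{method}, \code{units}.
#' @export
empirical_transitivity <- function(data, method = c("central", "spline"),
                                   ea_tol = NULL) {
  method <- match.arg(method)
  if (!inherits(data, "rate_dataset")) {
    tv_stop("data must be a rate_dataset", "tv_input_error")
  }
  n <- length(data$beta)
  if (n < 5) tv_stop("need >= 5 points for derivative estimation",
                     "tv_input_error")
  beta <- data$beta; lnk <- log(data$k)
  ea <- switch(method,
    central = -.grid_derivative(beta, lnk),
    spline = {
      ss <- stats::smooth.spline(beta, lnk, cv = FALSE)
      -stats::predict(ss, beta, deriv = 1)$y
    }
  )
  if (is.null(ea_tol)) {
    # floor at a unit slope so exactly-flat data (Ea = 0 up to rounding)
    # are always masked
    ea_tol <- 1e-8 * max(diff(range(lnk)), 1) / diff(range(beta))
  }
  masked <- abs(ea) < ea_tol
  gamma <- ifelse(masked, NA_real_, 1 / ea)
  structure(list(
    beta = beta, gamma = gamma, Ea = ea, masked = masked,
    lnk = lnk, method = method, window = 3L, units = data$units
  ), class = "transitivity_curve")
}

#' Transitivity curve of a known model on a grid
#'
#' Convenience: evaluates \code{\link{transitivity}} of a
#' \code{\link{rate_law}} on a coldness grid and wraps it as a
#' \code{"transitivity_curve"} (no masking, exact values).
#'
#' @param model A \code{\link{rate_law}}.
#' @param beta Coldness grid (increasing).
#' @return A \code{"transitivity_curve"}.
#' @export
model_transitivity_curve <- function(model, beta) {
  g <- transitivity(model, beta)
  structure(list(
    beta = beta, gamma = g, Ea = 1 / g, masked = rep(FALSE, length(beta)),
    method = "exact", window = NA_integer_, units = model$units
  ), class = "transitivity_curve")
}

#' @export
print.transitivity_curve <- function(x, ...) {
  cat(sprintf(
    "<transitivity_curve> %d points (%d masked), method = %s, beta in [%.5g, %.5g]\n",
    length(x$beta), sum(x$masked), x$method, min(x$beta), max(x$beta)))
  invisible(x)
}

#' @export
as.data.frame.transitivity_curve <- function(x, ...) {
  data.frame(beta = x$beta, gamma = x$gamma, Ea = x$Ea, masked = x$masked)
}

# ---- transitivity-plane fit ------------------------------------------

.fit_fixed_zeta <- function(b, g, w, zeta) {
  n <- length(b)
  if (zeta == 0) {
    cbar <- sum(w * g) / sum(w)
    rss <- sum(w * (g - cbar)^2)
    eps <- 1 / cbar
    se_c <- sqrt(rss / (n - 1) / sum(w))
    par <- c(eps_act = eps)
    se <- c(eps_act = se_c * eps^2)   # delta method on 1/c
    return(list(par = par, se = se, rss = rss, p = 1))
  }
  pred <- function(p) {
    u <- pmax(1 - b / p[["beta_dagger"]], 0)
    (1 / p[["eps_act"]]) * u^zeta
  }
  fn <- function(p) sqrt(w) * (g - pred(p))
  line <- stats::lm.fit(cbind(1, b) * sqrt(w), g * sqrt(w))
  a0 <- line$coefficients[1]; s0 <- line$coefficients[2]
  eps0 <- if (is.finite(a0) && a0 != 0) 1 / a0 else 1 / mean(g)
  bmax <- max(b)
  bd_line <- if (is.finite(s0) && s0 < 0) zeta * (-a0 / s0) else NA
  bd0 <- c(bd_line, bmax * c(1.05, 1.5, 3, 10))
  bd0 <- bd0[is.finite(bd0) & bd0 > bmax * (1 + 1e-9)]
  starts <- lapply(bd0, function(bd) {
    c(eps_act = unname(eps0), beta_dagger = unname(bd))
  })
  best <- .run_lm(fn, starts)
  if (is.null(best)) return(NULL)
  par <- best$par
  rss <- sum(fn(par)^2)
  se <- .se_from_resid(fn, par, rss, n)
  list(par = par, se = se, rss = rss, p = 2)
}

#' Fit the generalized transitivity law in the transitivity plane
#'
#' Fits \eqn{\gamma(\beta) = (1/\epsilon^\ddagger)
#' (1 - \beta/\beta^\dagger)^\zeta} to an empirical transitivity curve.
#' With \code{zeta} fixed, a nonlinear least-squares fit of
#' (\eqn{\epsilon^\ddagger}, \eqn{\beta^\dagger}); with \code{zeta}
#' free (the default), the exponent is profiled over a grid on [0, 4]
#' in steps of 0.05 (which contains the integer universality classes
#' 0 = Arrhenius, 1 = AM, 2 = VFT) and the winner is chosen by the
#' small-sample-corrected information criterion, ties going to the model
#' with fewer parameters and then to integer exponents.
#'
#' @param curve A \code{"transitivity_curve"} with >= 4 unmasked points.
#' @param zeta Fixed exponent, or \code{NULL} to select it.
#' @param zeta_grid Candidate exponents profiled when \code{zeta} is
#'   free.
#' @return A \code{fit_result} with \code{law = "zeta"}, the selected
#'   exponent in \code{$zeta}, and for \eqn{\zeta = 1} the implied AM
#'   deformation \code{d} among the parameters.
#' @export
fit_transitivity_plane <- function(curve, zeta = NULL,
                                   zeta_grid = seq(0, 4, by = 0.05)) {
  if (!inherits(curve, "transitivity_curve")) {
    tv_stop("curve must be a transitivity_curve", "tv_input_error")
  }
  keep <- !curve$masked & is.finite(curve$gamma)
  if (sum(keep) < 4) {
    tv_stop("need >= 4 unmasked transitivity points", "tv_input_error")
  }
  b <- curve$beta[keep]; g <- curve$gamma[keep]
  w <- rep(1, length(b))
  n <- length(b)
  scale <- mean(abs(g))

  fit_one <- function(z) {
    f <- .fit_fixed_zeta(b, g, w, z)
    if (is.null(f)) return(NULL)
    # +1 parameter charged for a freely selected exponent
    p_eff <- f$p + if (is.null(zeta)) 1 else 0
    f$zeta <- z
    f$aicc <- .aicc(.floor_rss(f$rss, scale, n), n, p_eff)
    f
  }

  if (!is.null(zeta)) {
    f <- fit_one(zeta)
    if (is.null(f)) tv_stop("transitivity fit failed", "tv_fit_failure")
  } else {
    cands <- sort(unique(round(zeta_grid, 10)))
    fits <- Filter(Negate(is.null), lapply(cands, fit_one))
    if (!length(fits)) tv_stop("transitivity fit failed for every zeta",
                               "tv_fit_failure")
    aic <- vapply(fits, `[[`, numeric(1), "aicc")
    elig <- which(aic <= min(aic) + 2)
    # tie-break: fewer parameters, then integer exponent, then smaller
    pnum <- vapply(fits, `[[`, numeric(1), "p")[elig]
    zval <- vapply(fits, `[[`, numeric(1), "zeta")[elig]
    ord <- order(pnum, abs(zval - round(zval)) > 1e-9, aic[elig], zval)
    f <- fits[[elig[ord[1]]]]
  }
  par <- f$par; se <- f$se
  if (f$zeta == 1) {
    d_hat <- 1 / (par[["eps_act"]] * par[["beta_dagger"]])
    par <- c(par, d = unname(d_hat))
    se <- c(se, d = NA_real_)
  }
  .new_fit_result("zeta", par, se, f$rss, f$aicc, n, curve$units,
                  zeta = f$zeta)
}

# ---- crossover detection ---------------------------------------------

.line_rss <- function(b, g) {
  ft <- stats::lm.fit(cbind(1, b), g)
  list(coef = ft$coefficients, rss = sum(ft$residuals^2))
}

# ln k of the piecewise-AM crossover model: two AM segments whose
# transitivity lines intersect at bc and whose ln k is continuous
# there.  Free parameters th = (logA, eps_l, d_l, d_r); continuity
# fixes the right-segment activation energy and prefactor.
.lam_lnk <- function(b, eps, d) {
  if (abs(d) < 1e-12) -eps * b else log(pmax(1 - d * eps * b, 1e-300)) / d
}

.piecewise_lnk <- function(beta, th, bc) {
  logA <- th[[1]]; eps_l <- th[[2]]; d_l <- th[[3]]; d_r <- th[[4]]
  g_c <- 1 / eps_l - d_l * bc
  eps_r <- 1 / (g_c + d_r * bc)
  lnk_c <- logA + .lam_lnk(bc, eps_l, d_l)
  ifelse(beta <= bc,
         logA + .lam_lnk(beta, eps_l, d_l),
         lnk_c + .lam_lnk(beta, eps_r, d_r) - .lam_lnk(bc, eps_r, d_r))
}

.fit_piecewise_lnk <- function(beta, lnk, bc, th0) {
  fn <- function(th) {
    r <- lnk - .piecewise_lnk(beta, th, bc)
    r[!is.finite(r)] <- 1e6
    r
  }
  f <- try(minpack.lm::nls.lm(
    par = th0, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)), silent = TRUE)
  if (inherits(f, "try-error")) return(NULL)
  list(par = f$par, rss = sum(f$fvec^2))
}

#' Detect a crossover temperature in the transitivity plane
#'
#' Searches for a kink between two linear (AM-class) transitivity
#' regimes.  Every interior grid point (with >= 3 points on each side,
#' the candidate shared by both segments) is tried as a breakpoint
#' \eqn{\beta_c}.  Candidates are scored by the total RSS of two
#' independent straight-line fits in the transitivity plane; when the
#' curve carries the underlying \eqn{\ln k} values (curves built by
#' \code{\link{empirical_transitivity}} do), the decisive comparison is
#' made in the Arrhenius plane, where the noise is uncorrelated: a
#' piecewise-AM model continuous in both \eqn{\gamma} and \eqn{\ln k}
#' at \eqn{\beta_c} (5 parameters) is profiled over all candidates and
#' compared with the single AM law (3 parameters) by the small-sample
#' corrected information criterion on \eqn{\ln k} residuals.  Because
#' \eqn{\beta_c} is maximally selected over \eqn{m} candidates, the
#' break model's criterion is additionally charged \eqn{2\ln m}.  The
#' single-line model is preferred whenever the criterion difference is
#' below 2.
#'
#' @param curve A \code{"transitivity_curve"} with >= 7 unmasked points.
#' @return A \code{fit_result} with \code{law = "crossover"}.  When a
#'   break is found, \code{$breakpoint} holds \code{beta_c},
#'   \code{T_c} and the per-segment (\code{eps_act}, \code{d});
#'   otherwise \code{$breakpoint} is \code{NULL} and the single-line AM
#'   parameters are reported.
#' @export
detect_crossover <- function(curve) {
  if (!inherits(curve, "transitivity_curve")) {
    tv_stop("curve must be a transitivity_curve", "tv_input_error")
  }
  keep <- !curve$masked & is.finite(curve$gamma)
  n <- sum(keep)
  if (n < 7) tv_stop("need >= 7 unmasked points for breakpoint detection",
                     "tv_input_error")
  b <- curve$beta[keep]; g <- curve$gamma[keep]
  lnk <- if (!is.null(curve$lnk)) curve$lnk[keep] else NULL
  scale <- mean(abs(g))
  units <- curve$units
  cand <- 3:(n - 2)             # candidate point belongs to both segments
  m <- length(cand)
  search_charge <- 2 * log(m)   # maximal selection over m candidates

  gamma_two_line <- lapply(cand, function(i) {
    left <- .line_rss(b[1:i], g[1:i])
    right <- .line_rss(b[i:n], g[i:n])
    list(i = i, rss = left$rss + right$rss, left = left, right = right)
  })
  g_rss <- vapply(gamma_two_line, `[[`, numeric(1), "rss")
  single_g <- .line_rss(b, g)
  line_pars <- function(cf) c(eps_act = unname(1 / cf[1]),
                              d = unname(-cf[2]))

  if (is.null(lnk)) {
    # gamma-plane comparison only
    best <- gamma_two_line[[which.min(g_rss)]]
    aicc_single <- .aicc(.floor_rss(single_g$rss, scale, n), n, 2)
    aicc_break <- .aicc(.floor_rss(best$rss, scale, n), n, 5) +
      search_charge
    use_break <- aicc_single - aicc_break >= 2 && best$rss <= single_g$rss
    seg_left <- line_pars(best$left$coef)
    seg_right <- line_pars(best$right$coef)
    i_best <- best$i
    rss_break <- best$rss
    rss_single <- single_g$rss
  } else {
    # Arrhenius-plane comparison: piecewise-AM ln k profile
    ds <- rate_dataset(beta = b, k = exp(lnk), units = units)
    single_fit <- fit_arrhenius_plane(ds, "am")
    rss_single <- single_fit$rss
    th0 <- c(single_fit$par[["logA"]], single_fit$par[["eps_act"]],
             single_fit$par[["d"]], single_fit$par[["d"]])
    profile <- lapply(cand, function(i) .fit_piecewise_lnk(b, lnk, b[i], th0))
    ok <- !vapply(profile, is.null, logical(1))
    if (!any(ok)) tv_stop("breakpoint profile failed", "tv_fit_failure")
    rss_prof <- vapply(profile[ok], `[[`, numeric(1), "rss")
    j <- which(ok)[which.min(rss_prof)]
    best_pw <- profile[[j]]
    i_best <- cand[j]
    rss_break <- best_pw$rss
    lnk_scale <- stats::sd(lnk)
    aicc_single <- .aicc(.floor_rss(rss_single, lnk_scale, n), n, 3)
    aicc_break <- .aicc(.floor_rss(rss_break, lnk_scale, n), n, 5) +
      search_charge
    use_break <- aicc_single - aicc_break >= 2 && rss_break <= rss_single
    th <- best_pw$par
    bc <- b[i_best]
    g_c <- 1 / th[[2]] - th[[3]] * bc
    seg_left <- c(eps_act = th[[2]], d = th[[3]])
    seg_right <- c(eps_act = 1 / (g_c + th[[4]] * bc), d = th[[4]])
  }

  if (use_break) {
    beta_c <- b[i_best]
    bp <- list(
      beta_c = beta_c,
      T_c = temperature_from_beta(beta_c, units),
      left = seg_left,
      right = seg_right
    )
    par <- c(beta_c = beta_c,
             eps_act_left = unname(seg_left[["eps_act"]]),
             d_left = unname(seg_left[["d"]]),
             eps_act_right = unname(seg_right[["eps_act"]]),
             d_right = unname(seg_right[["d"]]))
    se <- rep(NA_real_, length(par)); names(se) <- names(par)
    .new_fit_result("crossover", par, se, rss_break, aicc_break, n, units,
                    breakpoint = bp)
  } else {
    par <- line_pars(single_g$coef)
    se <- rep(NA_real_, length(par)); names(se) <- names(par)
    .new_fit_result("crossover", par, se, single_g$rss, aicc_single, n,
                    units, breakpoint = NULL)
  }
}

# ---- classification ---------------------------------------------------

#' Classify Arrhenius-plot behavior from an AM fit
#'
#' Maps the fitted deformation parameter to the field's taxonomy:
#' \code{"sub-Arrhenius"} (\code{d < -tol}; concave plot, quantum
#' propensity), \code{"super-Arrhenius"} (\code{d > tol},
#' \eqn{\epsilon^\ddagger > 0}; convex plot, classical/collective
#' propensity), \code{"anti-Arrhenius"} (\code{d > tol} with
#' \eqn{\epsilon^\ddagger < 0}; rate decreasing with temperature) or
#' \code{"Arrhenius"} (\eqn{|d| \le} tol).
#'
#' @param fit A \code{fit_result} carrying an AM deformation: either an
#'   Arrhenius-plane fit with \code{law = "am"} or a transitivity-plane
#'   fit with selected exponent 1.
#' @param tol Threshold on \eqn{|d|}; by default \code{1e-3}, widened to
#'   twice the standard error of \code{d} when that is available and
#'   larger.
#' @return A single classification string.
#' @export
classify_behavior <- function(fit, tol = 1e-3) {
  if (!inherits(fit, "fit_result") || !("d" %in% names(fit$par))) {
    tv_stop("classification needs a fit with an AM deformation parameter d",
            "tv_not_applicable")
  }
  d <- fit$par[["d"]]
  eps <- fit$par[["eps_act"]]
  se_d <- if ("d" %in% names(fit$se)) fit$se[["d"]] else NA_real_
  if (is.finite(se_d)) tol <- max(tol, 2 * se_d)
  if (abs(d) <= tol) return("Arrhenius")
  if (d < 0) return("sub-Arrhenius")
  if (eps < 0) return("anti-Arrhenius")
  "super-Arrhenius"
}
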