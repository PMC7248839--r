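# Local-polynomial derivative estimation on (possibly non-uniform)
# grids.  Used both for the empirical apparent activation energy
# Ea = -d ln k / d beta and as an independent check of the closed-form
# activation energies.

# Derivative of the interpolating quadratic through three points,
# evaluated at x0 (exact for quadratics, O(h^2) otherwise).
.quad_deriv <- function(x0, x, y) {
  stopifnot(length(x) == 3, length(y) == 3)
  d1 <- y[1] * (2 * x0 - x[2] - x[3]) / ((x[1] - x[2]) * (x[1] - x[3]))
  d2 <- y[2] * (2 * x0 - x[1] - x[3]) / ((x[2] - x[1]) * (x[2] - x[3]))
  d3 <- y[3] * (2 * x0 - x[1] - x[2]) / ((x[3] - x[1]) * (x[3] - x[2]))
  d1 + d2 + d3
}

# Pointwise derivative dy/dx on an increasing grid: three-point central
# stencils in the interior, one-sided three-point stencils at the ends.
.grid_derivative <- function(x, y) {
  n <- length(x)
  if (n < 3) tv_stop("need >= 3 points for derivative estimation",
                     "tv_input_error")
  dy <- numeric(n)
  dy[1] <- .quad_deriv(x[1], x[1:3], y[1:3])
  dy[n] <- .quad_deriv(x[n], x[(n - 2):n], y[(n - 2):n])
  if (n > 2) {
    for (i in 2:(n - 1)) {
      idx <- (i - 1):(i + 1)
      dy[i] <- .quad_deriv(x[i], x[idx], y[idx])
    }
  }
  dy
}

# Adaptive central-difference derivative of a function of beta, step
# h = max(1e-6, 1e-4 * beta); used as the numeric oracle for closed-form
# activation energies.
numeric_log_derivative <- function(f, beta) {
  vapply(beta, function(b) {
    h <- max(1e-6, 1e-4 * abs(b))
    (f(b + h) - f(b - h)) / (2 * h)
  }, numeric(1))
}
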