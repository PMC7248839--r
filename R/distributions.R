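# Finite-N statistical distributions and their convergence, through
# Euler's limit for the exponential, to the classical Poisson and
# Boltzmann laws; plus the Planck-oscillator average energy whose
# reciprocal motivates the transitivity function.

#' Binomial occupancy probability of a subvolume
#'
#' Probability that a subvolume \code{v} of a vessel of volume \code{V}
#' holding \code{N} ideal-gas particles contains exactly \code{n} of
#' them: the Bernoulli-trial binomial pmf with success probability
#' \code{v/V}.
#'
#' @param n Occupation number(s), integers in \code{0..N}.
#' @param N Total number of particles (integer >= 1).
#' @param v,V Subvolume and total volume, \code{0 < v <= V}.
#' @return Probability(ies).
#' @export
binomial_occupancy <- function(n, N, v, V) {
  if (N < 1 || N != round(N)) {
    tv_stop("N must be an integer >= 1", "tv_invalid_argument")
  }
  if (v <= 0 || V <= 0 || v > V) {
    tv_stop("volumes must satisfy 0 < v <= V", "tv_invalid_argument")
  }
  if (any(n < 0) || any(n > N) || any(n != round(n))) {
    tv_stop("n must be integer(s) in 0..N", "tv_invalid_argument")
  }
  stats::dbinom(n, size = N, prob = v / V)
}

#' Poisson limit of the occupancy distribution
#'
#' The thermodynamic-limit form of \code{\link{binomial_occupancy}}:
#' \eqn{P(n) = \bar{n}^n e^{-\bar{n}}/n!} at fixed mean occupation
#' \eqn{\bar{n} = N v/V} as \eqn{N, V \to \infty}.
#'
#' @param n Occupation number(s), non-negative integers.
#' @param n_bar Mean occupation, >= 0.
#' @return Probability(ies).
#' @export
poisson_limit <- function(n, n_bar) {
  if (!is.finite(n_bar) || n_bar < 0) {
    tv_stop("n_bar must be >= 0", "tv_invalid_argument")
  }
  if (any(n < 0) || any(n != round(n))) {
    tv_stop("n must be non-negative integer(s)", "tv_invalid_argument")
  }
  stats::dpois(n, lambda = n_bar)
}

#' Number of ways to distribute quanta among oscillators
#'
#' Stars-and-bars count \eqn{W(s, m) = \binom{s+m-1}{m}} of the ways to
#' distribute \code{m} indistinguishable quanta over \code{s} harmonic
#' oscillators.  Uses exact integer arithmetic for small systems and
#' log-gamma arithmetic above \code{s + m > 60}.
#'
#' @param s Number of oscillators (integer >= 1).
#' @param m Number of quanta (integer >= 0), scalar or vector.
#' @param log If \code{TRUE} return \eqn{\log W}.
#' @return Count(s) (or their logs).
#' @export
oscillator_ways <- function(s, m, log = FALSE) {
  .check_s(s)
  if (any(m < 0) || any(m != round(m))) {
    tv_stop("m must be non-negative integer(s)", "tv_invalid_argument")
  }
  lw <- lchoose(s + m - 1, m)
  if (log) return(lw)
  ifelse(s + m <= 60, round(exp(lw)), exp(lw))
}

#' Boltzmann distribution from oscillator counting
#'
#' Probability that a molecular subsystem holds \code{n} of the \code{M}
#' quanta of a system of \code{s} reservoir oscillators with total energy
#' \eqn{E = M h\nu}:
#' \deqn{P(n) = W(s, M-n) / \sum_{j=0}^{M} W(s, M-j),}
#' the counting construction that converges, as \eqn{s, M \to \infty} at
#' fixed \eqn{\bar{m} = M/s}, to the Boltzmann exponential with
#' \eqn{e^{-h\nu\beta} = \bar{m}/(1+\bar{m})}.  The normalization runs
#' over the admissible subsystem energies \code{0..M} (finite total
#' energy).
#'
#' @param n Quantum number(s) of the subsystem; values above \code{M}
#'   have probability zero.
#' @param s Number of reservoir oscillators (integer >= 1).
#' @param M Total number of quanta (integer >= 0).
#' @return Probability(ies).
#' @export
boltzmann_from_counting <- function(n, s, M) {
  .check_s(s)
  if (M < 0 || M != round(M)) {
    tv_stop("M must be an integer >= 0", "tv_invalid_argument")
  }
  if (any(n < 0) || any(n != round(n))) {
    tv_stop("n must be non-negative integer(s)", "tv_invalid_argument")
  }
  j <- 0:M
  lw <- lchoose(s + (M - j) - 1, M - j)
  lz <- .logsumexp(lw)
  p <- numeric(length(n))
  inside <- n <= M
  p[inside] <- exp(lchoose(s + (M - n[inside]) - 1, M - n[inside]) - lz)
  p
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Finite-N deformed Boltzmann factor
#'
#' Euler's succession \eqn{P_N(x) = (1 - x/N)^N} with
#' \eqn{x = \epsilon^\ddagger\beta}: the finite-\code{N} precursor of the
#' Boltzmann factor \eqn{e^{-x}}, reached pointwise as
#' \eqn{N \to \infty}.  With \eqn{d = 1/N} this is exactly the AM rate
#' law divided by its pre-exponential factor; \code{N} may be any
#' non-zero real.
#'
#' @param x Dimensionless energy \eqn{\epsilon^\ddagger\beta}, must
#'   satisfy \code{x < N} when \code{N > 0}.
#' @param N Deformation index (real, != 0).
#' @return Probability weight(s) \eqn{(1-x/N)^N}.
#' @export
deformed_boltzmann <- function(x, N) {
  if (!is.finite(N) || N == 0) {
    tv_stop("N must be finite and non-zero", "tv_invalid_argument")
  }
  if (N > 0 && any(x >= N)) {
    tv_stop("x must be < N for the deformed Boltzmann factor",
            "tv_domain_error")
  }
  (1 - x / N)^N
}

#' Tsallis entropic index of the finite-N distribution
#'
#' The finite-\code{N} deformed factor coincides with the Tsallis
#' q-exponential under \eqn{1/N = 1 - q}, i.e. \eqn{q = 1 - 1/N};
#' \eqn{N \to \infty} recovers Boltzmann-Gibbs (\eqn{q = 1}).
#'
#' @param N Deformation index (real, != 0), or with
#'   \code{inverse = TRUE} a q value (!= 1) to map back to N.
#' @param inverse Map q -> N instead of N -> q.
#' @return q (or N).
#' @export
tsallis_q <- function(N, inverse = FALSE) {
  if (inverse) {
    if (any(N == 1)) tv_stop("q = 1 maps to infinite N", "tv_invalid_argument")
    return(1 / (1 - N))
  }
  if (any(N == 0)) tv_stop("N must be non-zero", "tv_invalid_argument")
  1 - 1 / N
}

#' Planck-oscillator average energy
#'
#' Average energy of a quantized harmonic oscillator with level spacing
#' \eqn{h\nu}: \eqn{\bar{E}(\beta) = h\nu/(e^{h\nu\beta} - 1)}, the
#' logarithmic derivative of the geometric partition function.
#'
#' @param beta Coldness, > 0.
#' @param h_nu Energy per quantum, > 0.
#' @return Average energy value(s).
#' @export
planck_average_energy <- function(beta, h_nu) {
  if (!is.finite(h_nu) || h_nu <= 0) {
    tv_stop("h_nu must be > 0", "tv_invalid_argument")
  }
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    tv_stop("beta must be finite and > 0", "tv_invalid_argument")
  }
  h_nu / expm1(h_nu * beta)
}

#' Low-temperature expansion of the reciprocal Planck energy
#'
#' At low temperature (\eqn{h\nu\beta} large) the reciprocal average
#' energy \eqn{1/\bar{E} = (e^{h\nu\beta}-1)/h\nu} is dominated by the
#' exponential and expands as a power law in \eqn{\beta}:
#' \deqn{1/\bar{E} \simeq (1/h\nu)\left[1 + h\nu\beta +
#' (h\nu\beta)^2/2! + \ldots\right],}
#' whose full sum is \eqn{e^{h\nu\beta}/h\nu}.  This is the
#' quantum-oscillator analogue of the transitivity function.
#'
#' @inheritParams planck_average_energy
#' @param beta Coldness, >= 0.
#' @param order Highest power of \eqn{h\nu\beta} retained (0--4); the
#'   truncation error relative to the full sum is
#'   \eqn{O((h\nu\beta)^{order+1})}.
#' @return Truncated reciprocal energy value(s); \eqn{1/h\nu} at
#'   \eqn{\beta = 0}.
#' @export
reciprocal_energy_expansion <- function(beta, h_nu, order = 4) {
  if (!is.finite(h_nu) || h_nu <= 0) {
    tv_stop("h_nu must be > 0", "tv_invalid_argument")
  }
  if (any(beta < 0)) tv_stop("beta must be >= 0", "tv_invalid_argument")
  if (!order %in% 0:4) tv_stop("order must be 0..4", "tv_invalid_argument")
  x <- h_nu * beta
  acc <- 0
  for (j in 0:order) acc <- acc + x^j / factorial(j)
  acc / h_nu
}
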