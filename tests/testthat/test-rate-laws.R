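# Closed-form laws, their limits, and the identities tying the
# Arrhenius and transitivity representations together.

test_that("Arrhenius and AM closed forms give textbook values", {
  expect_equal(k_arrhenius(0, A = 1, eps_act = 1), 1)
  expect_equal(k_arrhenius(1, A = 1, eps_act = 1), exp(-1))
  expect_equal(k_arrhenius(c(0.3, 7), A = 2, eps_act = 0), c(2, 2))
  expect_error(k_arrhenius(1, A = -1, eps_act = 1),
               class = "tv_invalid_parameter")

  expect_equal(k_am(1, A = 1, eps_act = 1, d = 0.5), 0.25)
  expect_equal(k_am(1, A = 1, eps_act = 1, d = -1), 0.5)
  # d -> 0 recovers the exponential
  expect_equal(k_am(2, A = 1, eps_act = 1, d = 1e-8), exp(-2),
               tolerance = 1e-6)
})

test_that("AM domain handling: boundary extension and errors name the limit", {
  # continuous extension k = 0 exactly at beta_dagger for d > 0
  expect_equal(k_am(10, A = 1, eps_act = 1, d = 0.1), 0)
  expect_error(k_am(10, A = 1, eps_act = 1, d = 0.1, strict = TRUE),
               class = "tv_domain_error")
  err <- tryCatch(k_am(11, A = 1, eps_act = 1, d = 0.1), error = identity)
  expect_s3_class(err, "tv_domain_error")
  expect_match(conditionMessage(err), "beta_dagger")
})

test_that("AM reduces to Arrhenius along the whole plot as d -> 0", {
  beta <- seq(0, 5, length.out = 41)
  expect_lt(max(abs(log(k_am(beta, 1, 1, 1e-10)) -
                    log(k_arrhenius(beta, 1, 1)))), 1e-8)
})

test_that("VFT closed form and its divergence limit", {
  expect_equal(k_vft(0, A = 3, eps_act = 1, beta_dagger = 1), 3)
  expect_equal(k_vft(0.5, A = 1, eps_act = 1, beta_dagger = 1), exp(-1))
  b <- seq(0.9, 0.999, length.out = 20)
  k <- k_vft(b, 1, 1, 1)
  expect_true(all(diff(k) < 0))
  expect_lt(k[length(k)], 1e-300)
  expect_error(k_vft(1, 1, 1, 1), class = "tv_domain_error")
})

test_that("FG series matches its finite sums and the incomplete-gamma form", {
  # s = 3, x = 1: A e^-1 (1 + 1 + 1/2) = 2.5/e
  expect_equal(k_fg_series(1, A = 1, eps_act = 1, s = 3), 2.5 * exp(-1),
               tolerance = 1e-14)
  expect_equal(k_fg_series(1, A = 1, eps_act = 1, s = 2), 2 * exp(-1),
               tolerance = 1e-14)
  # s = 1 is exactly Arrhenius; x = 0 gives A for any s
  b <- seq(0, 5, 0.5)
  expect_equal(k_fg_series(b, 2, 1.3, 1), k_arrhenius(b, 2, 1.3))
  expect_equal(k_fg_closed(0, 5, 1, 17), 5)
  expect_error(k_fg_series(1, 1, 1, s = 0), class = "tv_invalid_parameter")

  # series/closed-form equivalence over the full working range
  x <- c(0, 0.01, 0.1, 1, 2, 5, 10, 20, 35, 50)
  for (s in c(1, 2, 3, 5, 10, 17, 30)) {
    ks <- k_fg_series(x, 1, 1, s)
    kc <- k_fg_closed(x, 1, 1, s)
    expect_equal(ks, kc, tolerance = 1e-12)
  }
})

test_that("closed-form activation energies match numerical differentiation", {
  models <- list(
    arr = arr_ref(),
    am_super = am_ref(),
    am_sub = rate_law("am", A = 1, eps_act = 1, d = -1 / 3, units = u_nat),
    vft = vft_ref(),
    fg = rate_law("fg", A = 1e8, eps_act = 25, s = 4, units = u_kj)
  )
  for (m in models) {
    beta <- switch(m$law,
      vft = seq(0.05, 0.9, length.out = 7) * m$params$beta_dagger,
      am = if (m$params$d > 0)
        seq(0.05, 0.9, length.out = 7) / (m$params$d * m$params$eps_act)
      else seq(0.1, 3, length.out = 7),
      seq(0.01, 0.45, length.out = 7)
    )
    ea_closed <- activation_energy(m, beta)
    ea_num <- -numeric_log_derivative(function(b) log(rate_constant(m, b)),
                                      beta)
    expect_equal(ea_closed, ea_num, tolerance = 1e-6)
  }
})

test_that("activation-energy spot values and Arrhenius reductions", {
  expect_equal(
    activation_energy(rate_law("am", A = 1, eps_act = 1, d = 0.5), 1), 2.0)
  # FG s=2, x=1: Ea = eps * x e^-x / Gamma(2,1) with Gamma(2,1) = 2/e
  expect_equal(
    activation_energy(rate_law("fg", A = 1, eps_act = 1, s = 2), 1), 0.5)
  expect_equal(
    activation_energy(rate_law("am", A = 1, eps_act = 7, d = 0), c(0, 1, 2)),
    rep(7, 3))
  expect_equal(
    activation_energy(rate_law("fg", A = 1, eps_act = 7, s = 1), c(0, 1, 2)),
    rep(7, 3))
})

test_that("transitivity is the reciprocal activation energy; AM is exactly linear", {
  expect_equal(transitivity(rate_law("am", A = 1, eps_act = 2, d = 0.1), 0),
               0.5)
  expect_equal(transitivity(rate_law("am", A = 1, eps_act = 1, d = 0.5), 1),
               0.5)
  expect_equal(transitivity(rate_law("fg", A = 1, eps_act = 1, s = 2), 1),
               2.0)

  # noiseless straight-line fit through AM gamma samples recovers
  # slope -d and intercept 1/eps to near machine precision
  m <- rate_law("am", A = 1, eps_act = 4, d = 0.07)
  beta <- seq(0, 3, length.out = 25)
  cf <- stats::lm.fit(cbind(1, beta), transitivity(m, beta))$coefficients
  expect_equal(unname(cf[1]), 0.25, tolerance = 1e-10)
  expect_equal(unname(cf[2]), -0.07, tolerance = 1e-10)
})

test_that("generalized transitivity law reproduces the integer classes", {
  beta <- seq(0, 0.45, length.out = 12)
  bd <- 0.5
  # zeta = 0: Arrhenius
  expect_equal(rate_from_transitivity(beta, 2, 3, Inf, 0),
               k_arrhenius(beta, 2, 3))
  # zeta = 1: AM with d = 1/(eps * beta_dagger)
  expect_equal(rate_from_transitivity(beta, 1, 40, bd, 1, "quadrature"),
               k_am(beta, 1, 40, d = 1 / (40 * bd)), tolerance = 1e-8)
  # zeta = 2: VFT
  expect_equal(rate_from_transitivity(beta, 1, 10, bd, 2, "quadrature"),
               k_vft(beta, 1, 10, bd), tolerance = 1e-8)
  expect_equal(rate_from_transitivity(beta, 1, 3, Inf, 0, "quadrature"),
               k_arrhenius(beta, 1, 3), tolerance = 1e-8)
})

test_that("non-integer exponent quadrature agrees with a brute-force trapezoid", {
  A <- 2; eps <- 1; bd <- 2; zeta <- 1.5; b <- 1
  kq <- rate_from_transitivity(b, A, eps, bd, zeta, "quadrature")
  u <- seq(0, b, length.out = 200001)
  f <- (1 - u / bd)^(-zeta)
  trap <- sum((f[-1] + f[-length(f)]) / 2) * (u[2] - u[1])
  expect_equal(kq, A * exp(-eps * trap), tolerance = 1e-6)
  expect_error(rate_from_transitivity(2.5, A, eps, bd, zeta),
               class = "tv_domain_error")
})

test_that("rate laws are non-increasing in coldness for positive barriers", {
  beta <- seq(0, 0.9, length.out = 50)
  laws <- list(
    k_arrhenius(beta, 1, 2),
    k_am(beta, 1, 2, 0.3),
    k_am(beta, 1, 2, -0.3),
    k_vft(beta, 1, 2, 1),
    k_fg_closed(beta, 1, 2, 6),
    rate_from_transitivity(beta, 1, 2, 1, 1.7)
  )
  for (k in laws) expect_true(all(diff(k) <= 0))
})

test_that("AM expansion error scales as the fifth power of eps*beta", {
  # measured where the x^5 term clears double-precision rounding noise
  d <- 0.5
  x <- 10^seq(log10(0.02), log10(0.2), length.out = 9)
  err <- abs(am_expansion(x, 1, 1, d) - k_am(x, 1, 1, d))
  slope <- stats::lm.fit(cbind(1, log(x)), log(err))$coefficients[2]
  expect_equal(unname(slope), 5, tolerance = 0.2)

  # d = 0 is exact; small-x agreement; higher order strictly better
  expect_equal(am_expansion(0.7, 2, 1, 0), 2 * exp(-0.7))
  expect_equal(am_expansion(0.1, 1, 1, 0.1), k_am(0.1, 1, 1, 0.1),
               tolerance = 1e-7)
  e2 <- abs(am_expansion(0.2, 1, 1, 0.1, order = 2) - k_am(0.2, 1, 1, 0.1))
  e4 <- abs(am_expansion(0.2, 1, 1, 0.1, order = 4) - k_am(0.2, 1, 1, 0.1))
  expect_lt(e4, e2)
  # halving beta cuts the order-4 truncation error by at least 2^5
  e_big <- abs(am_expansion(0.08, 1, 1, 0.1) - k_am(0.08, 1, 1, 0.1))
  e_small <- abs(am_expansion(0.04, 1, 1, 0.1) - k_am(0.04, 1, 1, 0.1))
  expect_lt(e_small, e_big / 2^5 * 1.2)
})

test_that("tunneling deformation follows the barrier-frequency formula", {
  # h*nu = 2*eps: d = -1/3; h*nu = eps: d = -1/12 (h folded into nu here)
  expect_equal(d_from_tunneling(2, 1, h = 1), -1 / 3)
  expect_equal(d_from_tunneling(1, 1, h = 1), -1 / 12)
  expect_equal(d_from_tunneling(1e-8, 1, h = 1), 0, tolerance = 1e-15)
  expect_lt(d_from_tunneling(6e12, 40), 0)   # always quantum propensity
  expect_error(d_from_tunneling(1e12, 0), class = "tv_invalid_parameter")
})

test_that("thermal limits obey eps_dagger = d*eps and the kB relation", {
  tl <- thermal_limits(10, 0.1, u_nat)
  expect_equal(tl$eps_dagger, 1)
  expect_equal(tl$beta_dagger, 1)
  expect_equal(tl$T_dagger, 1)   # natural units: T = eps/kB with kB = 1

  tl2 <- thermal_limits(40, 0.05, u_kj)
  expect_equal(tl2$eps_dagger, 2)
  expect_equal(tl2$T_dagger, 2 / 0.0083144626)
  expect_equal(1 - 0.05 * 40 / (0.0083144626 * tl2$T_dagger), 0,
               tolerance = 1e-12)
  # the AM law vanishes exactly at beta_dagger
  expect_equal(k_am(tl2$beta_dagger, 1e13, 40, 0.05), 0)

  expect_error(thermal_limits(40, -0.1), class = "tv_no_finite_limit")
  expect_error(thermal_limits(40, 0), class = "tv_no_finite_limit")
})

test_that("sub-Arrhenius AM approaches the Wigner power-law asymptote", {
  expect_equal(wigner_asymptote_residual(1e6, 1, 1, -1), 1, tolerance = 1e-5)
  expect_equal(wigner_asymptote_residual(1, 1, 1, -1), 0.5)
  b <- 2^(0:12)
  res <- wigner_asymptote_residual(b, 1, 1, -0.5)
  expect_true(all(diff(abs(res - 1)) < 0))
  expect_error(wigner_asymptote_residual(1, 1, 1, 0.2),
               class = "tv_not_applicable")
})
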