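# Parameter recovery in the Arrhenius plane, empirical transitivity
# curves, exponent selection, crossover detection and classification.

test_that("noiseless generator round-trips recover every law's parameters", {
  cases <- list(
    list(model = arr_ref(), law = "arrhenius",
         truth = c(eps_act = 40)),
    list(model = am_ref(), law = "am",
         truth = c(eps_act = 40, d = 0.05)),
    list(model = vft_ref(), law = "vft",
         truth = c(eps_act = 10,
                   beta_dagger = beta_from_temperature(150, u_kj))),
    list(model = rate_law("fg", A = 1e13, eps_act = 30, s = 5, units = u_kj),
         law = "fg", truth = c(eps_act = 30, s = 5))
  )
  for (cs in cases) {
    ds <- generate_rate_data(synthetic_spec(cs$model, 250, 400, n = 30))
    fit <- fit_arrhenius_plane(ds, cs$law)
    for (nm in names(cs$truth)) {
      expect_equal(fit$par[[nm]], cs$truth[[nm]], tolerance = 1e-5,
                   label = sprintf("%s:%s", cs$law, nm))
    }
    expect_equal(exp(fit$par[["logA"]]), 1e13, tolerance = 1e-5)
    # reported RSS is consistent with the stored parameters
    pred <- switch(cs$law,
      arrhenius = k_arrhenius(ds$beta, exp(fit$par[["logA"]]),
                              fit$par[["eps_act"]]),
      am = k_am(ds$beta, exp(fit$par[["logA"]]), fit$par[["eps_act"]],
                fit$par[["d"]]),
      vft = k_vft(ds$beta, exp(fit$par[["logA"]]), fit$par[["eps_act"]],
                  fit$par[["beta_dagger"]]),
      fg = k_fg_closed(ds$beta, exp(fit$par[["logA"]]), fit$par[["eps_act"]],
                       fit$par[["s"]]))
    expect_equal(fit$rss, sum((log(ds$k) - log(pred))^2), tolerance = 1e-10)
  }
})

test_that("fits refuse datasets that are too small", {
  ds <- rate_dataset(beta = c(0.3, 0.4), k = c(2, 1))
  expect_error(fit_arrhenius_plane(ds, "arrhenius"), class = "tv_input_error")
  ds4 <- rate_dataset(beta = c(0.1, 0.2, 0.3, 0.4), k = c(4, 3, 2, 1))
  expect_error(empirical_transitivity(ds4), class = "tv_input_error")
})

test_that("deformation is recovered to within 0.01 under 2% noise", {
  d_hat <- vapply(1:20, function(s) {
    ds <- generate_rate_data(synthetic_spec(am_ref(), 250, 400, n = 30,
                                            sigma = 0.02, seed = s))
    fit_arrhenius_plane(ds, "am")$par[["d"]]
  }, numeric(1))
  expect_lte(stats::median(abs(d_hat - 0.05)), 0.2 * 0.05)
})

test_that("empirical transitivity reproduces the closed forms", {
  # Arrhenius: gamma constant at 1/eps on interior points
  ds <- generate_rate_data(synthetic_spec(arr_ref(), 250, 400, n = 20))
  cv <- empirical_transitivity(ds, method = "central")
  interior <- 2:(length(cv$beta) - 1)
  expect_equal(cv$gamma[interior], rep(1 / 40, length(interior)),
               tolerance = 1e-6)

  # AM: gamma linear with slope -d
  ds2 <- generate_rate_data(synthetic_spec(am_ref(), 260, 400, n = 40))
  cv2 <- empirical_transitivity(ds2, method = "central")
  keep <- 2:(length(cv2$beta) - 1)
  cf <- stats::lm.fit(cbind(1, cv2$beta[keep]), cv2$gamma[keep])$coefficients
  expect_lt(abs(cf[2] + 0.05), 1e-3)
  expect_lt(abs(cf[1] - 1 / 40), 1e-4)

  # constant-rate data: Ea ~ 0 is masked, never inverted
  ds3 <- rate_dataset(beta = seq(0.1, 0.5, length.out = 8), k = rep(2, 8))
  cv3 <- empirical_transitivity(ds3, method = "central")
  expect_true(all(cv3$masked))
  expect_true(all(is.na(cv3$gamma)))
})

test_that("free-exponent transitivity fit selects the generating class", {
  models <- list(arrhenius = arr_ref(), am = am_ref(), vft = vft_ref())
  expected <- c(arrhenius = 0, am = 1, vft = 2)
  for (nm in names(models)) {
    ds <- generate_rate_data(synthetic_spec(models[[nm]], 250, 400, n = 30))
    fit <- fit_transitivity_plane(empirical_transitivity(ds))
    expect_identical(fit$zeta, expected[[nm]], label = nm)
  }
})

test_that("zeta = 1 plane fit recovers the AM slope and agrees across planes", {
  ds <- generate_rate_data(synthetic_spec(am_ref(), 250, 400, n = 30))
  plane_t <- fit_transitivity_plane(empirical_transitivity(ds), zeta = 1)
  plane_a <- fit_arrhenius_plane(ds, "am")
  expect_equal(plane_t$par[["d"]], 0.05, tolerance = 1e-3 / 0.05)
  expect_equal(plane_t$par[["eps_act"]], plane_a$par[["eps_act"]],
               tolerance = 5e-3)
  expect_equal(plane_t$par[["d"]], plane_a$par[["d"]], tolerance = 5e-3 / 0.05)
})

test_that("transitivity fit needs enough unmasked points", {
  cv <- structure(list(beta = 1:6 / 10, gamma = rep(NA_real_, 6),
                       Ea = rep(0, 6), masked = rep(TRUE, 6),
                       lnk = rep(0, 6), method = "central",
                       units = u_nat),
                  class = "transitivity_curve")
  expect_error(fit_transitivity_plane(cv), class = "tv_input_error")
})

test_that("crossover search finds the exact grid-point kink (noiseless)", {
  fx <- two_regime_fixture(n = 19)
  fit <- detect_crossover(empirical_transitivity(fx$data))
  expect_false(is.null(fit$breakpoint))
  expect_equal(fit$breakpoint$beta_c, fx$beta_c)
  expect_equal(fit$breakpoint$left[["d"]], 0.02, tolerance = 1e-3)
  expect_equal(fit$breakpoint$right[["d"]], 0.10, tolerance = 1e-3)
  expect_equal(fit$breakpoint$T_c,
               temperature_from_beta(fx$beta_c, u_nat))
})

test_that("single-regime and pure-noise data never yield a breakpoint", {
  ma <- rate_law("am", A = 1e6, eps_act = 1, d = 0.02, units = u_nat)
  ds <- generate_rate_data(synthetic_spec(ma, 0.1, 1, n = 19, grid = "beta"))
  expect_null(detect_crossover(empirical_transitivity(ds))$breakpoint)

  # seeded noise around a constant transitivity
  arr <- rate_law("arrhenius", A = 1e6, eps_act = 1, units = u_nat)
  dn <- generate_rate_data(synthetic_spec(arr, 0.1, 1, n = 19, grid = "beta",
                                          sigma = 0.02, seed = 7))
  expect_null(detect_crossover(empirical_transitivity(dn))$breakpoint)
})

test_that("a reported breakpoint never fits worse than the single line", {
  for (s in 1:10) {
    fx <- two_regime_fixture(n = 19, sigma = 0.02, seed = s)
    cv <- empirical_transitivity(fx$data)
    fit <- detect_crossover(cv)
    if (!is.null(fit$breakpoint)) {
      keep <- !cv$masked
      single <- stats::lm.fit(cbind(1, cv$beta[keep]), cv$gamma[keep])
      # decision is made on ln k residuals: compare there
      ds_single <- fit_arrhenius_plane(
        rate_dataset(beta = cv$beta, k = exp(cv$lnk), units = u_nat), "am")
      expect_lte(fit$rss, ds_single$rss)
    }
  }
})

test_that("classification maps the deformation sign and magnitude", {
  mk_fit <- function(d, eps = 40, se_d = NA_real_) {
    structure(list(law = "am",
                   par = c(logA = 30, eps_act = eps, d = d),
                   se = c(logA = NA, eps_act = NA, d = se_d),
                   rss = 0, aicc = 0, n = 10, zeta = NULL,
                   breakpoint = NULL, units = u_kj),
              class = "fit_result")
  }
  expect_identical(classify_behavior(mk_fit(0.05)), "super-Arrhenius")
  expect_identical(classify_behavior(mk_fit(-1 / 3)), "sub-Arrhenius")
  expect_identical(classify_behavior(mk_fit(0.05, eps = -20)),
                   "anti-Arrhenius")
  expect_identical(classify_behavior(mk_fit(1e-9)), "Arrhenius")
  # a large standard error widens the Arrhenius band
  expect_identical(classify_behavior(mk_fit(0.01, se_d = 0.02)), "Arrhenius")
  not_am <- structure(list(law = "vft", par = c(eps_act = 1), se = c(NA)),
                      class = "fit_result")
  expect_error(classify_behavior(not_am), class = "tv_not_applicable")
})
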