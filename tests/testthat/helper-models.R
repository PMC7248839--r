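# Shared fixtures: the unit systems and reference models most tests use.

u_kj <- unit_system("kJ/mol")
u_nat <- unit_system("kB.K")

am_ref <- function() rate_law("am", A = 1e13, eps_act = 40, d = 0.05,
                              units = u_kj)
arr_ref <- function() rate_law("arrhenius", A = 1e13, eps_act = 40,
                               units = u_kj)
vft_ref <- function() rate_law("vft", A = 1e13, eps_act = 10,
                               beta_dagger = beta_from_temperature(150, u_kj),
                               units = u_kj)

# Two-regime fixture in natural units: transitivity slopes -0.02 / -0.10
# meeting at a grid point of the beta-linear grid over [1, 10].
two_regime_fixture <- function(n = 19, sigma = 0, seed = 1, beta_c = 5.5) {
  ma <- rate_law("am", A = 1e6, eps_act = 1, d = 0.02, units = u_nat)
  mb <- am_segment_through(0.10, beta_c, transitivity(ma, beta_c),
                           units = u_nat)
  list(
    data = generate_two_regime(ma, mb, beta_c, T_min = 0.1, T_max = 1,
                               n = n, grid = "beta", sigma = sigma,
                               seed = seed),
    model_a = ma, model_b = mb, beta_c = beta_c
  )
}
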