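# transitivity

Tools for modelling, fitting and classifying the temperature dependence
of rate processes that deviate from the Arrhenius law — the
super-Arrhenius bending seen at low temperature in enzymatic catalysis,
glass-forming liquids, geochemical fluidity and plasma chemistry, and
the sub-Arrhenius flattening caused by quantum tunneling.  It is aimed
at kineticists who have a table of rate constants (or viscosities,
relaxation times, diffusivities) versus temperature and want to know
*which* rate law the data follow, with physically meaningful parameters.

## The two planes

Everything works in the coldness variable `β = 1/(k_B T)`.  The
**Arrhenius plane** plots `ln k` against `β`; the apparent (Tolman/IUPAC)
activation energy is its local slope,

    E_a(β) = −d ln k / dβ.

The **transitivity plane** plots the reciprocal,

    γ(β) = 1 / E_a(β),

interpreted as the propensity of the process to proceed.  Its power is
that common rate laws become elementary curves there:

| law | k(β) | γ(β) |
|---|---|---|
| Arrhenius | `A e^(−ε‡β)` | constant `1/ε‡` |
| Aquilanti–Mundim (AM) | `A (1 − d ε‡ β)^(1/d)` | straight line `1/ε‡ − d β` |
| Vogel–Fulcher–Tammann (VFT) | `A exp[−ε‡β/(1 − β/β†)]` | `1/ε‡ (1 − β/β†)^2` |
| Fowler–Guggenheim (FG, s oscillators) | `A Γ(s, ε‡β)/Γ(s)` | closed form in incomplete Γ |

All of these are members of the generalized transitivity law

    γ(β) = 1/ε‡ · (1 − β/β†)^ζ,

whose exponent indexes universality classes: ζ = 0, 1, 2 regenerate the
Arrhenius, AM and VFT laws, and non-integer ζ is fitted freely.  The AM
deformation `d` measures the curvature of the Arrhenius plot (`d < 0`
sub-Arrhenius / quantum propensity, `d > 0` super-Arrhenius, with a
lowest operative temperature `T† = d·ε‡/k_B`; `d > 0` with `ε‡ < 0` is
anti-Arrhenius) and connects to Tsallis statistics through
`d = 1/N = 1 − q`.  The package also implements the finite-`N`
statistical distributions behind that connection — the deformed
Boltzmann factor `(1 − x/N)^N`, binomial subvolume occupancy and
oscillator-counting distributions — together with their Euler-limit
convergence to the exponential, Poisson and Boltzmann laws.

## Worked example

Simulate 30 rate constants from a super-Arrhenius (AM) law with 2 %
multiplicative noise, then recover the law from the data:

```r
library(transitivity)
u <- unit_system("kJ/mol")
truth <- rate_law("am", A = 1e13, eps_act = 40, d = 0.05, units = u)
spec <- synthetic_spec(truth, T_min = 250, T_max = 400, n = 30,
                       sigma = 0.02, seed = 42)
ds <- generate_rate_data(spec)

fit <- fit_arrhenius_plane(ds, law = "am")
print(fit)
#> <fit_result: am>  n = 30, RSS = 0.0168685, AICc = -214.905
#>           estimate   std_error
#> logA    29.9098000 2.34301e-02
#> eps_act 39.9627000 3.97882e-02
#> d        0.0500494 5.59236e-05

classify_behavior(fit)
#> [1] "super-Arrhenius"
thermal_limits(fit$par[["eps_act"]], fit$par[["d"]], u)
#> <thermal_limits> eps_dagger = 2.00011 kJ/mol, T_dagger = 240.558 K,
#>                  beta_dagger = 0.499973 (kJ/mol)^-1

# transitivity-plane route: differentiate ln k, profile the exponent
curve <- empirical_transitivity(ds, method = "spline")
fit_transitivity_plane(curve)$zeta
#> [1] 1
```

The activation energy (39.96 ± 0.04 kJ/mol), deformation
(0.05005 ± 0.00006) and prefactor (`e^29.91 ≈ 9.8e12`) match the
generating values; the implied minimum operative temperature is
240.6 K, just below the coldest datum, and the free-exponent fit in the
transitivity plane places the data in the AM universality class
(ζ = 1).  `detect_crossover()` additionally searches a transitivity
curve for a kink between two AM regimes and reports the crossover
temperature only when an information criterion clearly prefers it.

A command-line wrapper with `simulate | fit | transitivity | classify |
crossover` subcommands is installed at
`system.file("scripts", "transitivity-cli.R", package = "transitivity")`.

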