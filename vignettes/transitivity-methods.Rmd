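---
title: "Methods: rate laws, transitivity fitting and crossover detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate laws, transitivity fitting and crossover detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transitivity)
```

## The model family

A rate process observed as rate constants $k$ over temperatures $T$ is
analysed in coldness $\beta = 1/(k_B T)$.  The apparent activation
energy is the Tolman/IUPAC derivative
$E_a(\beta) = -\mathrm{d}\ln k/\mathrm{d}\beta$, and the *transitivity*
is its reciprocal, $\gamma(\beta) = 1/E_a(\beta)$.  The package treats
four closed-form laws plus the generalized family that contains them:

* **Arrhenius** $k = A e^{-\epsilon^\ddagger \beta}$: constant
  $E_a = \epsilon^\ddagger$, constant
  $\gamma = 1/\epsilon^\ddagger$.
* **Aquilanti–Mundim (AM)**
  $k = A(1 - d\,\epsilon^\ddagger\beta)^{1/d}$: the deformed
  exponential obtained by *not* taking Euler's limit
  $(1-x/N)^N \to e^{-x}$, with $d = 1/N$.  Its transitivity is exactly
  linear, $\gamma = 1/\epsilon^\ddagger - d\beta$, which is why the
  transitivity plane is the natural diagnostic: curvature of the
  Arrhenius plot becomes a slope.  $d < 0$ gives concave
  (sub-Arrhenius) plots, the signature of tunneling — for a parabolic
  barrier, $d = -\tfrac{1}{3}(h\nu^\ddagger/2\epsilon^\ddagger)^2$ —
  and as $\beta \to \infty$ the sub-Arrhenius law flattens into the
  Wigner-type power law $A(|d|\epsilon^\ddagger\beta)^{1/d}$.
  $d > 0$ gives convex (super-Arrhenius) plots with a finite thermal
  limit $\beta^\dagger = 1/(d\epsilon^\ddagger)$, i.e. a lowest
  operative temperature $T^\dagger = d\,\epsilon^\ddagger/k_B$.
* **Vogel–Fulcher–Tammann (VFT)**
  $k = A\exp[-\epsilon^\ddagger\beta/(1-\beta/\beta^\dagger)]$, the
  empirical law of glass-forming transport coefficients.
* **Fowler–Guggenheim (FG)** unimolecular law
  $k = A e^{-x}\sum_{r=0}^{s-1} x^r/r!$ with
  $x = \epsilon^\ddagger\beta$, equivalently
  $A\,\Gamma(s,x)/\Gamma(s)$: activation energy accumulated over $s$
  internal oscillators.  Its $E_a =
  \epsilon^\ddagger x^{s-1}e^{-x}/\Gamma(s,x)$ *decreases* with
  $\beta$, a distinct mild non-Arrhenius signature.

All of these derive from one generalized transitivity law
$$\gamma(\beta) = \frac{1}{\epsilon^\ddagger}
  \left(1 - \frac{\beta}{\beta^\dagger}\right)^\zeta,$$
with $\ln k(\beta) = \ln A - \int_0^\beta \gamma^{-1}$.  The exponent
$\zeta$ indexes universality classes: $\zeta = 0, 1, 2$ give exactly
the Arrhenius, AM and VFT laws; non-integer $\zeta$ is admitted and
evaluated by adaptive quadrature.

## Units

Temperatures are always kelvin; $\beta$ and energies live in a
declared energy unit (`kJ/mol`, `kcal/mol`, `eV`, or natural `kB.K`
units), with $k_B$ fixed per unit (default kJ/mol,
$k_B = 0.0083144626$ kJ mol⁻¹ K⁻¹).  The prefactor $A$ passes through
in whatever rate unit the data use: all fitting happens on $\ln k$, so
$A$'s unit only shifts an intercept.

## Fitting: what is estimated and how

**Arrhenius plane** (`fit_arrhenius_plane`): weighted least squares on
$\ln k$ — rate data span orders of magnitude, so log-space residuals
(equivalently multiplicative lognormal noise) are the operative error
model.  The plain Arrhenius line seeds every nonlinear fit;
Levenberg–Marquardt (via `minpack.lm`) then runs from multiple starts
($d \in \{-0.1, -0.01, 10^{-6}, 0.01, 0.1\}$ for AM;
$\beta^\dagger \in \{1.2, 1.5, 3, 10\}\times\beta_{\max}$ for VFT),
keeping the lowest RSS.  A deterministic multi-start was chosen over
stochastic annealing for bit-reproducibility; the FG integer $s$ is
profiled exhaustively over $1..30$.  Standard errors come from the
Jacobian at the optimum.  Domain violations during iteration are
handled by clamping the deformed logarithm, which collapses the
predicted $\ln k$ and pushes the optimizer back inside — no hard
constraint machinery is needed.

**Empirical transitivity** (`empirical_transitivity`): $E_a$ is
estimated pointwise from the data.  The default is a local quadratic
stencil (exact three-point central differences on the non-uniform
$\beta$ grid, one-sided at the ends), which is unbiased up to
$O(h^2)$ and exact for log-linear data; for noisy data a smoothing
spline of $\ln k$ with GCV-selected smoothness is available
(`method = "spline"`).  The central stencil is the default because the
package's primary diagnostic workflows start from dense, low-noise
(often synthetic or computed) rate tables, where the spline's GCV
smoothing adds variance without reducing bias.  Points with
$|E_a|$ below a tolerance ($10^{-8}$ of the data's overall log-slope,
floored at a unit slope so exactly-flat data are always caught) are
masked rather than inverted.

**Exponent selection** (`fit_transitivity_plane`): with $\zeta$ free,
candidates on $[0, 4]$ in steps of 0.05 (containing the integer
classes) are each fitted by nonlinear least squares on $\gamma$, and
compared by AICc with the exponent charged as a parameter
($\zeta = 0$ fits only a constant).  Among candidates within 2 AICc
units of the best, the tie goes to fewer parameters, then to integer
exponents.  Near-zero RSS values from noiseless data are floored at a
resolution scale ($10^{-10}$ of the mean $|\gamma|$ per point) so that
criteria compare parameter counts instead of rounding noise.

**Crossover detection** (`detect_crossover`): a mechanism change
appears as a kink between two straight transitivity lines.  Every
interior grid point with at least three points on each side is a
candidate $\beta_c$ (the candidate belongs to both segments, so a
noiseless kink is recovered uniquely and exactly).  Candidates are
scored by two-line RSS in the transitivity plane; the *decision*,
however, is made in the Arrhenius plane whenever the curve carries its
$\ln k$ values: differentiation turns independent measurement noise
into strongly autocorrelated $\gamma$ noise, and an information
criterion applied there badly overfits (in simulation, spurious
breakpoints in roughly a third of pure single-regime datasets).  So a
piecewise-AM model — continuous in both $\gamma$ and $\ln k$ at
$\beta_c$, 5 free parameters — is profiled over all candidates and
compared with the single AM law (3 parameters) by AICc on $\ln k$
residuals, where the noise is uncorrelated.  Because $\beta_c$ is
maximally selected over $m$ candidates, the break model's criterion is
additionally charged $2\ln m$ (a Bonferroni-type selection penalty).
The single-line model is kept whenever the criterion difference is
below 2.  Under the package's simulation conditions (19-point grids,
2 % noise, slopes $-0.02$/$-0.10$) this recovers the true breakpoint
within one grid step in 100/100 replicates with 0/100 false positives.

**Classification** (`classify_behavior`): the fitted $d$ maps to
sub-/super-/anti-Arrhenius with an $|d| \le 10^{-3}$ Arrhenius band,
widened to twice the standard error of $d$ when available — a point
estimate smaller than its own uncertainty should not be called
curvature.

## Finite-N distributions

The statistical side implements the pre-limit distributions whose
Euler limits are the classical laws: binomial subvolume occupancy
$\to$ Poisson at fixed mean occupancy; the deformed factor
$(1-x/N)^N \to e^{-x}$; and the oscillator-counting distribution
$P(n) \propto W(s, M-n)$ with $W(s,m) = \binom{s+m-1}{m}$, whose
level ratio tends to the Boltzmann factor
$\bar{m}/(1+\bar{m}) = e^{-h\nu\beta}$.  Two implementation choices:
the counting normalization sums over the admissible subsystem energies
$0..M$ (the printed unconstrained sum would diverge; the finite-energy
reading reproduces the Boltzmann limit), and the coldness implied by a
finite system is *defined* through that level ratio for convergence
tests.  Combinatorics switch from exact integers to log-gamma
arithmetic above $s + m > 60$.  The low-temperature reciprocal of the
Planck oscillator energy is implemented as the printed power-law
series (leading term 1), i.e. the asymptote $e^{h\nu\beta}/h\nu$ of
the exact reciprocal $(e^{h\nu\beta}-1)/h\nu$; it is documented and
tested as an asymptotic form, not an identity.

## Numerical choices

* $k_{AM}$ is evaluated as $\exp(\mathrm{log1p}(-d\epsilon^\ddagger
  \beta)/d)$; the naive power form loses six decimal digits by
  $d \sim 10^{-10}$, visibly breaking the Arrhenius reduction.
* At exactly $\beta = \beta^\dagger$ the super-Arrhenius AM law
  returns its continuous extension $k = 0$ (the operative lower
  limit); `strict = TRUE` turns the boundary into an error.
* Closed-form activation energies are validated against adaptive
  central differences of $\ln k$ with step
  $h = \max(10^{-6}, 10^{-4}\beta)$ at $10^{-6}$ relative.
* Non-integer-$\zeta$ rate reconstruction uses adaptive quadrature at
  $10^{-10}$ absolute/relative tolerance, cross-checked against a
  $2\times10^5$-interval trapezoid at $10^{-6}$.
* The fifth-order truncation scaling of the deformed-exponential
  expansion is verified on $\epsilon^\ddagger\beta \in [0.02, 0.2]$:
  below that window the $x^5$ term sits beneath double-precision
  rounding of $k \approx 1$ and the measurement would only probe
  noise.
* Seeded noise generation saves and restores the caller's RNG state,
  so generators are reproducible without clobbering user code.

## What the synthetic generator does and does not emulate

`synthetic_spec`/`generate_rate_data` produce rate tables from a known
law on a temperature window (linear in $T$ or in $\beta$) with
constant relative lognormal noise — the error structure implied by
log-space fitting and typical of rate measurements spanning decades.
The reference validation conditions are 30 points on 250–400 K with
$A = 10^{13}$, $\epsilon^\ddagger = 40$ kJ/mol, $d = 0.05$ (placing
$T^\dagger \approx 240.6$ K just below the window, the demanding
near-singular regime) and $\sigma = 2\%$; crossover studies use
19-point $\beta$-linear grids in natural units with transitivity
slopes $-0.02$/$-0.10$ meeting at a grid point.  Replicate studies use
100 seeds; these sizes keep the full suite under a minute while
leaving Monte Carlo margins far from the pass thresholds.  The
generator does *not* emulate temperature-dependent heteroscedasticity,
calibration drift, or correlated instrument error; passing recovery
tests therefore demonstrates correctness of the estimators under the
stated noise model, not robustness to arbitrary real-world error
structure.  Two-regime data are built continuous in both $\gamma$ and
$\ln k$ at the crossover; real mechanism changes need not be
continuous, in which case the breakpoint remains detectable but the
segment parameters near the joint are biased.

## Known limitations

* The generalized-$\zeta$ fit assumes $\gamma \to 1/\epsilon^\ddagger$
  at $\beta = 0$ with reference coldness $\beta_0 = 0$; Laurent-type
  expansions about a nonzero $\beta_0$ are not fitted.
* Crossover detection assumes exactly two AM (linear-$\gamma$)
  regimes; three-regime data will report the dominant kink only.
* FG fits profile integer $s \le 30$; physically larger molecules are
  capped at the boundary rather than extrapolated.
* No experimental datasets ship with the package; validation is
  entirely against the seeded generator with known ground truth.
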