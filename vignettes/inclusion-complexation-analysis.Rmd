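---
title: "Analysing drug–cyclodextrin inclusion complexation: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing drug-cyclodextrin inclusion complexation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(cdinclusion)
```

Cyclodextrins solubilise poorly water-soluble drugs by enclosing them in a
hydrophobic cavity. This package implements the quantitative workflow used to
characterise such host–guest systems — here celecoxib with
hydroxypropyl-β-cyclodextrin (HP-β-CD) as the running example — from two
directions: saturation-solubility experiments (phase-solubility analysis) and
pulling-based free-energy calculations (Jarzynski reconstruction, state
thermodynamics, trajectory statistics). A synthetic-data module generates
every input with the statistical structure the estimators assume, so the
whole pipeline is testable without laboratory or simulation output.

Units are fixed globally: kcal/mol, Å, ns, K, mol/L, with
R = 1.987×10⁻³ kcal/(mol·K) (`gas_constant_kcal()`).

## Phase-solubility analysis

For the equilibrium $D + n\,CD \leftrightarrow D\,CD_n$, with coexisting
1:1 and 1:2 complexes the total dissolved drug at saturation is

$$S_{tot} = S_0\left(1 + K_{1:1}[CD] + K_{1:1}K_{1:2}[CD]^2\right),$$

where $S_0$ is the intrinsic solubility. Four estimators are provided:

* **`classify_profile()`** fits a quadratic in $[CD]$ and tests the
  curvature term: significantly positive ⇒ `A_p` (higher-order
  complexation), insignificant ⇒ `A_L` (linear, first-order),
  significantly negative ⇒ `indeterminate` (outside the 1:1/1:2 model
  rather than forced into `A_L`). Default `alpha = 0.05`. Zero-residual
  fits (exact model data) are handled by a relative-curvature fallback
  because the t-test degenerates there.
* **`fit_loglog_stoichiometry()`** regresses
  $\log_{10}(S_{tot}-S_0)$ on $\log_{10}[CD]$; the slope estimates the
  effective stoichiometry $n$ (exactly 1 for pure 1:1 data, strictly
  between 1 and 2 for mixed 1:1/1:2 data). Points with
  $S_{tot} \le S_0$ are a hard error, never silently dropped — dropping
  them biases the slope. Base-10 logs; the slope is base-invariant.
* **`fit_al_k11()`** uses the A_L slope formula
  $K_{1:1} = m/(S_0(1-m))$, valid for slopes in (0, 1); slopes outside
  are an error, not a clamp.
* **`fit_ap_linearized()`** regresses $(S_{tot}-S_0)/[CD]$ on $[CD]$:
  intercept $K_{1:1}S_0$, slope $K_{1:1}K_{1:2}S_0$, with a delta-method
  covariance for $(K_{1:1}, K_{1:2})$. A slightly negative slope (the
  degenerate pure-1:1 case under noise) is clamped to $K_{1:2}=0$ with the
  raw value retained.
* **`fit_ap_nonlinear()`** fits the forward model directly by
  box-constrained Levenberg–Marquardt ($K \ge 0$), initialised from the
  linearized estimates. Its default objective minimises squared
  *relative* residuals. This was a genuinely open design choice: the
  classical description is plain least squares, but the package's error
  model for solubility measurements is multiplicative with constant CV
  (chromatographic error scales with concentration), under which plain
  SSE lets the largest concentrations dominate and determines $K_{1:1}$
  poorly — in simulation at 2% CV the unweighted fit roughly triples the
  median $K_{1:1}$ error. `weighting = "absolute"` restores the plain
  objective; both coincide on noiseless data.

**Concentration convention.** Field practice, followed here by default, fits
against *total* cyclodextrin concentration even though the equilibrium is
written in free concentration. `predict_total_solubility(...,
free_cd_correction = TRUE)` makes the approximation explicit by solving the
mass balance
$[CD]_{tot} = [CD] + S_0K_{1:1}[CD] + 2S_0K_{1:1}K_{1:2}[CD]^2$ for the free
concentration (bracketed root on $[0, [CD]_{tot}]$, which always exists for
admissible parameters). For a pure 1:1 system generated under the free-CD
balance, the A_L formula then recovers the true constant rather than the
total-CD approximation.

**$S_0$ handling.** Unless supplied, $S_0$ is the mean of the zero-CD
measurements. Every linearization hinges on it, so the resolution rule is
shared and explicit.

**Identifiability caveat.** When $K_{1:2} \gg K_{1:1}$ the intercept
$K_{1:1}S_0$ can fall below the noise floor and only the product
$K_{1:1}K_{1:2}$ is well determined; no estimator can then recover
$K_{1:1}$ individually at realistic noise. Recovery tests therefore use a
well-conditioned system ($K_{1:1}=100$, $K_{1:2}=50$ L/mol,
$S_0=10^{-5}$ mol/L).

```{r}
d <- sim_phase_solubility(1e-5, k11 = 100, k12 = 50, noise_cv = 0.02,
                          replicates = 3, seed = 1)
run_solubility_arc(d)$summary
```

## State thermodynamics

`free_energy_states()` ships binding free energies (relative to the unbound
pair, with repeat-based SDs) for the four celecoxib/HP-β-CD complexation
states — I and II (1:1 inclusion via different drug rings), III (1:2
inclusion) and IV (surface association, 333 K only) — at 298 and 333 K.
On top of any such table:

* `transition_dg()` forms $\Delta G_{A\to B} = \Delta G_{U\to B} -
  \Delta G_{U\to A}$ with SDs combined in quadrature (per-state estimates
  treated as independent — only per-state SDs are available).
* `boltzmann_ratio()` returns $C_{to}/C_{from} = e^{-\Delta G/RT}$, the
  relative probability of forming the two states from a common unbound
  start. The sign convention ($\Delta G = G_{to}-G_{from}$) makes
  "state I is favoured over IV ≈ 269:1 at 333 K" read directly as
  `boltzmann_ratio(transition_dg(tb, "IV", "I", 333)$dg_kcal_mol, 333)`.
* `arrhenius_rate_ratio()` gives $k(T_2)/k(T_1) =
  \exp(-(E_a/R)(1/T_2 - 1/T_1))$ under a temperature-independent
  frequency factor. The activation energy is deliberately a caller
  input: which barrier governs a given interconversion is a modelling
  decision the data alone do not determine.
* `rank_states()` orders states by decreasing free energy (ties broken
  alphabetically, with a message).

```{r}
tb <- free_energy_states()
boltzmann_ratio(transition_dg(tb, "IV", "I", 333)$dg_kcal_mol, 333)
rank_states(tb, 333)$state
```

## PMF reconstruction from pulling work

Constant-velocity steered pulling produces, per repeat, cumulative external
work $W(\lambda)$ along the restraint position. The Jarzynski equality
$e^{-\beta\Delta F} = \langle e^{-\beta W}\rangle$ turns a work ensemble
into a free-energy profile:

* **`jarzynski_pmf()`**: $F(\lambda) = -\beta^{-1}\ln N^{-1}\sum_i
  e^{-\beta W_i(\lambda)}$, evaluated via log-sum-exp — mandatory, since
  $\beta W$ beyond ~700 overflows naive exponentials.
* **`cumulant_pmf()`**: $F = \overline W - \tfrac{\beta}{2}s_W^2$
  (unbiased variance). Exact for Gaussian work and much less noisy than
  the exponential average at the tiny repeat counts (N = 3) typical of
  steered-MD studies.
* **`mean_work_pmf()`**: the dissipation-inflated upper profile; the
  Jarzynski profile can never exceed it (Jensen), which every fixture is
  tested against.

Profiles are anchored to 0 at the first grid point (the bound end), making
them invariant to a common work offset. **Uncertainties are leave-one-out
jackknife SDs over repeats** — both per grid point and for endpoint
differences (`pmf_delta()`, linear interpolation on the ≥200-point grids the
generator emits). Jackknife was chosen as the minimal-assumption estimator
that is defined at N = 3; the profile object carries its work matrix so
`pmf_delta()` can re-estimate leave-one-out profiles with the same
estimator. For a state reached by sequential pulls (a 1:2 complex whose
hosts are separated before the drug is extracted), endpoint differences add
and SDs combine in quadrature (`run_simulation_arc()`).

The generator `sim_pull_ensemble()` integrates overdamped Langevin dynamics
(Euler–Maruyama) of one coordinate in an analytic landscape (`pmf_flat()`,
`pmf_quadratic()`, `pmf_double_well()`) with a harmonic restraint moving at
constant velocity, accumulating $W = k_s\int(\lambda - x)v\,dt$ by the
trapezoidal rule. Euler–Maruyama suffices for a 1-D toy; the integrator
enforces the stability bound
$dt < \gamma/(10(k_s + \max U''))$ and reports the admissible bound when
violated. Defaults (1 Å/ns pulling, 3 repeats) mirror common steered-MD
practice; friction 0.3 kcal·ns/(mol·Å²) keeps mean dissipation
($\approx \gamma v L$) near 1–2 $k_BT$ over a 5 Å pull so that a
200-repeat Jarzynski average converges.

```{r}
w <- sim_pull_ensemble(pmf_quadratic(0.5), spring_k = 50, velocity = 1,
                       friction = 0.3, temperature = 300, duration = 5,
                       dt = 2e-4, n_repeats = 200, seed = 42)
pmf_delta(jarzynski_pmf(w), 0, 5) # true value: 6.25 kcal/mol
```

## Trajectory statistics and state calling

`centroid_distance_series()` computes per-frame Euclidean distances between
unweighted geometric centroids (the sources report "centroids" without mass
weighting, and the classification depends only on contrasts). Input
trajectories must be whole-molecule and unwrapped; no periodic-boundary
handling is attempted. `windowed_stats()` reports mean ± sample SD over a
time window with inclusive ends.

`classify_states()` maps distance bands to states: `inclusion` below
`t_inc` (5.8 Å), `association` below `t_assoc` (9.0 Å), else `unbound`;
frames whose *secondary* host distance falls below `t_cover` (7.5 Å) are
upgraded to `dual` — the 1:2 signature in which a second cyclodextrin
covers, without enclosing, the drug. Runs shorter than `min_dwell`
(0.05 ns) are merged into neighbours to suppress threshold flicker. These
defaults are engineering calibrations chosen once to separate typical
reported regimes (enclosed ≈3.6–5.3 Å versus covering ≈6.7 Å); they are
configurable and are not experimental findings.

## What the synthetic data do and do not emulate

`sim_phase_solubility()` reproduces the equilibrium isotherm with
multiplicative lognormal noise of configurable CV (default 0.02 — a
plausible chromatographic precision, chosen once as a stand-in since no
measured error magnitude is available). It does not emulate systematic
errors (drift, dilution bias) or cyclodextrin self-association.
`sim_pull_ensemble()` produces work ensembles with the correct
second-law/Jarzynski structure on a 1-D landscape; it is not molecular
dynamics — no solvent, orientational or multidimensional effects, so
passing tests demonstrate estimator correctness, not force-field realism.
`sim_state_trajectory()` emits piecewise-Gaussian distance regimes
(truncated at zero) without autocorrelation; dwell-time statistics of real
trajectories are not modelled.

## Numerical choices and degenerate inputs

* Log-sum-exp for all exponential averaging; bracketed `uniroot` on
  $[0, [CD]_{tot}]$ for the free-CD balance; analytic Jacobian for the
  LM fit, with covariance from the local quadratic approximation
  (`NA` when singular, e.g. exactly at the $K_{1:2}=0$ boundary).
* Zero-residual regressions (exact synthetic data) degenerate the
  curvature t-test; classification then falls back to relative curvature
  magnitude with threshold $10^{-8}$.
* Single-repeat ensembles: Jarzynski reduces to the work curve itself;
  jackknife SDs are undefined and reported `NA`; `pmf_delta()` and the
  simulation arc refuse to fabricate an uncertainty.
* Ties in state ranking are broken alphabetically, with a message.
* Generators are bit-reproducible under a fixed seed and leave the
  caller's RNG state untouched.

## Problem sizes used in the shipped checks

The test-suite and reproduction-script sizes were chosen as the smallest
that make each statistical claim sharp: 21-concentration isotherms with
100 noise realisations for constant recovery; 10⁴ Gaussian work samples
against the analytic $\mu - \beta\sigma^2/2$ limit; 200 Brownian pulls of
5 ns at dt = 2×10⁻⁴ ns for end-to-end PMF recovery (dissipation ≈ 2 kBT,
jackknife z-scores well inside ±3); 990-frame two-series trajectories for
state calling.

## Known limitations

* Only 1:1 and 1:2 stoichiometries; no drug₂·CD or higher species, and no
  temperature interpolation of constants (temperatures are fitted
  independently).
* The nonlinear estimator is an ordinary (weighted) least-squares fit; it
  stands in for older graphical/iterative procedures whose exact numerics
  are not reproduced.
* No stiff-spring deconvolution or umbrella-sampling reweighting beyond
  the three work estimators; strongly dissipative ensembles bias the
  Jarzynski estimate at small N (use `cumulant_pmf()` or more repeats).
* The Arrhenius helper computes the stated closed form only; it does not
  select a barrier for you, and rate ratios inherit the barrier choice.
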