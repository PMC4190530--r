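# cdinclusion

Analysis of host–guest inclusion complexation between poorly soluble drugs
and cyclodextrins, built around the celecoxib / hydroxypropyl-β-cyclodextrin
(HP-β-CD) system. The package connects the two standard characterisation
routes:

* **Phase-solubility analysis** (Higuchi–Connors): classify the diagram of
  total dissolved drug *S*<sub>tot</sub> versus total cyclodextrin [CD] as
  linear (A<sub>L</sub>, first-order complexation) or positively curved
  (A<sub>p</sub>, higher-order), estimate the effective stoichiometry *n*
  from the log–log slope of (*S*<sub>tot</sub> − *S*<sub>0</sub>) on [CD],
  and estimate stability constants from

  *S*<sub>tot</sub> = *S*<sub>0</sub>(1 + K<sub>1:1</sub>[CD] +
  K<sub>1:1</sub>K<sub>1:2</sub>[CD]²)

  by the A<sub>L</sub> slope formula K<sub>1:1</sub> = m/(S₀(1 − m)), the
  linearized A<sub>p</sub> regression of (*S*<sub>tot</sub> − *S*₀)/[CD] on
  [CD], and a box-constrained nonlinear least-squares fit, with an optional
  free-cyclodextrin mass-balance correction.

* **Pulling-based free-energy analysis**: reconstruct potentials of mean
  force from constant-velocity pulling work ensembles via the Jarzynski
  equality exp(−βΔF) = ⟨exp(−βW)⟩ (log-sum-exp evaluated), a second-order
  cumulant alternative, and mean work; jackknife uncertainties over
  repeats; Boltzmann occupancy ratios C_B/C_A = exp(−ΔG/RT) and Arrhenius
  rate ratios between complexation states; centroid-distance trajectory
  statistics and threshold-based complexation-state calling
  (inclusion / association / dual / unbound).

A synthetic-data module (`sim_phase_solubility()`, `sim_pull_ensemble()`,
`sim_state_trajectory()`) generates every input — equilibrium isotherms
with multiplicative lognormal noise, overdamped-Langevin pulling work on
analytic landscapes, piecewise-Gaussian distance regimes — so the entire
pipeline is testable end to end with no laboratory or simulation output.
It is aimed at formulation scientists and simulation practitioners who
need the estimators, their uncertainties and their failure modes in one
tested, scriptable place.

## Worked example

```r
library(cdinclusion)

# -- solubility arc: simulate a 1:1/1:2 system at 2% CV and analyse it
d <- sim_phase_solubility(1e-5, k11 = 100, k12 = 50, noise_cv = 0.02,
                          replicates = 3, seed = 1)
run_solubility_arc(d)$summary[, c("profile", "n_hat", "k11_ap_lin",
                                  "k12_ap_lin", "k11_ap_nl", "k12_ap_nl")]
#>   profile n_hat k11_ap_lin k12_ap_lin k11_ap_nl k12_ap_nl
#> 1 A_p      1.69       97.5       52.4      104.      48.8
```

The diagram is called A<sub>p</sub> (positively curved, so complexes of
order above 1:1 are present), the effective stoichiometry 1.69 lies between
1 and 2 as it must for a 1:1/1:2 mixture, and both estimators recover the
generating constants (100, 50 L/mol) within a few percent at this noise
level.

```r
# -- state thermodynamics: how strongly is inclusion I favoured over
#    surface association IV at 333 K?
tb <- free_energy_states()
boltzmann_ratio(transition_dg(tb, "IV", "I", 333)$dg_kcal_mol, 333)
#> [1] 268.6513

# -- PMF reconstruction: 200 Brownian pulls across a quadratic well of
#    depth 6.25 kcal/mol, Jarzynski estimator, jackknife uncertainty
w <- sim_pull_ensemble(pmf_quadratic(0.5), spring_k = 50, velocity = 1,
                       friction = 0.3, temperature = 300, duration = 5,
                       dt = 2e-4, n_repeats = 200, seed = 42)
pmf_delta(jarzynski_pmf(w), 0, 5)
#>   lambda_a lambda_b dg_kcal_mol sd_kcal_mol
#> 1        0        5        6.27       0.165
```

The ≈269:1 ratio says surface association is a negligible end state at
333 K; the reconstructed 6.27 ± 0.17 kcal/mol endpoint difference brackets
the true 6.25 despite mean dissipation of ≈1.3 kcal/mol in the pulls.

`tidy()`/`glance()` methods expose all fits in broom form;
`plot_phase_solubility()` and `autoplot()` methods for PMF profiles and
distance series provide quick diagnostics.

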