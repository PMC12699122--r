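---
title: "Kinetic models and calibration methods for enzymatic amoxicillin synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models and calibration methods for enzymatic amoxicillin synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amoxkin)
```

## The reaction network and its two models

Penicillin G acylase couples the activated acyl donor
(*p*-hydroxyphenylglycine methyl ester, `AB`) to 6-aminopenicillanic acid
(`NH`) to give amoxicillin (`AN`). The same acyl-enzyme intermediate is
also attacked by water, and amoxicillin itself is re-hydrolyzed, so
*p*-hydroxyphenylglycine (`AOH`) accumulates along two parallel routes and
the product concentration peaks transiently. Any useful reactor model must
capture this partitioning.

`amoxkin` implements two rate laws over the state
`Y = (C_AB, C_AN, C_NH, C_AOH)` in mM:

* **Model 1** is semi-empirical: Michaelis–Menten consumption of the ester
  with competitive inhibition by amoxicillin and by-product; a fraction
  `Tmax * C_NH / (KEN + C_NH)` of consumed ester is routed to synthesis
  (6-APA adsorption on the acyl-enzyme complex); and Michaelis–Menten
  hydrolysis of amoxicillin with competitive inhibition by ester, 6-APA
  and by-product. Ten parameters (`params_model1()`).
* **Model 2** is mechanism-based: rates are assembled from elementary
  constants of the acyl-enzyme cycle — formation (`k2`), ester hydrolysis
  (`k3`), synthesis (`k4`) and its reverse (`k−4`), by-product formation
  through the product route (`k5`) — together with the nucleophile
  association constant `KN` and the substrate/product equilibrium
  constants `KS`, `KP`. Eight parameters (`params_model2()`). The net
  amoxicillin rate can be negative, but only when product is present.

Both right-hand sides conserve the ester moiety `C_AB + C_AN + C_AOH` and
the nucleus `C_AN + C_NH` *identically* — the test suite asserts this on
the rate functions to machine precision, independently of the integrator.
Semi-batch operation adds piecewise-constant volumetric feed rates
`F_AB(t)`, `F_NH(t)` to the ester and nucleus equations, so the moiety
sums grow exactly by the integrated feed. Solid substrate addition is
modeled as an equivalent molar feed at constant working volume
(instantaneous dissolution); volume dynamics, enzyme deactivation and
pH/temperature effects are out of scope.

### Enzyme-load units

Model 1 expresses catalytic constants per international unit of
immobilized enzyme activity, so its load `C_EZ` is in i.u./mL and
`Kcat · C_EZ` has units mM/min. Model 2 uses first-order constants
(min⁻¹) and a molar enzyme concentration (mM). `reactor_conditions()`
carries an explicit unit tag and `simulate_reactor()` refuses a
model/unit mismatch — mixing the two conventions silently would rescale
every estimated constant.

## Numerical integration

`simulate_reactor()` integrates with `deSolve::lsoda` (stiff-capable,
`rtol = 1e-8`, `atol = 1e-10` by default); the right-hand sides are
compiled C for speed, with the exported R rate functions as a
cross-checked reference path (`compiled = FALSE`). States are clipped at
zero inside the RHS so integrator overshoot cannot generate spurious
negative rates. Feed discontinuities are never stepped across: the
integration restarts at every feed breakpoint. Interpolation between
stored nodes is monotone cubic (Fritsch–Carlson), exact at the nodes.

The solver is validated against an independent fixed-step RK4 oracle
(agreement < 0.01 mM on the low-concentration scenario), a 10× tolerance
refinement (endpoint shift < 1e-4 mM), conservation-law drift
(< 1e-6 relative), and closed-form limits (frozen system at zero enzyme
load, linear accumulation under pure feeding, complete double hydrolysis
as t → ∞).

## The synthetic study conditions

No reactor dataset is deposited, so `generate_dataset()` stands in for the
experiments and defines the conditions every estimator is tested under:

* **Charges**: `scenario("LC")` = 80 mM ester + 60 mM 6-APA;
  `scenario("HC")` = 120 mM ester + 30 mM 6-APA; product and by-product
  start at exactly zero (fresh charge); horizon 240 min.
* **Sampling**: 13 equispaced points on [0, 240] min, emulating the
  sampling density of typical batch runs.
* **Noise**: additive i.i.d. Gaussian per species and time point, default
  sd 1.0 mM. The error sd used in the original likelihood is not
  published; 1.0 mM is a package default chosen as a realistic HPLC-scale
  error for concentrations of tens of mM, and it is configurable
  everywhere. Noisy values are *not* truncated at zero — truncation would
  bias the Gaussian likelihood the estimators assume.
* **Enzyme loads**: model 1 defaults to 2.5 i.u./mL, which converts about
  two thirds of the ester over the horizon. For model 2 the package
  default is 0.05 mM: with the reference rate constants a load of order
  1 mM exhausts the ester within minutes, leaving a 13-point grid with
  almost no kinetic information, whereas 0.05 mM yields ~87% conversion
  with a transient spanning most of the horizon — the same design goal
  (more than half the ester converted, informative data) at a load that
  actually exercises the dynamics.

What the generator does *not* emulate: heteroscedastic or multiplicative
measurement error, sampling-time optimization, enzyme deactivation,
crystallization at high concentrations. Passing recovery tests therefore
demonstrate estimator correctness under a well-specified model, not
robustness to the model misfit real reactors exhibit.

## Metropolis–Hastings sampler

The posterior is `prior × likelihood` with a fixed error sd (no
hyperparameters). Choices that were genuinely open:

* **Prior**: the published description fixes a Gaussian prior with "a
  deviation of 0.6". Across the reference tables the parameters span
  0.06–815, so an *absolute* sd of 0.6 would be meaningless for most of
  them; the package uses a relative sd, `sd_j = 0.6 · P0_j`, truncated to
  positive values. The truncation is handled in the prior (candidates with
  a non-positive component get log-prior −∞), which keeps the proposal
  symmetric.
* **Proposal**: a Gaussian random walk with per-component scale
  `w · P0_j`, anchored to the initial estimate rather than the current
  state so the proposal stays symmetric and the Metropolis ratio exact.
  Whether the original used a uniform or Gaussian perturbation is not
  recoverable from its description; the Gaussian walk is adopted and
  documented.
* **Step size**: the published relative step `w = 6e-3` is the package
  default. At desk-scale iteration counts such a small step leaves the
  chain mean dominated by Monte-Carlo error (the integrated
  autocorrelation time scales as `(posterior sd / step)²`), so the
  recovery studies in the tests and acceptance script use `w = 0.02`
  (model 1, 10 free parameters, ≈25% acceptance) and `w = 0.05` (model 2,
  3 free parameters, ≈55% acceptance) with 1e5 / 5e4 iterations — mixing-
  efficient settings for the same target distribution.
* **Burn-in**: default 20% of the chain; the prior-recovery test checks
  that summaries are insensitive to this choice.
* **Failed integrations** are absorbed into a log-likelihood of −∞, i.e.
  rejected, rather than raised.
* A subset of parameters can be held fixed (`estimate =` in
  `mcmc_config()`); the high-concentration model 2 study estimates
  `k3, k4, KP` with the five unpublished constants fixed at the package's
  nominal values (`ref_params_model2()`).

Sampler validity is established *without* the ODE: under a flat likelihood
(empty dataset) the chain must reproduce the truncated prior's mean and sd
(closed forms), and the credible bounds must match Gaussian quantiles on
i.i.d. draws.

## Genetic algorithm

Real-coded, generational, with the classical operator suite: roulette
selection, scattered (binary-mask) crossover applied to 90% of parent
pairs, per-gene uniform-resampling mutation at rate 0.10, and elitism
(default 2), which guarantees a monotone best-so-far fitness. Design
choices:

* The objective is a *deviation* (sum over species of fractional rRMSE),
  so roulette weights are the minimization transform
  `(f_worst − f) + 1e-12`; infeasible individuals (failed integration,
  fitness +∞) receive only the tie-breaking `1e-12`.
* Search bounds default to one decade around the literature initial
  estimates. For model 1, `fit_ga()` additionally caps the `Tmax` upper
  bound at 1: `Tmax` is a conversion *fraction*, and what the data
  constrain is the lumped factor `Tmax·C_NH/(KEN + C_NH)`, so without the
  cap the optimizer drifts along a (`Tmax`, `KEN`) ridge to physically
  meaningless `Tmax` values at equal fitness.
* With uniform-resampling mutation, gene values can only come from the
  initial population or fresh uniform draws, which bounds the terminal
  precision: on a separable quadratic over one decade, 200 generations of
  100 individuals reliably reach an objective value within 1% of the
  optimum (unit scale), corresponding to per-parameter errors of a few
  percent. The test suite asserts exactly that, rather than a per-gene
  precision the operator set cannot deliver.

## Model selection and the interaction grid

`rrmse()` implements the RMSE normalized by the mean of the measured
sequence, in percent; it is scale-invariant and zero only for identical
sequences. `interaction_grid()` runs the eight fits of the study design
(2 models × 2 estimators × 2 charges), scores each per species, and
`grid_winner()` selects the minimum rRMSE sum per charge. The
self-consistency property — data generated from model 1 are won by
model 1 fits — holds in at least 4 of 5 seeded replicates at desk scale.
Formal Bayesian model comparison (Bayes factors, information criteria) is
deliberately out of scope; selection is by rRMSE only.

## Batch-to-semi-batch transfer

`predict_semibatch()` forward-simulates the fed-batch reactor with
batch-calibrated parameters, with no re-fitting. The default validation
scenario feeds both substrates at 0.2 mM/min for 120 min on a 400-min
horizon at the low-concentration enzyme load — a package choice, since the
original feed schedule is not fully specified. `predictive_band()`
propagates a thinned posterior subsample (default 500 draws) through the
simulator and returns pointwise quantile envelopes;
on well-specified synthetic data the 99% band covers ≥95% of noiseless
truth points across seeds. `to_mass_units()` converts to g/L with the
species molar masses (181.19, 365.40, 216.26, 167.16 g/mol for ester,
amoxicillin, 6-APA and by-product).

## Problem sizes used in the tests

The shipped suite runs every study at sizes chosen to keep the full check
under a few minutes while leaving each conclusion statistically clear:
recovery studies use 13-point datasets with 1e5 (model 1) or 5e4
(model 2) MCMC iterations and 300 GA generations of 100 individuals;
property loops use 10–25 random cases under fixed seeds; grid and
coverage studies use shortened chains (1200–3000 iterations) and reduced
populations, which is sufficient because their assertions compare methods
rather than report absolute accuracy.

## Known limitations

* `KM1`, `KM2` and several inhibition constants are only weakly identified
  by a single 13-point batch trajectory: they enter near-saturated or
  ridge-coupled terms, so their posteriors remain prior-dominated and
  posterior means vary noticeably across data realizations. The recovery
  studies document this rather than hide it — point estimates for the
  well-identified constants (`Kcat1`, `k4`) recover tightly, the weakly
  identified ones recover to within their published uncertainty.
* The mechanism-based model's published description leaves five of its
  eight constants unreported; the package's nominal values are documented
  in `ref_params_model2()` and all conclusions involving model 2 are
  conditional on them.
* The genetic algorithm uses exactly the published operator suite; it is
  a capable global searcher but a poor terminal refiner. Hybridizing with
  a local search would change the algorithm under study and is not done.
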