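# amoxkin

Kinetic modeling and calibration of the enzymatic synthesis of amoxicillin
by immobilized penicillin G acylase (PGA, EC 3.5.1.11), for bioprocess
engineers and modelers working on kinetically controlled β-lactam
synthesis in batch and fed-batch reactors.

## The problem

Under kinetic control, PGA transfers the acyl group of
*p*-hydroxyphenylglycine methyl ester (the activated donor, `AB`) to
6-aminopenicillanic acid (the nucleus, `NH`) to form amoxicillin (`AN`) —
while two parallel hydrolyses, of the ester and of amoxicillin itself,
drain the yield into *p*-hydroxyphenylglycine (`AOH`). The product
concentration therefore peaks transiently, and reactor design hinges on a
kinetic model calibrated against concentration time series.

The package implements two competing ODE models of the network
(states `Y = [C_AB, C_AN, C_NH, C_AOH]`, mM):

**Model 1** (semi-empirical, Michaelis–Menten with competitive inhibition):

```
v_AB = Kcat1·C_AB·C_EZ / (KM1·(1 + C_AN/kAN + C_AOH/kAOH) + C_AB)
v_S  = v_AB · Tmax·C_NH / (KEN + C_NH)
v_AN = Kcat2·C_AN·C_EZ / (KM2·(1 + C_AB/kAB + C_NH/kNH + C_AOH/kAOH) + C_AN)

dC_AB/dt = −v_AB            dC_AN/dt = v_S − v_AN
dC_NH/dt = v_AN − v_S       dC_AOH/dt = v_AB − v_S + v_AN
```

**Model 2** (mechanism-based, acyl-enzyme cycle with rate and equilibrium
constants `k2, k3, k4, k−4, k5, KN, KS, KP`): with
`D = k3·KN + (k4 + k5)·C_NH`,

```
R_P = C_EZ·[k2·k4·C_AB·C_NH/KS − k−4·C_AN·(k3·KN + k5·C_NH)/KP] / D
R_B = C_EZ·(k3·KN + k5·C_NH)·[k2·C_AB/KS − k−4·C_AN/KP] / D
dC_AB/dt = −(R_P + R_B),  dC_AN/dt = R_P,  dC_NH/dt = −R_P,  dC_AOH/dt = R_B
```

Both conserve the ester moiety (`C_AB + C_AN + C_AOH`) and the nucleus
(`C_AN + C_NH`) exactly; semi-batch operation adds feed rates `F_AB(t)`,
`F_NH(t)` to the ester and nucleus equations.

Calibration is by two estimators applied to noisy concentration data:

* **Metropolis–Hastings MCMC** — Gaussian i.i.d. likelihood with fixed
  error sd, independent Gaussian priors centered at an initial estimate
  with relative sd 0.6 (truncated positive), symmetric Gaussian random
  walk; posterior means and 99% credible intervals from the retained
  chain.
* **Real-coded genetic algorithm** — roulette selection (minimization
  transform), scattered crossover (rate 0.90), uniform-resampling mutation
  (rate 0.10), elitism; objective = sum over the four species of the
  relative RMSE.

Model x method x condition combinations are compared by
`rRMSE = 100·sqrt(Σ(Ym − Ye)²/nt)/Ȳm` per species, and batch-calibrated
parameters are transferred unchanged to semi-batch prediction with
posterior predictive bands.

Since no reactor dataset is deposited, a first-class synthetic-data module
reproduces the study conditions: batch charges of 80 mM ester + 60 mM
6-APA ("LC") or 120 mM ester + 30 mM 6-APA ("HC"), 13 samples over
240 min, additive Gaussian noise (default sd 1.0 mM).

## Worked example

Generate a noisy LC batch dataset from the published low-concentration
posterior means, re-estimate model 1 by MCMC, and score the fit:

```r
library(amoxkin)
p    <- ref_params_model1("lc_mcmc")
cond <- scenario("LC")
ds   <- generate_dataset("model1", p, cond, n_points = 13, noise_sd = 1, seed = 7)
cfg  <- mcmc_config(P0 = p, N = 2e4, w = 0.02, seed = 7)
fit  <- posterior_summary(run_mcmc("model1", ds, cond, cfg))
fit
#> Parameter fit (model1, MCMC)
#>         estimate      lower      upper
#> Kcat1  0.2131479  0.1806440  0.2431944
#> Kcat2  0.5005647  0.2773573  0.7117351
#> KM1    6.9553739  4.1536053  9.9916610
#> KM2    2.2123843  0.7598725  3.7917381
#> Tmax   0.8333289  0.7132127  0.9471189
#> ...
#> acceptance rate: 0.255
round(evaluate_fit(ds, "model1", fit$estimates, cond)$per_variable, 2)
#>  C_AB  C_AN  C_NH C_AOH
#>  2.36  7.09  1.44  4.98
```

The posterior means sit near the generating values (`Kcat1` 0.213 vs
0.181; catalytic constants in µmol/(i.u.·min), Michaelis and inhibition
constants in mM), the 99% credible intervals bracket them, and the
per-variable rRMSE values (in percent) sit on the noise floor implied by
the 1 mM measurement error — a few percent of each species' mean level.

A config-driven command-line surface is installed at `exec/amoxkin`
(subcommands `simulate`, `generate`, `fit-mcmc`, `fit-ga`, `grid`,
`validate`, `convert-units`), each a thin wrapper over the functions
above.

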