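# ifnwave

Population-level dynamics of the type I interferon (IFN-I) response in
TLR-stimulated human immune cells, for systems immunologists who want to
fit, simulate and stress-test the *first responder / second responder*
model of IFN-alpha production.

## The model

Only a small, fixed fraction of cells (*first responders*, `fr` = 1% of the
population) produces IFN-alpha directly upon TLR stimulation. Their
secreted IFN-alpha accumulates in the supernatant and, once it crosses an
activation threshold, recruits a much larger pool of *second responders*
(up to `sr` = 50% of the population) through paracrine IFNAR signaling;
the remaining cells never respond. The package implements the
three-state ODE system

```
df1/dt    = kon (fr − f1) − koff f1
df2/dt    = kon · [IFN]^H / (T^H + [IFN]^H) · (sr − f2) − koff f2
d[IFN]/dt = kf (f1 + f2) − df [IFN]
```

with `f1`, `f2` the activated first-/second-responder fractions,
`[IFN]` the supernatant IFN-alpha concentration (pg/mL), `kon`/`koff`
activation and turn-off rates (per hour), `kf` the secretion rate
(pg/mL/h), `df` the first-order consumption/degradation rate (per hour),
`T` the paracrine activation threshold (pg/mL) and `H` the Hill
coefficient of the IFN-IFNAR activation gate. The measured observables
are the percent of IFN-alpha-positive cells, `100·(f1+f2)`, and `[IFN]`.

Around the model the package provides:

* **Joint multi-condition least-squares fitting** (`ifn_fit()`): each
  parameter is declared fixed, shared across conditions (optionally in
  share groups) or condition-specific; both observables are fitted
  together with max-normalized weights; concentrations left-censored at
  the ELISA limit of quantification (12.5 pg/mL for IFN-alpha) incur a
  one-sided penalty; optimization is bounded Levenberg–Marquardt in
  log-space from seeded log-uniform multistarts.
* **Parsimony comparison** of nested constraint families
  (`parsimony_compare()`, `run_dose_response()`) and objective profiling
  for identifiability (`profile_parameter()`).
* **A synthetic-data generator** (`generate_dataset()`) emulating the
  experimental readouts: binomial counting noise over 25,000 cells per
  well for percent-positive, multiplicative lognormal noise (5% CV) with
  LOQ censoring for ELISA concentrations, replicate averaging with SEMs.
* **Recovery studies** (`recovery_study()`) measuring how well free
  parameters are re-identified from noisy synthetic data.

The four bundled parameter regimes (`ifn_regimes()`) describe CpG-C
stimulation at 0.5, 5 and 50 µg/mL and R848: rising CpG-C dose lowers
the threshold `T` (440 → 230 → 20 pg/mL) and speeds turn-off `koff`
(0.2 → 0.33 → 2 h⁻¹), with a reduced secretion rate (`kf` = 2000 instead
of 6600 pg/mL/h) at the highest dose; R848 acts through much faster
activation (`kon` = 1.5 vs 0.4 h⁻¹).

## Worked example

Simulate the low-dose CpG-C regime, generate one noisy synthetic dataset
at it, and re-fit the threshold and turn-off rate:

```r
library(ifnwave)

params <- ifn_regimes()$cpg_0.5
traj <- simulate_ifn(params)            # hourly, 0-26 h
round(traj[traj$time_h %in% c(0, 6, 12, 18, 26), ], 3)
#>    time_h    f1    f2 ifn_pg_ml percent_positive
#> 1       0 0.000 0.000     0.000            0.000
#> 7       6 0.006 0.006   200.935            1.199
#> 13     12 0.007 0.312  6737.771           31.821
#> 19     18 0.007 0.333 17075.296           33.940
#> 27     26 0.007 0.333 27757.209           34.000

ds <- generate_dataset(ifn_regimes()["cpg_0.5"], seed = 7)
fit <- ifn_fit(ds$observations, roles = list(T = "free", koff = "free"),
               fixed = lapply(ds$truth, unclass))
fit
#> Responder-model fit over 1 condition(s): cpg_0.5
#> Weighted least-squares objective: 0.0067585
#> Estimated entries:
#> koff|c:cpg_0.5    T|c:cpg_0.5
#>        0.20029      438.34000
```

The trajectory shows the two-wave structure: for the first ~6 h only the
1% first-responder pool is active (`f1` ≈ 0.006, ~1.2% positive); once
the supernatant concentration crosses `T` = 440 pg/mL the second
responders switch on and the positive fraction rises to its plateau of
34% (= 100·(f1* + f2*), with steady state `f1*` = 1/150, `f2*` ≈ 1/3).
Refitting the noisy dataset recovers the generating threshold
(438.3 vs 440 pg/mL) and turn-off rate (0.2003 vs 0.2 h⁻¹).

`plot(fit)` overlays fitted curves on the observations;
`profile_parameter(fit, "T", grid)` maps the objective around the
optimum; `run_dose_response()` chains generation, a nested family of
joint fits and the parsimony ranking into one reproducible scenario.

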