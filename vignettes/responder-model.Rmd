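---
title: "Modelling first- and second-responder IFN-I dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling first- and second-responder IFN-I dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the fitting machinery, the synthetic
data generator and the numerical and design choices behind them — the
things a maintainer or a careful user should know before trusting a fit.

## The model and its assumptions

The package describes the population-level IFN-alpha response of
TLR-stimulated immune cells with three ordinary differential equations:

$$\frac{df_1}{dt} = k_{on}(f_r - f_1) - k_{off} f_1$$
$$\frac{df_2}{dt} = k_{on}\frac{[IFN]^H}{T^H + [IFN]^H}(s_r - f_2) - k_{off} f_2$$
$$\frac{d[IFN]}{dt} = k_f (f_1 + f_2) - d_f [IFN]$$

* $f_1$ — activated *first responders*: a small, fixed fraction
  ($f_r = 0.01$ of the population) that needs only the TLR stimulus.
* $f_2$ — activated *second responders*: a larger pool (at most
  $s_r = 0.5$) that additionally needs paracrine IFN-I signaling,
  gated by a Hill function of the supernatant concentration with
  threshold $T$ (pg/mL) and coefficient $H$.
* $[IFN]$ — bulk supernatant IFN-alpha (pg/mL), fed by every activated
  cell at rate $k_f$ and cleared first-order at rate $d_f$.

Key structural assumptions:

* **Stimulus is implicit.** There is no stimulus state variable; the
  activation rate $k_{on}$ encodes stimulus identity and potency
  (it differs between R848 and CpG-C), and dose acts through the fitted
  condition-specific parameters ($T$, $k_{off}$, and $k_f$ at the
  highest CpG-C dose), not through an explicit dose variable.
* **Well-mixed bulk.** $[IFN]$ is a single concentration seen equally
  by every cell — appropriate for microwell supernatants, not for
  droplet-encapsulated single cells.
* **Identical turn-off.** First and second responders share
  $k_{off}$; activation is the only asymmetry.
* **Measured ELISA concentrations and the model's $[IFN]$ are taken to
  be on the same scale** (no calibration factor), which is what makes
  fitting $T$ in pg/mL meaningful. This is an identification choice:
  any common scale error in the assay would be absorbed into $k_f$ and
  $T$ jointly.
* The model contains no TNF-alpha compartment, no intracellular
  signaling (IFNAR/JAK/STAT), and no donor heterogeneity.

The observables are `percent_positive` $= 100(f_1+f_2)$, matching
percent-IFN-alpha-positive flow readouts, and $[IFN]$ itself, matching
supernatant ELISA.

Two consequences of the vector field are used as invariants everywhere:
$0 \le f_1 \le f_r$, $0 \le f_2 \le s_r$, $[IFN] \ge 0$ are forward
invariant from the rest state (at $f_1 = f_r$ the derivative is
$-k_{off} f_r < 0$, and similarly at the other boundaries), and with
$k_f = 0$ the first equation decouples with the closed form
$f_1(t) = \frac{k_{on} f_r}{k_{on}+k_{off}}(1 - e^{-(k_{on}+k_{off})t})$.
Both are asserted in the test suite; the closed form and an independent
fixed-step RK4 integration serve as numerical oracles for the adaptive
solver.

## Initial condition, time base, integration

* **Initial condition** is the rest state $(0, 0, 0)$ at stimulus
  addition: cells start inactive and no IFN-alpha is present. The
  experimental protocol (stimulate, then sample) makes this the only
  biologically sensible choice, and it makes the "first wave" of the
  narrative literal.
* **Time base** is hours, with a default hourly reporting grid over the
  26 h observation window. Internally the solver is adaptive; reported
  states are its dense output at the grid times.
* **Integrator**: Dormand–Prince 4(5) (`deSolve::ode`, method
  `"ode45"`) with `rtol = 1e-8`, `atol = 1e-10` and a compiled
  right-hand side. The system is non-stiff at all bundled regimes
  (fastest rate $k_{off} = 2\,h^{-1}$), so an explicit adaptive RK pair
  is appropriate; within the fitting bounds rates up to $100\,h^{-1}$
  remain tractable. Integration failure raises an error — it is never
  silently converted to `NA` or a penalty inside `simulate_ifn()`
  (inside a fit, a failed evaluation marks that start as failed).
* Solver rounding can leave states a few ulps outside their invariant
  box; `simulate_ifn()` clips within a $10^{-7}$ relative band onto
  the box and errors beyond it, so downstream code may rely on the
  bounds holding exactly.
* `hill_activation()` returns exactly 0 at zero concentration (avoiding
  $0^H/0^H$ pitfalls for non-integer $H$) and the correctly rounded
  limit 1 when $(ifn/T)^H$ overflows. $H$ is any real $\ge 1$; fits may
  explore non-integer values.
* `steady_state()` reduces the fixed point to scalar root finding on
  $[IFN]^*$ in the bracket $[k_f f_1^*/d_f,\; k_f(f_1^*+s_r)/d_f]$,
  whose endpoints bound the secretion balance below and above; both
  fixed-point residuals are verified to $10^{-10}$ relative before the
  result is returned.

## The fitting procedure

`ifn_fit()` minimizes the joint weighted sum of squared residuals over
all conditions and both observables.

* **Roles.** Every parameter is `"fixed"` (held at a supplied value),
  `"shared"` (one value across conditions), `"free"`
  (condition-specific), or assigned to a named share group — e.g. one
  $k_f$ for the lower CpG-C doses and R848 and another for 50 µg/mL.
  `fr` and `sr` default to fixed 0.01 and 0.5.
* **Weighting.** The experiment gives percentages (order 1–40) and
  concentrations (order $10^4$–$10^5$ pg/mL). By default each
  observable's residuals are divided by the maximum observed value of
  that observable across all fitted conditions, so both contribute
  comparably; `weighting = "none"` gives raw units. The scheme is
  recorded in the fit object. This is a declared design choice — a
  plain least-squares criterion does not dictate one.
* **Censoring.** Concentrations below the ELISA limit of
  quantification (IFN-alpha LOQ 12.5 pg/mL) are reported at the LOQ
  with a flag. In the objective such points contribute nothing while
  the model is also below the LOQ and a one-sided penalty
  $(model - LOQ)^2$ (scaled) above it — the standard treatment of
  left-censored concentrations in a least-squares setting, without
  introducing a likelihood.
* **Optimizer.** Parameters are positive and span decades, so they are
  optimized in log-space, within bounds
  $k_{on}, k_{off} \in [10^{-3}, 10^2]\,h^{-1}$,
  $T \in [10^{-1}, 10^5]$ pg/mL, $H \in [1, 8]$,
  $k_f \in [1, 10^6]$ pg/mL/h, $d_f \in [10^{-4}, 10]\,h^{-1}$ —
  generous log-scale envelopes around the plausible ranges. Each of 16
  (default) start points is drawn log-uniformly within bounds from a
  seeded RNG and refined with bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`, `maxiter` 100, `ftol`/`ptol` $10^{-12}$); the
  best refined objective wins, ties broken by lowest start index, so a
  seed fixes the result bit-exactly. Callers may append explicit extra
  starts; `run_dose_response()` uses this to warm-start each nested
  family member from the previous member's solution, which guarantees
  a more permissive structure never ranks worse merely for want of a
  good start.
* **Guard rails.** A fit with more estimated entries than uncensored
  data points is refused; a fit with nothing free degenerates to an
  objective evaluation.

`profile_parameter()` re-optimizes all remaining free parameters at
each grid value of one parameter — the usual profile-objective
identifiability diagnostic. `parsimony_compare()` ranks a nested family
(validated by set inclusion of the freed parameter names) by objective
versus number of condition-specific parameters and selects the smallest
member within a factor (default 1.05) of the fully-free member's
objective.

## The synthetic-data generator

`generate_dataset()` produces observation tables with the statistical
structure of the experimental readouts, so the whole pipeline is
testable without any external data:

* **Flow percent-positive**: $k \sim \mathrm{Binomial}(n, p)$ positive
  events among $n = 25{,}000$ acquired cells per well, reported as
  $100k/n$. Counting error is the irreducible noise floor; gating,
  spillover and compensation artifacts are *not* modeled.
* **ELISA concentration**: multiplicative lognormal noise with unit
  median and 5% CV by default — concentration immunoassays have
  roughly constant CV.
* **Replicates**: 3 by default (the smallest replicate count in the
  emulated experiments); per-point SEMs across replicates are
  attached. The replicate mean is compared against the LOQ and, if
  below, reported at the LOQ with the censoring flag — one flag per
  reported point, as in standard ELISA tables.
* **Determinism**: one seed fixes the whole dataset bit-exactly, and
  the caller's RNG state is restored afterwards.

What passing recovery tests on these data do **not** show: robustness
to donor-to-donor parameter heterogeneity (the experimental error bars
are SEMs across donors, not wells), to assay drift between plates, or
to model misspecification — the generator draws from the fitted model
itself. Recovery results are statements about identifiability under
honest measurement noise, not about biological validity.

## Study conditions and problem sizes

The recovery studies and the acceptance script use the design of the
emulated experiment throughout: hourly sampling over 0–26 h, 3
replicates, 25,000 cells/well, 5% ELISA CV, LOQ 12.5 pg/mL; 20
independent seeds per study and 16 multistarts per fit. Single-regime
studies free the dose-specific parameters ($T$, $k_{off}$, plus $k_f$
at 50 µg/mL CpG-C and $k_{on}$ for R848); the joint study fits the two
lower CpG-C doses with $k_{on}, H, k_f, d_f$ shared and $T, k_{off}$
per dose — the same constraint structure that generated the data. The
parsimony study generates data in which only $T$ and $k_{off}$ differ
between doses and checks that the nested comparison picks exactly that
structure. These sizes keep a full run in the minutes range on one CPU
while leaving the median-over-seeds estimates stable.

## Known limitations

* The Hill-gated ODE is a mean-field description; it cannot represent
  the single-cell stochasticity the droplet experiments reveal, only
  its population-level consequence.
* $k_{on}$/$k_{off}$ can trade off when both are free with a steep
  activation gate (the rise of $f_1$ constrains their sum more tightly
  than each separately); profiles are the tool of choice there, and
  recovery tolerances for these two parameters are accordingly looser.
* The one-sided censoring penalty makes the objective only piecewise
  smooth at the LOQ boundary; Levenberg–Marquardt copes in practice,
  but a censored-likelihood treatment would be the principled upgrade.
* Fold-change utilities (`fold_change()`,
  `randomized_pairing_fold_change()` — pairing is without replacement
  when replicate counts match, with replacement otherwise;
  `replicate_spread()` is the sample SD with $n-1$) operate on
  replicate tables and are deliberately model-free.
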