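---
title: "Kinetic and Arrhenius shelf-life modelling with shelfkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic and Arrhenius shelf-life modelling with shelfkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfkin)
```

## The modelling problem

Perishable ready-to-eat foods spoil through coupled microbial, chemical and
physical processes. Rather than storing product at the retail temperature and
waiting months for it to fail, accelerated shelf-life testing stores samples at
several elevated temperatures, models how each spoilage indicator moves, and
extrapolates to any temperature of interest. shelfkin implements the classical
two-stage version of this workflow for indicator panels such as total volatile
base nitrogen (TVB-N, mg/100 g), total viable count (TVC, log10 CFU/g), acid
value (AV, mg KOH/g) and instrumental texture (springiness, hardness).

**Stage 1 — reaction-order kinetics at each temperature.** The indicator value
$A(t)$ at constant storage temperature is assumed to follow one of three
integrated rate laws:

* zero order: $A = A_0 + kt$,
* first order: $\ln A = \ln A_0 + kt$,
* second order: $1/A = 1/A_0 + kt$,

each of which is a straight line in $t$ after the corresponding transform.
`fit_kinetic()` estimates $k$ (the slope, per day) by ordinary least squares
with a free intercept; `fit_all_orders()` repeats this at every temperature,
and `select_order()` picks the order with the largest $\sum_T R^2$ across
temperatures (ties: smaller summed RMSE, then lower order). Model comparison by
summed $R^2$ — rather than AIC/BIC — is deliberate: it is the convention of
this literature and keeps every reported statistic directly comparable with
published fit tables.

**Stage 2 — Arrhenius temperature dependence.** The fitted rate constants obey
$k(T) = K_0 \exp(-E_a/(RT))$, i.e. $\ln|k|$ is linear in $1/T$ (Kelvin).
`fit_arrhenius()` regresses $\ln|k|$ on $1/T$; the activation energy is
$E_a = -\mathrm{slope} \cdot R/1000$ kJ/mol and the pre-exponential factor
$K_0 = \exp(\mathrm{intercept})$. Decaying indicators (texture) have negative
$k$; their absolute values enter the regression and the sign is stored and
restored on prediction (`rate_at()`).

**Shelf life.** With a critical limit $A_c$ (e.g. 35 mg/100 g for TVB-N,
6 log CFU/g for TVC, 5.0 mg KOH/g for AV), the storage time to reach it is

$$\mathrm{SL}(T) = \frac{A_c - A_0}{k(T)} \quad\text{(order 0)},\qquad
  \mathrm{SL}(T) = \frac{\ln A_c - \ln A_0}{k(T)} \quad\text{(order 1)}.$$

Only orders 0 and 1 admit this closed form; order 2 is fit-only.
`shelf_life_time()` guarantees inverse consistency —
`predict_value(model, SL, T)` returns the limit to $10^{-9}$ relative — and
`overall_shelf_life()` takes the minimum over an indicator panel.

## Conventions and units

* **Time** is internally always in days; the CSV reader converts hours by exact
  division by 24 (mixed designs — days at 4 °C, hours at 25/37 °C — are
  common). All rate constants are per day.
* **Temperature** is Kelvin internally with the standard offset
  $T(K) = T(°C) + 273.15$; every user-facing argument takes °C.
* **Gas constant** $R = 8.3144$ J K⁻¹ mol⁻¹, the rounding conventional in
  food-kinetics tables (not full CODATA precision), so derived $E_a$ values
  track published tables digit for digit.
* **TVC** is modelled directly on the log10 CFU/g scale (so "first order on
  TVC" means exponential growth of the log count). Published validation tables
  for products of this kind are only reproducible under this convention.
* **$R^2$ vs RMSE spaces.** $R^2$ is reported in the transformed (linear)
  space where the regression is performed; RMSE is reported in original
  indicator units after back-transforming fitted values. Published fit tables
  behave this way (zero-order TVB-N RMSE ≈ 1 mg/100 g), though it is rarely
  stated; it is recorded here as a package convention.
* **Relative deviation** in validation is
  $100\,|A_\text{meas} - A_\text{pred}|/|A_\text{pred}|$: the predicted value
  is the denominator. Validation tables in this literature that are
  arithmetically exact from their printed inputs match only this convention.
* **$A_0$** in a shelf-life model defaults to the measured $t = 0$ value of
  the calibration series (averaged over temperatures in `run_pipeline()`), not
  the regression intercept. A config override is available.

## Free versus forced intercept

The textbook rate equations algebraically force the fitted line through the
transformed initial value $A_0$. Published fit statistics, however, behave like
conventional free-intercept regressions, and with a free intercept the two
common definitions of $R^2$ (squared Pearson correlation and
$1 - SS_{res}/SS_{tot}$) coincide. `fit_kinetic()` therefore defaults to a free
intercept; `force_intercept = TRUE` provides the constrained form for users who
want the textbook identity.

## The synthetic-data generator

`simulate_series()` is the package's stated world: Arrhenius-consistent rate
constants, exact zero- or first-order trajectories, plus i.i.d. additive
Gaussian measurement noise. This matches how such studies report symmetric
error bars on raw indicator scales; a log-normal option exists for strictly
positive first-order indicators. Every simulation takes an explicit integer
seed and restores the caller's RNG state — no global RNG is consumed.

What the generator deliberately does **not** emulate: microbial lag and
stationary phases (TVC growth is log-linear from $t=0$), replicate-level
variance structure, non-isothermal storage, and autocorrelated measurement
error. A green recovery test therefore establishes that the estimation chain
is correct *under the model's own assumptions* — not that real spoilage data
satisfy those assumptions.

`make_reference_fixture()` emits a five-indicator CSV mimicking a published
study design: sampling on days 0–10 (step 2) at 4 °C and hours 0–60 (step 12)
at 25/37 °C, with initial values and end-of-storage magnitudes taken from
printed endpoints (TVC 0.57 → 1.7/6.83/7.8 log CFU/g; hardness 379 g falling
23.75/49.87/67.55 %; springiness 4.23 → 3.6/3.2/3.0 N/m²). Trajectories are
generated from the endpoint-implied per-temperature rate constants directly —
endpoint-exact rather than forced to be Arrhenius-consistent, since real data
are not exactly Arrhenius-consistent either. The noise SDs (0.5 mg/100 g
TVB-N, 0.08 log CFU/g TVC, 0.05 for AV and springiness, 5 g hardness) are
fixture choices on the order of the error bars such studies plot; they are not
claims about any particular data set.

```{r recovery}
cfg <- synthetic_config("TVB-N", order = 0, a0 = 6.9,
                        ea_kj_per_mol = 70.736, k0 = 2.72e13, rate_sign = 1,
                        temperatures_c = c(4, 25, 37),
                        times_days = list(seq(0, 10, 2), seq(0, 2.5, 0.5),
                                          seq(0, 2.5, 0.5)),
                        noise_sd = 0.5, seed = 11)
rec <- recovery_experiment(cfg, replicates = 50)
rec$summary[c("order_accuracy", "ea_median_rel_err")]
```

## Numerical choices and degenerate inputs

* OLS lines are solved by QR (`stats::lm.fit`); the test suite checks them
  against independently coded normal equations to $10^{-9}$.
* Order selection uses a $10^{-12}$ tolerance when declaring summed-$R^2$
  ties; ties fall back to the smaller summed RMSE, then the lower order.
* A constant series fits with $k = 0$, RMSE 0 and (by convention) $R^2 = 1$
  when the residuals are exactly zero; $R^2$ of a genuinely pathological fit
  may be negative and is flagged, not rejected.
* First-order transforms reject non-positive values, naming the offending time
  point; in simulation, additive noise that pushes an order-1 trajectory to
  $\le 0$ is clipped to a small positive floor (default $10^{-6}$) with a
  warning.
* $k = 0$ in a shelf-life model signals an unbounded shelf life (`Inf`), not
  an error; a rate pointing away from the limit raises an infeasibility error
  carrying the sign diagnostic.
* Exact shelf-life ties across indicators resolve to the canonical registry
  order (TVB-N, TVC, AV, springiness, hardness, pH, sensory), with all tied
  indicators reported.

## Known inconsistencies in the published reference tables

The bundled reference tables (`crayfish_*_reference()`) reproduce printed
values verbatim, including three internal inconsistencies that the package
documents rather than silently repairs:

* the springiness pre-exponential factor is printed as $4.10 \times 10^7$,
  but its own printed intercept gives $\exp(17.259) = 3.13 \times 10^7$
  (consistent instead with 17.529 — an apparent digit transposition). K0 is
  always derived from the intercept here.
* the hardness zero-order $\sum R^2$ is printed as 2.916 while its printed
  components sum to 2.913; `indicator_kinetics()` computes sums from
  components exactly. Order selection is unaffected.
* four of the 25 printed validation deviations (TVC days 2/4/6, AV day 4)
  cannot be reproduced from their printed measured/predicted pairs under any
  simple formula — they evidently derive from unrounded underlying values.
  The other 21 recompute to within ±0.15 points, and the recomputed maximum
  over all 25 pairs (9.07 %) respects the published ≤ 9.5 % bound.

Separately, the shelf-life equation table of the same source disagrees with
its own Arrhenius parameter table in the exponents; the Arrhenius parameter
table is treated as authoritative because back-calculation from the validation
predictions is consistent with it.

## Limitations

The package is isothermal: it does not integrate time-varying temperature
profiles, model microbial lag phases, weight observations, or produce
confidence intervals on $E_a$ (none are reported in the tables it mirrors).
Second-order kinetics are supported in fitting and selection but have no
closed-form shelf life. These are scope decisions, not oversights.
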