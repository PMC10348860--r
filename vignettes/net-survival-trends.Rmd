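---
title: "Methods: net-survival trend analysis with nordsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: net-survival trend analysis with nordsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nordsurv)
```

# What the package computes

`nordsurv` analyses long-run trends in cancer patient survival from
population-based registry data. The chain of quantities is:

1. **Relative (net) survival** per 5-year diagnosis period, age-standardized,
   at 1- and 5-year horizons, estimated with the Pohar Perme estimator.
2. A **Bayesian Gaussian GAM** of the period series against calendar time,
   giving posterior draws of the survival curve on a 0.1-year grid.
3. **Conditional 5/1-year survival**, obtained by dividing posterior draws of
   the 5-year curve by draws of the 1-year curve.
4. **Change windows and breakpoints** from credible intervals of the
   posterior's first and second time derivatives.

A synthetic-registry module generates patient-level cohorts with *known*
ground-truth net survival, so every stage above is testable by parameter
recovery without access to any real registry.

# Relative survival and the Pohar Perme estimator

Relative (net) survival compares the observed survival of patients with the
expected survival of a demographically matched slice of the general
population, estimating survival in the hypothetical absence of other causes
of death. Expected mortality comes from a life table $q(a, y)$ (annual death
probability at age $a$ in calendar year $y$). Each patient's background
hazard is taken piecewise-constant on follow-up years: during follow-up year
$k$ it is the hazard of age $a_i + k$ in calendar year
$\lfloor y_i \rfloor + k$ — ages and years advance together on diagnosis
anniversaries, the same convention the simulator uses.

The Pohar Perme estimator weights each patient's events and at-risk time by
the inverse of their expected survival $w_i(s) = 1/S_{E,i}(s)$, which removes
the informative-censoring bias of older relative-survival estimators.

**Discretization.** The estimator runs on a monthly grid (1/12 year)
augmented with the observed death times:

* weights are updated at month starts (stable within a month);
* each observed death contributes a product-limit factor
  $1 - D_w(s)/Y_w(s)$ at its exact time, where $D_w$ sums the weights of the
  deaths at $s$ and $Y_w$ the weights of the risk set at $s$;
* each month contributes one expected-mortality factor
  $1 + E_w/\bar Y_w$, where $E_w$ accumulates $w_i \lambda_{E,i}\,dt$ over
  the month and $\bar Y_w$ is weighted person-time divided by the month
  width;
* the variance of the cumulative net hazard is
  $\sum_s \sum_{i \in D(s)} w_i^2 / Y_w(s)^2$.

The product-limit form (rather than $\exp(-\sum \Delta\Lambda)$) was chosen
deliberately: with a zero life table all weights are 1 and the expected
factors vanish, so the estimator reduces *exactly* to Kaplan–Meier, ties
included. That exact reduction is an anchor for the test suite. Confidence
intervals use the log(−log) transform of the survival scale; estimates at or
above 100% — legitimate for net survival in sparse strata — fall back to a
plain delta-method interval and are flagged, never clipped.

**Age standardization** uses external weights over five groups
(0–49 / 50–59 / 60–69 / 70–79 / 80–89, default weights
0.25/0.25/0.20/0.20/0.10 — a documented convention, configurable, since
standard weight tables vary between agencies). It is implemented by
individual reweighting: each patient in group $g$ has estimator weight
multiplied by $w_g/\hat p_g$. When the cohort's age mix equals the weights
this reproduces the unstandardized estimate exactly; it agrees with the
weighted mean of group-specific estimates up to second-order
($O_p(n^{-1/2})$) terms, which is how the test suite checks it.

**Period assembly.** Nine completed periods (1971–75 … 2011–15) use the
cohort method. The final period 2016–20 uses a hybrid period/cohort
analysis: patients diagnosed 2012–2020 contribute only person-time falling
inside the calendar window [2016, 2021) — delayed entry at
$\max(0, 2016 - y_i)$ and right censoring at the window end — so recent
diagnoses inform early follow-up intervals and older diagnoses the late
intervals. The diagnosis window 2012–2020 is a configurable choice (the
standard period-analysis construction for a 5-year horizon); it is isolated
in one function argument.

# The trend model

Period-wise survival percentages (one value per country and period, at the
period midpoints 1973, 1978, …, 2018) are modelled on the raw % scale as

$$y_{cj} = \alpha + u_c + \gamma_c (t_j - \bar t) + Z(t_j) b_c +
  \varepsilon_{cj}, \qquad \varepsilon \sim N(0, \sigma^2),$$

a global intercept, a country offset and a country-specific penalized
cubic B-spline (P-spline) smooth of calendar time with second-difference
penalty, written in mixed-model form ($b_c \sim N(0, \tau_c^2 I)$ after
reparameterization; the penalty null space — constant and linear — is
handled by centring and the explicit linear term). Priors are weakly
informative: $N(0, 50^2)$ on intercepts/offsets/linear slopes (on centred
data), half-$N(0, 10)$ on $\sigma$, half-$N(0, 5)$ on each $\tau_c$ (units:
survival %). Defaults: `basis_dim = 8` per country for 10 observations,
`n_draws = 2000` over 2 chains.

**Sampling.** The sampler is a collapsed Gibbs scheme: the five (or $1 + C$)
variance parameters $(\log\sigma, \log\tau_c)$ are updated by univariate
slice sampling against the *marginal* posterior with all regression
coefficients integrated out analytically; the coefficients are then drawn
exactly from their joint Gaussian conditional. Because the Gaussian layer is
integrated out, there is no funnel geometry and mixing is near-iid;
split-$\hat R$ across split half-chains is attached to every posterior and
values above 1.05 abort with an error. Fixed seeds give bit-identical
draws.

**What is not propagated.** Observations enter unweighted: the standard
errors of the period estimates are not passed into the GAM. The posterior
therefore reflects residual scatter of the ten period values, not the
estimator's own uncertainty. This mirrors the usual practice of fitting
published period estimates directly and is a documented limitation.

# Derived trends and detection rules

* **Conditional 5/1-year survival**: draw $i$ of the 5-year posterior is
  divided by draw $i$ of the 1-year posterior (times 100). The two models
  share no parameters, so index pairing is an arbitrary but reproducible
  coupling; cross-model correlation is not modelled. Any non-positive 1-year
  draw is an error rather than a silent Inf.
* **Derivatives**: per-draw central finite differences with $h$ = the grid
  step (0.1 year): exact for linear and quadratic draws, $O(h^2)$ otherwise;
  one grid point is consumed at each boundary.
* **Change windows**: maximal runs where the pointwise 95% credible interval
  of the first derivative excludes zero with constant sign, reported when
  the run *spans* at least 5 years ($t_{end} - t_{start} \ge 5$, boundaries
  inclusive; a 4.9-year run is not reported).
* **Breakpoints**: the same run rule on the second derivative with a 3-year
  span; within a qualifying run the breakpoint is the peak — the time of the
  largest absolute posterior-mean second derivative, ties broken toward the
  earliest time. Posterior mean (not median) defines the peak; the choice is
  isolated in one function.
* **Country contrasts**: draw-wise differences $A - B$ with the same 5-year
  run rule on the difference's credible interval.

All interval rules are pointwise with run-length guards as the multiplicity
control — deliberately so, rather than simultaneous bands; the run length is
what protects against isolated pointwise exclusions.

# The synthetic registry

The generator's purpose is parameter recovery, not demographic realism.

* **Excess hazard**: two-phase in time since diagnosis — one level in the
  first year, a constant level thereafter — calibrated from target 1- and
  5-year net survival curves $S_1(y), S_5(y)$ of diagnosis year. This gives
  closed-form net survival for any $(t, y)$ and exact inverse-CDF
  simulation. Calendar shapes cover flat, linear, piecewise-linear and
  logistic trends; the default scenario set emulates the qualitative trend
  shapes of long-run female-cancer registry series (steady rise, rise with
  levelling-off, steep piecewise rise from a low start, upward-bending rise,
  flat), with small logit-scale country offsets.
* **Background mortality**: Gompertz life tables
  $q = 1 - \exp\{-h_0 e^{ba} e^{-c(y-1961)}\}$ (defaults $h_0 = 2.5\times
  10^{-5}$, $b = 0.095$, $c = 0.01$: roughly female-Nordic-shaped, entirely
  synthetic), simulated year-by-year along the attained-age/calendar
  diagonal as piecewise-constant annual hazards. Excess and background act
  as independent competing risks — exactly the assumption under which
  relative survival estimates net survival.
* **Ages** at diagnosis: discretized Normal(65, 12²) truncated to 30–89,
  keeping all five standardization groups populated. Diagnosis dates are
  uniform within calendar years. Administrative censoring at the end of
  2020; an optional independent censoring rate is exposed because real
  registries' emigration behaviour is unknown.

What a green recovery test establishes: the estimator chain is unbiased and
correctly calibrated *under these assumptions* (proportional, age-constant
excess hazard; exact life tables; independent competing risks). It does not
establish robustness to age-dependent excess hazards, life-table
misspecification, or dependent censoring — real-data features the generator
deliberately does not emulate.

# Rate standardization and smoothing

Incidence/mortality series are age-standardized to the 18-group Segi world
standard population (the conventional "world standard" in registry work;
configurable, since some agencies use the WHO 2000 standard):
$ASR = \sum_g w_g (cases_g / person\text{-}years_g) \times 10^5$.
Display series are smoothed with a natural cubic smoothing spline
(Green–Silverman formulation, penalty $\lambda \int f''^2$ on the raw year
scale, $\lambda$ by generalized cross-validation). The smoother is
implemented directly because `stats::smooth.spline`'s internal predictor
rounding limits reproducibility against a textbook reference; it is checked
against both an independent Reinsch-algorithm implementation and
`smooth.spline` in the tests. Smoothing is presentation-only: every
statistic runs on unsmoothed series.

# Numerical and edge-case conventions

* Time is decimal years; intervals are half-open $[start, end)$; the
  administrative horizon "end of 2020" is calendar time 2021.0.
* Life-table lookups clamp above the oldest age (99) and outside the covered
  year range; missing cells are errors naming the (age, year) gap.
* Empty risk sets before the horizon carry the last estimable value forward
  with a `carried_forward` flag; empty diagnosis periods yield `NA` rows
  flagged `no-patients` (the 10-row series shape is always preserved).
* An age group with positive standard weight but no patients is an error
  listing the group — silent reweighting would bias the estimate.
* GCV for the display smoother is searched on a log-$\lambda$ interval
  scaled by $range(x)^3$, the natural invariance scale of the penalty.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → rates → estimate → fit → detect →
report, writes every table as CSV, figures as PDF (with the PDF creation
dates scrubbed so byte-identical content hashes certify determinism), and
returns a manifest of MD5 hashes. A stage failure removes the partial
outputs and aborts with a stage-named error. Every number shown in a figure
is also present in a CSV artifact. The packaged CLI
(`inst/scripts/nordsurv-cli.R`) is a thin wrapper exposing the stages as
subcommands; the R functions are the primary interface.

# Known limitations

* Estimate-level uncertainty is not propagated into the trend model (above).
* The conditional 5/1-year posterior ignores cross-model correlation.
* The hybrid diagnosis window (2012–2020) is a convention, not an inferred
  quantity.
* Net-survival recovery at $n = 2000$ diagnoses/period has a sampling SD of
  roughly 1–1.6 %-units depending on the survival level, so single-period
  estimates should be read with their confidence intervals, not as point
  values.
* The synthetic world emulates trend *shapes*; absolute levels of incidence,
  mortality and survival are not calibrated to any real population.
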