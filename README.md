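# nordsurv

Long-run **net-survival trend analysis** for population-based cancer registry
data, with a fully synthetic registry for validation.

Cancer registries publish relative (net) survival — the ratio of patients'
observed survival to the expected survival of a demographically matched
general population — in 5-year diagnosis periods spanning decades. The
scientific questions this package addresses are the ones registry
epidemiologists ask of such series: *how much* has survival improved, *when*
was it improving with high plausibility, *when did the pace change*, and how
do patients who survive the first year fare? It is written for biostatisticians
and cancer epidemiologists working with registry extractions (e.g. NORDCAN-style
period series) or with patient-level data plus national life tables.

## What it computes

1. **Age-standardized relative survival** at 1 and 5 years per 5-year period,
   with the Pohar Perme estimator
   (weights `w_i(s) = 1/S_E,i(s)`; net-hazard increments
   `(sum w dN - sum w lambda_E Y ds) / sum w Y`; variance
   `sum w^2 dN / Y_w^2`), using the cohort method for completed periods and a
   hybrid period/cohort analysis (left truncation at the calendar-window
   start) for the most recent period 2016–2020.
2. A **Bayesian Gaussian GAM** of survival % vs calendar time per country —
   global intercept, country offset, country-specific P-spline smooth
   (cubic B-splines, second-difference penalty) — sampled by a collapsed
   Gibbs scheme (slice sampling of variance parameters against the
   coefficient-marginalized posterior, exact Gaussian coefficient draws),
   yielding posterior draws of the fitted curve on a 0.1-year grid.
3. **Conditional 5/1-year survival**: draw-wise division of the 5-year
   posterior by the 1-year posterior.
4. **Change windows**: maximal runs where the pointwise 95% CrI of the first
   derivative excludes zero for at least 5 years. **Breakpoints**: the peak
   of the posterior-mean second derivative within runs where its 95% CrI
   excludes zero for at least 3 years. **Country contrasts** and
   **improvement posteriors** `f(t1) - f(t0)`.
5. **World-standard (Segi) age-standardized incidence/mortality rates** per
   100 000 with natural-cubic-smoothing-spline display smoothing.
6. A **synthetic registry**: Gompertz life tables and patient cohorts with
   known two-phase excess hazards (closed-form net survival), so every stage
   is validated by parameter recovery.

See `vignettes/net-survival-trends.Rmd` for the model details, conventions
and limitations.

## Worked example

```r
library(nordsurv)

# a synthetic Swedish-style breast-cancer registry with known truth
lt  <- build_life_table("SE", baseline = 2.5e-5, slope = 0.095, decline = 0.01)
sc  <- default_scenarios("SE", "breast")$SE.breast
coh <- simulate_cohort(sc, lt, n_per_year = 400, seed = 1)

# ten 5-year periods of age-standardized 5-year net survival
ss <- assemble_period_series(coh, lt, horizon = 5)
ss[c(1, 5, 10), c("period", "method", "n", "estimate", "ci_low", "ci_high")]
#>       period method    n estimate ci_low ci_high
#> 1  1971-1975 cohort 2000     60.3   57.6    62.9
#> 5  1991-1995 cohort 2000     69.8   67.1    72.3
#> 10 2016-2020 hybrid 3416     85.8   83.6    87.7

# Bayesian trend GAM and derived quantities
obs <- data.frame(country = ss$country, time = ss$midpoint, value = ss$estimate)
tp  <- fit_trend_gam(obs, seed = 1, site = "breast", measure = "surv5")[["SE"]]
imp <- survival_improvement(tp, 1973, 2018)
sprintf("improvement 1973->2018: %.1f%% units (95%% CrI %.1f to %.1f)",
        imp$mean, imp$ci[1], imp$ci[2])
#> "improvement 1973->2018: 24.1% units (95% CrI 19.8 to 28.5)"

significant_change_windows(derivative_curves(tp, 1))
#>   t_start  t_end direction
#> 1  1973.1 1983.2  increase
#> 2  1989.4 2017.7  increase
```

The estimated 5-year net survival rises from ~60% to ~86% — the generating
truth moves from 63.2% to 89.2% over the same span, and each period estimate
carries its Pohar Perme confidence interval. The trend posterior identifies
two sustained improvement windows; under this gently-bending scenario no
slope breakpoint reaches the 3-year curvature criterion.

The full pipeline (simulate → rates → estimate → fit → detect → report, with
CSV artifacts, figures and a hash manifest) runs via `run_pipeline()` or the
thin CLI in `inst/scripts/nordsurv-cli.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch under the given
seed — synthetic cohorts and life tables, period-wise Pohar Perme series
(cohort + hybrid), trend GAMs, conditional 5/1-year posteriors, and
derivative-based change detection — and writes the JSON report to `--out`.
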