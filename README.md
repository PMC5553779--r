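# ichcost

Hospital treatment costs and length of stay after spontaneous intracerebral
hemorrhage (ICH), modelled from ICD-coded administrative discharge records.

ICH is the deadliest common stroke subtype and among the most expensive to
treat, and two thirds of ICH patients arrive at hospital hypertensive.
`ichcost` is for health-services researchers and biostatisticians who want
to quantify how admission morbidities — hypertension above all — drive
hospital cost and prolonged stay, and how cost relates to time spent in
hospital. The package implements the full analysis pipeline and, because
patient-level administrative data cannot be redistributed, ships a
calibrated synthetic discharge-cohort generator so that every stage is
runnable and testable end to end.

## What it computes

* **Morbidity coding** — each discharge's ICD-9-CM/ICD-10-CA codes are
  classified into 13 admission-morbidity categories from a plain-text
  catalog of exact codes, wildcard stems (`401.x`) and ranges
  (`430.x–438.x`); the index ICH code is excluded and the multimorbidity
  count is the number of flagged categories.
* **Dollar-scale cost effects** — OLS on `ln(cost)` with HC1 sandwich
  standard errors; effects are retransformed with the Duan smearing factor
  `S = mean(exp(residuals))`, and the reported dollar change of an exposure
  is the cohort-average difference of smeared predictions
  `mean(S·e^{Xβ|x=1}) − mean(S·e^{Xβ|x=0})`, with a percentile-bootstrap CI.
* **Relative risks** — binomial GLM with log link for prolonged stay
  (strictly > 7 days) or death, with an automatic modified-Poisson
  (robust-variance) fallback when the log-binomial fit does not converge.
* **Cost vs time** — restricted cubic splines (Harrell knots) and weekly
  linear splines of `ln(cost)` on length of stay, with robust slope and
  slope-change tests, plus cost summaries by stay window.
* **Generational Monte Carlo simulation** — replicate cohorts of ICH
  admissions over a 100-year horizon (0.94 %/yr population growth, 12
  admissions per 100,000, ages ~ N(70, 13²) truncated to [18, 126],
  hypertension 77 %), costs resampled from a reference cohort by
  nearest-age matching within hypertension strata, compared with the
  primary estimate by Welch's unequal-variance test.

The methods vignette (`vignettes/ichcost-methods.Rmd`) documents the
generative model, the calibration procedure and all numerical choices.

## Worked example

```r
library(ichcost)

cohort <- generate_cohort(cohort_config())   # 987 discharges, default seed
summarize_cohort(cohort)
#> Cohort summary (n = 987 )
#>   Sex (% male)            52
#>   Age (years)             70.8 (22.1-98.9)
#>   Length of stay (days)   8 (1-159)
#>   Died in hospital (%)    31
#>   Had surgery (%)         18
#>   Total cost (USD)        10384.3 (602.1-633297)
#>   Morbidities at admission (%):
#>     Hypertension               68
#>     ...
#>     Overall (any)              83

fit_log_cost(cohort, c("morb_hypertension", "age"), n_boot = 200)
#> Log-cost regression (cost_total), n = 987, smear factor = 2.3009
#>           covariate beta_log se_robust  p_value dollar_change  ci_low  ci_high
#> 1 morb_hypertension   0.3617    0.0868 3.09e-05       8527.53 4038.92 12256.26
#> 2               age   0.0086    0.0033 8.41e-03        218.53   58.58   398.38

fit_rr(add_long_stay(cohort), "los_gt7", "morb_hypertension", adjust = "age")
#> RR (morb_hypertension) = 1.283, 95% CI 1.115-1.475, p = 0.0004856
#> [log-binomial; adjusted for age]

fit_rcs(cohort)
#> Restricted cubic spline of ln(cost) on length of stay
#>   knots (days): 2, 5, 8, 13, 35.7
#>   n = 987, R^2 = 0.729
```

Reading: in this synthetic decade of 987 discharges, hypertensive patients
cost on average ~$8.5k (95 % CI $4.0k–$12.3k) more per discharge than
non-hypertensive patients of the same age, carry a 28 % higher risk of
staying beyond one week, and length of stay alone explains ~73 % of the
variance in log cost along a steep-then-flattening curve. At n = 987 these
one-cohort estimates are noisy; at n = 50,000 the pipeline recovers the
generator's calibrated targets to within a few percent (see below).

Real discharge files enter through `ingest()`, which applies the study
exclusions (missing/nonpositive cost, age < 18), classifies codes when
morbidity flags are absent, and reports the exclusion accounting.
`inflate()` rescales historical costs to a reference year from a
user-supplied two-column CPI series.

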