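# airtwa

Time-weighted individual ambient air pollution exposure and survival
analysis.

## The problem

Cohort studies of air pollution and cardiovascular outcomes usually assign
each participant the outdoor concentration at their home address. Adults,
however, spend most of the day indoors — where only an infiltrated fraction
of the ambient pollutant penetrates — split their time between home and a
workplace that may sit in a different part of the city, and commute inside
vehicles with their own infiltration behaviour. `airtwa` is for
environmental epidemiologists who want to carry a *micro-environment
time-weighted* personal exposure through a full survival analysis, and to
validate every step on synthetic cohorts with known ground truth (the real
cohorts behind such analyses are typically private).

## The model

On a working day, the personal daily concentration for a pollutant is

    Y = [ C_h*T_hout + C_w*T_wout
          + IF_h*(C_h*T_hin + C_w*T_win)
          + T_trans*IF_t*(C_h + C_w)/2 ] / 24

with `C_h`, `C_w` the outdoor concentrations at the home and work address
that day, `T_*` the hours spent outdoors/indoors at each place and
commuting (summing to 24 h), `IF_h ∈ (0,1]` the indoor infiltration factor
and `IF_t` the in-vehicle factor for the commute mode. On days off work the
workplace terms drop out:

    Y = [ C_h*T_hout + IF_h*C_h*T_hin + T_trans*IF_t*C_h ] / 24

Daily values are averaged over trailing windows (1–5 years) ending the day
before each participant's anchor date — diagnosis for cases, last
follow-up for censored participants — and the window averages feed:

* **Cox proportional-hazards models** with three nested covariate sets,
  reporting hazard ratios per interquartile range and by exposure quartile
  (Efron ties, Wald 95% CIs);
* **restricted-cubic-spline exposure–response curves** with the knot count
  (3–7, Harrell quantile placement) chosen by AIC and the curve normalised
  to HR = 1 at the median exposure;
* **quantile g-computation** for the six-pollutant mixture: quartile
  scores, one joint Cox fit, overall effect ψ = Σβ (mixture HR = exp(ψ))
  with sign-partitioned pollutant weights;
* sensitivity analyses (no infiltration, medication-free subset,
  complete-case subset, two-pollutant models with a |ρ| > 0.6 Spearman
  screen, 1–5-year window sweep) and subgroup analyses.

Missing commute times are multiply imputed (chained-equation regression
with predictive mean matching, m = 5) and estimates pooled by Rubin's
rules. A seeded synthetic generator supplies concentration fields
(seasonal, spatially graded, cross-pollutant correlated), questionnaire
answers in coded form, and proportional-hazards event times driven by the
true time-weighted exposure.

## Worked example

```r
library(airtwa)

cfg  <- cohort_config(n_participants = 1500, seed = 7)
coh  <- simulate_cohort(cfg)
coh
#> Synthetic cohort: n = 1500, events = 526 (35.1%), baseline 2015-01-01, end 2016-12-31
#>   commute time missing: 280 (18.7%); seed 7

imp  <- impute_missing_times(coh$activity, m = 5, seed = 7)
expo <- compute_cohort_exposures(coh$participants, imp[[1]], coh$field,
                                 infiltration_table(), windows = c(365, 730),
                                 pollutants = c("pm25", "pm10"))
exposure_iqr(expo)
#>   pollutant window      iqr
#> 1      pm25    365 4.362985
#> 2      pm25    730 4.315969
#> 3      pm10    365 4.807637
#> 4      pm10    730 4.880083

wide <- merge(coh$participants, exposure_wide(expo), by = "id")
fit_cox(wide, "pm25_730", model = 3, form = "iqr")
#> Cox model (17 covariates), exposure 'pm25_730' [iqr], n = 1500, events = 526
#>   IQR used for scaling: 4.316
#>     term estimate    se    hr    lo    hi     p
#>  per_iqr    0.119 0.064 1.126 0.994 1.276 0.061

fit_spline(wide, "pm25_730", model = 3)
#> Restricted cubic spline exposure-response for 'pm25_730'
#>   selected 3 knots (df = 2) by AIC; reference = 52.12 (HR = 1)
#>   departure-from-linearity LRT p = 0.438
```

The per-IQR hazard ratio of 1.126 says the hazard of the simulated outcome
rises ~13% per interquartile-range (4.3 µg/m³) increase in two-year
time-weighted PM2.5 — a single-seed draw around the generating truth of
exp(0.05 × 4.3) ≈ 1.24. The spline's likelihood-ratio p = 0.44 correctly
finds no departure from the log-linear truth.

The mixture fit on the same cohort illustrates honest quantile
g-computation behaviour under collinearity:

```r
expo6 <- compute_cohort_exposures(coh$participants, imp[[1]], coh$field,
                                  infiltration_table(), windows = 730)
wide2 <- merge(coh$participants, exposure_wide(expo6), by = "id")
fit_qgcomp_cox(wide2, paste0(POLLUTANTS, "_730"), model = 3)
#> Quantile g-computation (Cox, q = 4): n = 1500, events = 526
#>   psi = -0.1915; mixture HR per quantile increase = 0.826 (95% CI 0.708-0.963)
#>  pollutant coefficient partition weight
#>   pm25_730      0.1912  positive  0.307
#>   pm10_730      0.2861  positive  0.459
#>    so2_730     -0.2214  negative  0.272
#>    no2_730      0.1454  positive  0.233
#>     co_730     -0.4011  negative  0.493
#>     o3_730     -0.1918  negative  0.235
```

Only PM2.5 carries a true effect here, but the six window exposures are
strongly rank-correlated (shared coordinates, behaviour and weather), so
individual coefficients — and hence ψ — borrow signal from one another
with unstable signs. This is a known property of mixture models under
collinearity, and it is why the package ships the two-pollutant
correlation screen and why the mixture recovery experiment in the test
suite uses six *independent* exposures (where ψ = 0.30 is recovered to
within a few percent). The pipeline wrapper (`run_analysis()`) sequences
all of the above plus sensitivity and subgroup batteries into a
reproducible report bundle with a manifest.

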