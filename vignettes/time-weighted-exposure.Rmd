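---
title: "Micro-environment time-weighted exposure and the survival analysis battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-environment time-weighted exposure and the survival analysis battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airtwa)
```

## The exposure model

Assigning every participant the outdoor concentration at their home address
misclassifies personal exposure: adults spend most of the day indoors, part
of it at a workplace kilometres away, and a non-trivial slice inside
vehicles. `airtwa` models a day as five micro-environments. On a working
day the personal daily concentration is

$$Y = \frac{C_h T_{hout} + C_w T_{wout}
      + IF_h\,(C_h T_{hin} + C_w T_{win})
      + T_{trans}\, IF_t\, \tfrac{C_h + C_w}{2}}{24},$$

where $C_h$ and $C_w$ are the outdoor concentrations at the home and work
addresses that day, the $T$'s are hours spent outdoors/indoors at each
place and commuting (summing to 24), $IF_h \in (0,1]$ is the fraction of
the ambient pollutant found indoors, and $IF_t$ the in-vehicle fraction for
the participant's commute mode. The in-vehicle ambient level is taken as
the average of the home and work outdoor concentrations. On days off work
the workplace terms drop out:

$$Y = \frac{C_h T_{hout} + IF_h\, C_h T_{hin} + T_{trans}\, IF_t\, C_h}{24}.$$

Daily values are averaged over trailing windows of 365, 730, 1095, 1460 or
1825 days ending the day *before* each participant's anchor date — the
diagnosis date for cases, the last follow-up for censored participants —
and those window averages enter the survival models.

### Conventions the equations leave open

Several details are not dictated by the equations themselves; the package
fixes them as follows and exposes each as an argument where a user could
reasonably want another convention.

* **Day-off time budget.** An activity profile carries one set of hours.
  On days off, workplace hours are reattributed to the corresponding home
  micro-environment (indoor work time to indoor home time, outdoor to
  outdoor), with commuting unchanged, so the day-off budget also sums to
  24 h. Workdays are the first `workweek` (default 5) days of each 7-day
  block of the concentration field's coverage.
* **Budget tolerance.** Questionnaire sums rarely close exactly. Budgets
  within $24 \pm 0.5$ h are rescaled proportionally to 24; anything further
  off is treated as a data error and refused rather than silently patched.
* **Exercise.** Weekly exercise ($f$ sessions of length $\ell$) is spread
  as $f\ell/7$ hours per day and folded into the home budget by venue:
  outdoor exercise moves that much time from indoors-at-home to
  outdoors-at-home; indoor exercise stays within indoor time. The daily
  equations carry no separate exercise term, so this folding rule is a
  modelling choice, not a claim about the underlying physiology.
* **Units.** Hours internally; concentrations in µg/m³ (CO in mg/m³); the
  equations divide by 24 exactly as written.

### Questionnaire decoding

Commute duration options (< 30, 30–60, > 60 min one way) map to 30, 45 and
60 minutes; exercise frequency options (1–2, 3–5, > 5 per week) to 2, 4
and 6 sessions; session length options to 30, 45 and 60 minutes. Directly
reported hours pass through. Venue is derived from the exercise type
(yoga, swimming, gym ball sports → indoor; jogging, climbing, bicycling →
outdoor) unless given explicitly.

### Infiltration factors

The shipped table (`infiltration_table()`) contains plausible mid-range
values for urban buildings and vehicles — e.g. home infiltration 0.70 for
PM2.5 and 0.45 for PM10, vehicle factors by commute mode, walking/cycling
treated as outdoor exposure ($IF_t = 1$). They are **configurable
defaults**, not measured constants: published infiltration studies vary
widely by building stock and season, and every downstream result is
reproducible under any user-supplied table with factors in (0, 1]. A
missing PM10 bus factor is substituted by the PM2.5 bus factor, the
convention forced by the scarcity of in-bus PM10 measurements. Note that
because indoor attenuation is stronger for coarse particles, time-weighted
PM10 exposure can fall below PM2.5 exposure even where ambient PM10 is
higher — an expected consequence of the model, not a bug.

### Missing commute times

Missing `t_trans` is multiply imputed ($m = 5$) by a chained-equation
scheme specialised to the single incomplete variable: Bayesian linear
regression of commute time on the other time-budget variables and commute
mode, with predictive mean matching (5 donors) so imputed values remain
within the observed range. Downstream per-IQR, quartile and mixture
estimates are pooled across imputations by Rubin's rules. A whole spline
curve has no canonical pooling rule, so the exposure–response curve is
fitted on the first completed dataset.

## The survival battery

* **Nested Cox models.** Model 1 adjusts for age and sex; Model 2 adds
  education, smoking, drinking, physical activity intensity, excessive
  salt intake and medication histories; Model 3 adds BMI, mean arterial
  pressure, fasting glucose, uric acid, LDL-C, HDL-C and triglycerides.
  The sequence is a fixed nesting, not automated variable selection. Ties
  are handled by Efron's method, and confidence intervals are Wald at 95%
  (the likelihood-ratio alternative differs negligibly at these event
  counts). Exposure enters either continuously, scaled by its
  interquartile range so the hazard ratio is per-IQR, or as quartile
  groups with Q1 as reference; quartile boundaries assign tied values to
  the lower group. Covariates that are constant in a given subset (the
  medication flags inside the medication-free sensitivity analysis) are
  dropped with a message rather than left to alias the fit.
* **Restricted cubic splines.** Candidate knot counts 3–7 are placed at
  Harrell's default quantiles and compared by the AIC of the partial
  likelihood; a $k$-knot restricted cubic spline has $k-1$ degrees of
  freedom, so the conventional 3-df display curve is the 4-knot fit,
  always reported alongside the AIC winner. The curve is normalised to
  HR = 1 at the reference exposure (the median), with pointwise Wald
  bands, and a likelihood-ratio test against the linear model quantifies
  departure from linearity. The basis is the natural cubic spline
  (`splines::ns`) with the outer knots as boundary knots — the same
  function space as the classical truncated-power restricted cubic
  spline, in a better-conditioned parameterisation.
* **Quantile g-computation.** Each of the six pollutants is quantized to
  quartile scores 0–3 (boundary values go up; scores are rank-invariant);
  one joint Cox model linear in all scores plus the Model-3 covariates is
  fitted; $\psi$ is the exact sum of the six coefficients and
  $\exp(\psi)$ the hazard ratio for raising every exposure one quartile
  simultaneously. Its variance is $\mathbf{1}'\Sigma\mathbf{1}$ from the
  joint covariance (delta method). Weights are sign-partitioned: each
  pollutant's coefficient divided by the summed coefficients of its sign,
  so each non-empty partition sums to 1; zero coefficients sit in the
  positive partition by convention. For this linear specification the
  marginal one-quantile contrast equals the coefficient sum, so the
  non-bootstrap estimator is exact and is the default; a seeded bootstrap
  CI is available for nonlinear extensions. Pairs of quantized exposures
  with $|r| > 0.99$ abort the fit with the offending pair named.
* **Two-pollutant models.** For each co-pollutant, Model 3 plus that one
  co-pollutant is refitted unless the Spearman correlation with the index
  exposure exceeds 0.6 in absolute value, in which case the pair is
  logged as not conducted due to collinearity.
* **Subgroups.** Model-3 per-IQR fits within strata split at sex, age 60,
  LDL-C 3.4, TG 1.7, HDL-C 1.0 (mmol/L), BMI 24 (kg/m²) and the
  sex-specific hyperuricemia thresholds (≥ 360 µmol/L women, ≥ 420 men);
  the stratifying covariate is removed from its own adjustment set, and
  strata under 50 participants are skipped with a note.

Throughout, two-sided α = 0.05 with no multiplicity correction — a
deliberate mirror of common practice in this literature, flagged here so
nobody mistakes the sensitivity battery for independent confirmations.

## The synthetic cohort generator

Because real cohort data of this kind are private, the package ships a
seeded generator that makes every stage testable with known ground truth.

* **Concentration fields.** Daily values at planar coordinates follow
  annual mean + seasonal sinusoid + linear spatial gradient + day-to-day
  noise, clipped at zero. The noise vector is shared across space and
  correlated across pollutants (positive among the combustion-related
  pollutants, negative for ozone), drawn once at construction so lookups
  are deterministic. Defaults emulate a heavily polluted
  northern-hemisphere city: winter-peaking particulates around
  60/95 µg/m³ annual mean, summer-peaking ozone. Zero-clipping affects
  well under 1% of days under the defaults. What the field does *not*
  emulate: temporal autocorrelation of synoptic weather, localised
  sources, long-term trends, or any land-use structure — passing tests
  say the pipeline is correct, not that the field is Beijing.
* **Participants and activity.** Demographics, lifestyle, labs and
  medication flags are drawn to loosely match an urban health-checkup
  cohort (median age ~42, 46% male, ~19% smokers); home/work coordinates
  live on an abstract 30 km square (no geodesy). Questionnaire answers
  are generated in coded form and passed through the same decoder as
  real data; time budgets carry reporting noise inside the ±0.5 h
  tolerance, which also keeps commute time from being a deterministic
  function of the other components (otherwise imputation would be
  trivial). Commute-time missingness is completely at random at a
  configurable fraction (default 0.2).
* **Event times.** A piecewise-constant daily hazard
  $h_i(t) = h_0 \exp\{\beta\,X_i(t) + \gamma'z_i\}$ drives
  inverse-transform sampling, where $X_i(t)$ is the *true* trailing
  730-day time-weighted exposure recomputed each follow-up day — exactly
  the quantity the analysis estimates at the anchor — and $z_i$ are
  centred covariates (age, sex by default). Enrollment begins after
  `history_days` (≥ 730) of field coverage so every anchor has a full
  window, entry is staggered over an enrollment window (default one
  year), and follow-up runs to each participant's last attended annual
  visit (per-year retention 0.9 by default) or the study end — the
  individual-censoring structure of a real checkup cohort. The default
  baseline hazard (6e-5/day) gives roughly a one-third cumulative
  incidence at typical exposure levels, matching the outcome frequency
  of carotid atherosclerosis screening cohorts.

One property of this design deserves a note. The analysis measures
exposure at each participant's own anchor date, so cases and censored
participants are measured at different calendar times. Because part of
the day-to-day concentration noise is shared city-wide, the trailing
730-day mean drifts slowly over calendar time as a common curve, and the
case-versus-risk-set comparison picks up a replicate-specific slice of
that drift. The result is extra replicate-to-replicate variability in
the estimated log-HR beyond the model standard error — an intrinsic
feature of diagnosis-date-anchored exposure windows under shared
temporal variation, not an implementation artifact (the same experiment
with exposure anchored at the entry date, which is independent of the
event process, shows no inflation). The replicate-mean estimate remains
unbiased and recovers the true 0.05 per µg/m³; null-configuration
confidence-interval coverage sits slightly below nominal (roughly 93%
across replicate blocks instead of 95%), while the same experiment with
entry-anchored exposure is fully nominal — both are quantified by the
replicated experiments in the test suite. Analysts using exit-anchored
windows on real data should be aware that strong secular concentration
trends would amplify this variance component.

## Numerical choices and problem sizes

* Vectorisation: the daily equations are linear in $(C_h, C_w)$, so each
  participant reduces to two coefficients per day type; cohort exposure is
  dense matrix arithmetic plus row cumulative sums, verified against a
  literal scalar day-by-day loop to 1e-9 on 50 random participants.
* Window averages use exact trailing sums (no FFT, no approximation); an
  insufficient history is an error naming the participant and window, not
  an NA.
* Quartile cutpoints use the default empirical quantile (type 7); tied
  cutpoints that would empty a group are an error naming the collision.
* The test suite runs cohorts of 200–3000 participants over 2.5–4 years of
  daily field coverage; the replicated recovery experiments use n = 3000
  with 50–200 replicates. These sizes give the recovery experiments
  standard errors an order of magnitude below the tolerances they check.

## Known limitations

* Household sources (cooking fuel, tobacco) are outside the model, as is
  geocoding — coordinates are abstract.
* The infiltration defaults are plausible, not measured; results that
  depend on the *absolute* exposure level (e.g. PM10 medians falling below
  PM2.5) follow from whatever table is supplied.
* The generator's field omits weather autocorrelation; if anything this
  makes the anchor-date variability note above conservative, since real
  synoptic persistence would lengthen, not shorten, the memory of the
  trailing mean.
* Mixture weights describe the fitted joint model; under strong
  collinearity between pollutants their individual signs are not stable
  even when the overall mixture effect is, which is precisely why the
  collinearity screens exist.
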