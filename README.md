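# glucirc

Blood glucose in intensive-care patients varies over the 24-hour day even
while nutrition is delivered continuously through an enteral tube at a
constant rate. Whether that pattern is endogenous circadian physiology (a
dawn-phenomenon-like morning rise) or an artifact of hospital routine —
morning lab rounds, daytime dextrose and glucocorticoid dosing, sampling
that intensifies when glucose is unstable — can only be decided by an
analysis that curates the event record carefully and adjusts for the
exposures measurement by measurement.

`glucirc` implements that analysis for MIMIC-style EHR event tables, for
clinical researchers studying diurnal physiology in routinely collected
ICU data:

* **Curation** — cohort inclusion (length of stay ≥ 4 days, no
  readmissions, glucose and enteral nutrition present), chart/store
  timestamp resolution, sample-type validity limits (capillary > 27.8
  mmol/L and laboratory > 55.6 mmol/L excluded), deduplication of
  simultaneous measurements by whole-blood > serum > capillary
  preference, restriction to enteral-nutrition periods.
* **Exposure matching** — pharmacokinetic effect windows (insulin start
  +0.5 h and end +2/4/10/12 h by action class, glucocorticoid end +24 h,
  dextrose pushes spread over 10 min), a sweep-line interval join of
  windows to each measurement, carbohydrate rates from product content,
  and derived covariates (days since admission, time to next sample,
  ventilation, sedation score).
* **Models** — the nested random-intercept sequence

  m1: glucose ~ 1; m2: + age + sex + diabetes; m3: + carbohydrate +
  insulin + dextrose + glucocorticoid; m4: + hour-of-day (24 levels),

  each `glucose ~ X + (1 | patient)`, REML for variance components, ML
  refits for likelihood-ratio tests (df 5/10/23) and hourly
  estimated-marginal-means profiles with Wald intervals; residual
  diagnostics; an XGBoost/SHAP cross-check on the uncategorised
  covariates.
* **Subgroups** — per-level m4 refits for ventilation, mortality,
  sedation (RASS ≤ −2), ICU day, sample type, sampling frequency, and
  stay-level insulin requirement (0 / ≤35 / ≤70 / >70 units/day).
* **Synthetic cohorts** — a generator with known ground truth at
  clinically realistic magnitudes (intercept 6.6 mmol/L, diabetes +2.2,
  between-patient/residual variances 2.8/5.4;
  a sinusoidal hour effect peaking at 10:00) including planted inclusion
  violations, out-of-range values, simultaneous duplicates, and optional
  diurnally confounded exposure schedules.

## Worked example

```r
library(glucirc)

g  <- generate_cohort(synth_config(n_patients = 500, seed = 42))
bt <- build_analysis_table(g$tables)   # curate + match + categorise
ms <- fit_model_sequence(bt$rows)      # m1..m4, REML + ML
ms
#> <glucirc_model_set>
#>   m1 (REML): 1 fixed params, logLik -38545.9, var(patient) 3.90, var(resid) 5.74
#>   m2 (REML): 6 fixed params, logLik -38484.8, var(patient) 2.85, var(resid) 5.74
#>   m3 (REML): 16 fixed params, logLik -38109.7, var(patient) 2.78, var(resid) 5.47
#>   m4 (REML): 39 fixed params, logLik -37929.1, var(patient) 2.80, var(resid) 5.34
#>   ...

lrt(ms$fits$ML$m3, ms$fits$ML$m4)      # does hour of day matter?
#> LRT: chi-square(df = 23) = 426.4, p = 6.53e-76

emm_profile(ms$fits$ML$m4)
#> <emm profile> peak 10.69 mmol/L at 11:00, trough 9.52 at 20:00 (amplitude 1.17)
```

The variance components land on the generating truth (2.8 between
patients, 5.4 residual), the hour-of-day block is overwhelmingly
supported by the LRT, and the adjusted hourly profile recovers the
injected morning peak (true peak 10:00; at ~30 measurements per stay the
argmax hour carries ±1 h of noise) with roughly the injected 1.0 mmol/L
peak-to-trough swing. Model coefficients are recovered at their
generating magnitudes, e.g. diabetes 2.1 (true 2.2), top carbohydrate
band 1.4 (true 1.4), glucocorticoid 1.0 (true 1.0).

`run_pipeline(g, "out/")` executes everything — curation report, model
fits, LRTs, EMM profile, SHAP profile, subgroup profiles — and writes
each result as CSV/JSON with a reproducibility manifest.

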