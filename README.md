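# icualert

Dynamic prediction of ICU-acquired infection (ICU-AI) with competing
risks, for biostatisticians and critical-care data scientists who want a
fully reproducible, data-free testbed for landmark survival modelling on
high-frequency ICU data.

ICU-AI — infection with onset more than 48 h after ICU presentation — is
predicted dynamically: every 8 hours along an ICU stay, at landmark time
$t_{LM}$, the package estimates the absolute risk of infection onset
within the next $w$ hours (48 by default, 24 as a sensitivity setting),
with death and ICU discharge as competing events. The core is a
**landmark competing-risk Cox supermodel**: cause-specific Cox models on
window time $u \in (0, w]$ fitted to the stacked landmark dataset with
landmark-time terms $s, s^2$ (or landmark strata), combined into the
cumulative incidence

$$\widehat F_{\mathrm{inf}}(w \mid x) = \sum_{u_j \le w} S(u_j^-)\,
\Delta\Lambda_{\mathrm{inf}}(u_j \mid x), \qquad
S(u_j) = \prod_{u_i \le u_j}\Bigl(1 - \sum_k \Delta\Lambda_k(u_i \mid x)\Bigr).$$

A **1-D convolutional network** (five conv/pool/dropout blocks, sigmoid
head; implemented in RcppArmadillo inside the package, trained with Adam
and early stopping, hyperparameters selected by cross-validated mean
AUC) turns the 5-channel 1-minute vital-sign window ending at $t_{LM}$
into an ancillary risk score; adding it to the supermodel gives the
nested *deep* model compared to the base model by likelihood ratio.

Because individual-level ICU data cannot be shipped, the package
includes a calibrated **synthetic cohort generator** (recurrent onsets
with 48-h post-onset blackouts, per-patient frailty, pre-onset drifts in
CRP/temperature/platelets, vital-sign deterioration signatures) plus the
full evaluation suite: patient-grouped cross-validation, per-landmark
Harrell c-index under administrative censoring of competing events,
Brier score, Aalen–Johansen calibration, Wald-χ² and permutation
importance heatmaps, and alert lead-time analysis.

## Worked example

```r
library(icualert)

cfg    <- generator_config(n_admissions = 300, seed = 2024)
cohort <- simulate_cohort(cfg, include_vitals = FALSE)
summarize_incidence(cohort)
#> Synthetic ICU cohort incidence summary
#>   admissions:                300
#>   at-risk patient-days:      2052.8
#>   infection onsets:          82
#>   daily incidence:           3.99% (95% CI 3.18-4.96, exact Poisson (person-time offset))
#>   admissions ever infected:  21.3%
#>   median first onset (day):  7.4
#>   median recurrent onset:    18.3
#>   patients with recurrence:  5.7%

cv <- cross_validate(cohort, k = 5, seed = 1)
cv$metrics$base$global$c_index
#>      mean        lo        hi
#> 0.8619... 0.8446... 0.8792...

alert_analysis(cv$oof, cohort$timelines, threshold = 0.10)[
  c("fraction_above", "lead_median_h")]
#> $fraction_above  [1] 0.1617...
#> $lead_median_h   [1] 29.90...
```

The 300-admission cohort shows a daily ICU-AI incidence of 4.0% and
21.3% of admissions ever infected (small-sample wobble around the
calibration targets of 3.5% and 18.8%). Out-of-fold discrimination of
the base supermodel is c = 0.86 — high because the synthetic pre-onset
drifts are strong and clean. The strongest infection-cause predictors
recovered by Wald χ² are exactly the generator's drifting channels
(platelets, HR 0.96 per unit; CRP, HR 1.05 per mg/L; temperature, HR
3.7 per °C), and a 10% risk threshold alerts on 16% of predictions with
a median 30 h lead before onset.

The deep branch needs vital streams (`include_vitals = TRUE`,
`use_cnn = TRUE` in `cross_validate()`); `run_full(run_config(...), dir)`
executes the whole flow — simulate, build landmarks, per-fold CNN +
supermodels, metrics, manifest — and `inst/cli/icualert.R` exposes
`run | simulate | build | fit` subcommands for shell use.

## Layout

- `R/` — generator, landmark builder, CNN wrapper, supermodel, metrics,
  pipeline; `src/` — the CNN and concordance kernels (RcppArmadillo).
- `vignettes/icualert-methods.Rmd` — the models, their assumptions, all
  tunable parameters and the design decisions, including what the
  synthetic cohort does and does not emulate.
- `inst/extdata/file_schemas.json` — column documentation for every
  delimited file the pipeline reads or writes.
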