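---
title: "Dynamic landmark prediction of ICU-acquired infection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic landmark prediction of ICU-acquired infection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icualert)
```

# The prediction problem

ICU-acquired infection (ICU-AI) is an infection whose onset occurs more
than 48 hours after ICU presentation. `icualert` implements a dynamic
prediction pipeline for ICU-AI: at scheduled *landmark* times
$t_{LM}$ placed every 8 hours along an ICU stay, the model estimates the
absolute risk that an infection begins within the next $w$ hours
($w = 48$ by default, 24 as a sensitivity setting), using only
information observed up to $t_{LM}$. Death and ICU discharge compete
with infection: a patient who dies or leaves the ICU inside the window
can no longer develop ICU-AI there, so all risk statements are
cumulative incidences in the competing-risks sense, never naive
one-minus-survival quantities.

Three timing rules shape the data. Data from the first 24 h of stay are
discarded (run-in), and the first landmark sits at 48 h, so that every
prediction instance has at least 24 h of observed history and the
outcome is ICU-acquired by definition. After every onset, the following
48 h are blacked out: nothing observed there is used, no new onset is
defined there, and when the patient is still in the ICU at the end of
the blackout a *reset* series starts, treated as an independent
event-free period with its own landmark clock.

# The landmark supermodel

For each cause $k \in \{\text{infection}, \text{death},
\text{discharge}\}$ a cause-specific Cox model is fitted on *window
time* $u \in (0, w]$, the time since the landmark, with the competing
causes censored at their event times and Efron tie handling. All
landmark rows are stacked into one dataset and fitted jointly (a
landmark supermodel), with rows of one patient across landmarks treated
as independent partial-likelihood contributions; patient-clustered
robust standard errors are available behind the `robust` flag but are
off in the default preset.

Landmark time enters in one of two ways, and the package ships both
because they resolve an identifiability tension differently:

* **pooled** (default): one Breslow baseline per cause, with the
  landmark day $s = t_{LM}/24$ (centered at the stacked mean, to
  decorrelate it from its square) and $s^2$ as covariates of every
  cause. This is the classical supermodel form and yields risk curves
  that vary smoothly across landmarks.
* **stratified**: one baseline per landmark level, with $s, s^2$
  dropped from the design — inside a stratum they are constants and
  cannot be identified alongside a stratum-specific baseline.

Predictions combine the three fits through the discrete product
integral. With Breslow increments $\Delta\Lambda_k(u_j \mid x) =
\Delta\Lambda_{0k}(u_j)\, e^{x^\top \beta_k}$ on the pooled event-time
grid,

$$ S(u_j) = \prod_{u_i \le u_j} \Bigl(1 - \sum_k \Delta\Lambda_k(u_i
\mid x)\Bigr), \qquad \widehat F_{\text{inf}}(w \mid x) = \sum_{u_j \le
w} S(u_j^-)\, \Delta\Lambda_{\text{inf}}(u_j \mid x). $$

This form makes $\sum_k \widehat F_k(w) + S(w) = 1$ an exact identity,
which the tests assert to $10^{-10}$; a step whose all-cause increment
exceeds one (possible for covariates far outside the training bulk) is
scaled back so the product integral remains a probability, and such
rows are flagged `outside_support` rather than rejected. Against the
closed-form competing-exponential solution $F(w) =
\lambda_{\text{inf}}/\lambda_{\text{tot}}\,(1 -
e^{-\lambda_{\text{tot}} w})$ the discretised prediction agrees to
better than $10^{-3}$ at a 0.05 h baseline step.

Covariates are last-observation-carried-forward within a 24 h lookback
(the daily cadence of labs makes older values stale); a value absent
from the whole lookback is flagged and filled with the training-fold
median. No predictor reduction is performed. Covariates are centered
internally, so adding a constant to a covariate changes neither
coefficients nor predictions (tested).

# The CNN vital-sign score

The deep branch summarises the five 1-minute vital-sign channels (heart
rate, mean arterial pressure, pulse pressure, respiratory rate,
SpO$_2$) over the window ending at the landmark into one probability of
infection within $w$. The network is five blocks of three hidden layers
each — same-padding 1-D convolution with ReLU, max-pooling, dropout —
followed by flattening and a dense sigmoid head. It is implemented in
RcppArmadillo inside this package (forward and backward passes,
class-weighted binary cross-entropy, Adam, early stopping on a
validation split), with one `std::mt19937` stream seeded from R so that
training is bit-reproducible.

Choices the data cannot dictate, made once:

* **Input window**: 480 minutes (the inter-landmark spacing) at 1-minute
  resolution by default. A `downsample` option block-averages minutes
  before the network; the test presets use shorter, downsampled windows
  so the suite trains in seconds on one CPU core.
* **Gap handling** at extraction: gaps of at most 5 minutes are linearly
  interpolated, longer gaps carried forward, leading gaps filled with
  the within-window channel median; the original gap mask is preserved.
* **Class imbalance** by class weighting rather than resampling, which
  preserves the ranking behaviour of the score.
* **Hyperparameter selection** by mean validation AUC over 5
  patient-grouped folds, ties broken by grid order; the selected
  configuration is refitted on all training data.

Channel standardisation constants are computed on training data only
and stored in the model; scoring never uses statistics of the scored
data. The score then enters the infection-cause design as one extra
covariate (the *deep* model), so the base/deep comparison is nested
with one degree of freedom and the likelihood-ratio test applies.

# Evaluation

Everything is evaluated by repeated patient-grouped 5-fold
cross-validation: imputation constants, CNN weights and Cox
coefficients are fitted per fold on training patients only, and all
reported metrics are computed on out-of-fold predictions. Summaries are
the mean over folds with a normal-approximation 95% interval.

* **Discrimination**: Harrell's c-index after administrative censoring
  of competing events — a patient who dies or is discharged inside the
  window counts as infection-free through the whole window (censored at
  the horizon). The alternative reading (censoring competing events at
  their event time) is available behind a switch. The pair-counting
  kernel is exact and is tested against exhaustive enumeration.
* **Accuracy**: the Brier score against the binary
  infection-within-window indicator, competing and censored rows
  counting zero. Treating competing events as non-events (rather than
  excluding them) is the default; both alternatives of that open choice
  are switchable.
* **Calibration**: deciles of predicted risk against the Aalen–Johansen
  cumulative incidence of infection at the horizon within each decile;
  slope and intercept from bin-size-weighted least squares on the
  probability scale. When predictions equal the data-generating risks
  the slope is 1 and the intercept 0 within Monte-Carlo error (tested
  at $n = 10{,}000$); predictions doubled on the probability scale give
  slope near one half.
* **Importance**: per-landmark Wald $\chi^2$ rankings from
  landmark-specific infection-cause fits, and a permutation $\Delta c$
  — the mean drop in out-of-fold c-index when one covariate is permuted
  across rows and re-predicted with each fold's own model (20 seeded
  permutations by default). Permutation was chosen over refit-without
  because the refit variant costs a full model per covariate per
  landmark per fold and answers a different question.
* **Alerts**: the fraction of predictions above a 10% risk threshold,
  and per first infection the lead time from the first alerting
  landmark (strictly before onset, initial series) to onset, summarised
  as median and IQR.

# The synthetic cohort generator

No individual-level ICU data ship with the package; the generator is a
first-class, tested component that emulates the statistical structure
the analysis assumes, calibrated so that a large simulated cohort
reproduces published incidence statistics of a mixed tertiary-ICU
population: a near-constant cause-specific infection hazard of 3.5% per
at-risk day, 18.8% of admissions with at least one ICU-AI, a median
first onset near day 7, recurrent onsets near day 14.5, and 4.4% of
patients with recurrence.

Events follow competing exponential cause-specific hazards,
piecewise-constant over regimes: all hazards zero before 48 h (the
ICU-stay > 48 h inclusion criterion holds by construction), infection
suppressed during each post-onset blackout, and terminal hazards
switched to post-infection levels (discharge $\times$ 0.40, death
$\times$ 1.2) after a first onset, reflecting the longer stays and
higher mortality of infected patients. A per-patient log-normal frailty
multiplies the terminal hazards only. Two calibration facts drove the
defaults and deserve a note:

* A constant 3.5%/day infection hazard with a homogeneous terminal
  hazard cannot put the median first onset at day 7 while only 18.8% of
  admissions ever get infected — the implied length-of-stay decay is
  too fast. Heavy between-patient heterogeneity resolves this:
  `frailty_sigma = 1.3` makes infections concentrate in long-staying,
  low-terminal-hazard patients, moving the conditional onset median
  late without inflating the cumulative incidence.
* Pure log-normal frailty creates a tail of near-immortal stayers whose
  recurrent infections cluster around day 27, far beyond the day-14.5
  statistic. Administrative truncation of follow-up at 22 days bounds
  the recurrence distribution where the target statistics live (the
  landmark analysis itself concerns roughly the first ten ICU days); a
  frailty floor was tried instead and rejected because it pulled the
  first-onset median down.

The clinical series (CRP, temperature, WBC, platelets, creatinine,
FiO$_2$, SOFA on an 8-h grid; labs observed once daily) drift before
each onset — CRP +80 mg/L over 48 h, temperature +1.2 °C over 24 h,
platelets −30% over 72 h — mirroring the classical early signs of
infection. Vital signs are baseline + 24-h circadian sinusoid + AR(1)
noise at 1-minute resolution, with a linear pre-onset deterioration
ramp (HR +15 bpm, RR +6/min, MAP −10 mmHg, PP −5 mmHg, SpO$_2$ −2%
over the final 24 h, with ±30% patient-level amplitude jitter) and 5%
of minutes dropped at random. These signal models are synthetic
stand-ins: no published waveform model underlies them, and they are
deliberately simple.

What passing tests therefore show — and what they do not: the pipeline
recovers known hazards, closed-form incidences, constructed signatures
and self-consistent calibration under the generator's assumptions
(exponential regimes, monotone pre-onset drifts, stationary noise).
Real vital-sign streams have artifacts, nonstationarity, informative
missingness and intervention feedback that the generator does not
emulate, so performance figures obtained on synthetic cohorts
characterise the software, not clinical utility.

# Numerical choices and degenerate inputs

* Event-time ties are handled by Efron's correction (the 8-h grid plus
  hour-scale event times makes ties routine); tie-free fits agree with
  direct numerical maximisation of the hand-coded partial likelihood to
  $10^{-6}$.
* On exact within-window ties between event types, infection takes
  precedence over death over discharge (the outcome of interest wins;
  its reference time is the start of therapy).
* A landmark falling exactly on a segment end contributes no row — the
  patient is no longer at risk there.
* Reset series anchor their landmark clock at the blackout end rather
  than re-aligning to the admission-wide 8-h grid; both the anchoring
  and an extra observation delay before the first reset landmark are
  configurable, since the convention is genuinely open.
* Empty cohorts, single-class labels, zero-event causes, constant
  covariates and singular designs produce explicit errors or flagged
  degenerate summaries, never silent results.
* Derived seeds: every stage hashes the master seed with a stage label,
  so adding a stage never shifts another stage's random stream; all
  derived seeds stay below $2^{31}$.

# Problem sizes in the shipped tests

The test suite and the reproduction script choose sizes that make
Monte-Carlo error small relative to each tolerance while training
networks and fitting supermodels in seconds to a few minutes on one
core: 5,000 admissions for the incidence calibration (binomial
half-widths well inside the ±10% bands), 20,000 event-only timelines
for hazard-fidelity checks (half-width < 0.002/day), 2,000 windows for
the CNN signal-capture check, 200 replicates of 2,000 rows for
coefficient recovery and coverage, 10 seeds for the directional
deep-vs-base and 24-vs-48-h comparisons. CNN presets in tests use
shorter, downsampled windows (e.g. 240 min averaged to 48 samples) and
narrow filter banks; the package default remains the full 480-minute,
1-minute-resolution preset.

# Known limitations

* The generator models no microbiology, no antibiotic exposure, no
  adjudication uncertainty, and its covariate set approximates — not
  reproduces — the full predictor list of a production model.
* Cohort-dependent performance statistics (c-index, Brier, calibration
  slopes of a real ICU population) are not reproduction targets of this
  package; the tests assert property-based analogues instead
  (directional improvements, null calibrations, oracle equalities).
* The two-dimensional CNN variant and external-validation tooling are
  out of scope.
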