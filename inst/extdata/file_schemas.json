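{
  "admissions.csv": {
    "description": "One row per ICU admission; static covariates sampled at admission.",
    "columns": {
      "patient_id": "patient identifier (groups admissions and folds)",
      "admission_id": "admission identifier (unique)",
      "age": "years",
      "male": "0/1",
      "surgical": "surgical admission, 0/1",
      "prior_icu": "previously admitted to ICU, 0/1",
      "sepsis_admission": "sepsis at ICU admission, 0/1",
      "diabetes": "0/1",
      "immunodeficiency": "0/1",
      "malignancy": "0/1",
      "cardiovascular_insuff": "chronic cardiovascular insufficiency, 0/1",
      "renal_insuff": "chronic renal insufficiency, 0/1",
      "respiratory_insuff": "chronic respiratory insufficiency, 0/1",
      "apache_iv": "APACHE-IV score, points (>= 0)",
      "sofa": "SOFA score at admission, points (0-24)"
    }
  },
  "events.csv": {
    "description": "Event timeline per admission; times in hours from ICU admission.",
    "columns": {
      "admission_id": "admission identifier",
      "onset_times_h": "semicolon-delimited ICU-AI onset times (hours); empty when none",
      "terminal_event": "death | discharge | administrative",
      "terminal_time_h": "time of the terminal event (hours, > 48 by inclusion)"
    }
  },
  "clinical.csv": {
    "description": "8-hourly clinical series in long format; missing entries are omitted (labs are observed once daily).",
    "columns": {
      "admission_id": "admission identifier",
      "time_h": "grid time (hours, multiples of 8)",
      "channel": "crp (mg/L) | temperature (degC) | wbc (1e9/L) | platelets (1e9/L) | creatinine (umol/L) | fio2 (fraction) | sofa (points)",
      "value": "measured value"
    }
  },
  "vitals.csv": {
    "description": "1-minute vital signs in long format; dropped minutes are omitted (gaps are marked, never interpolated at generation time).",
    "columns": {
      "admission_id": "admission identifier",
      "minute": "minutes since ICU admission (0-based)",
      "channel": "hr (bpm) | map (mmHg) | pp (mmHg) | rr (/min) | spo2 (%)",
      "value": "measured value"
    }
  },
  "stacked.csv": {
    "description": "Stacked landmark dataset: one row per (admission, series, landmark). The sidecar stacked.csv.meta.json records the landmark grid, covariate spec and s-centering constant.",
    "columns": {
      "admission_id": "admission identifier",
      "patient_id": "patient identifier",
      "series_id": "0 = initial at-risk series, k = series after the k-th onset",
      "t_lm": "landmark time (hours)",
      "s": "landmark time in days, centered at the stacked mean",
      "s2": "s squared",
      "<channel>": "last observation of the dynamic channel within the lookback window (NA when none)",
      "miss_<channel>": "TRUE when the channel value was unobserved in the lookback (imputed downstream)",
      "<static>": "static covariates copied from admissions.csv",
      "cnn_score": "CNN vital-sign risk score (when present)",
      "outcome_type": "infection | death | discharge | censored, first event in (t_lm, t_lm + horizon]",
      "outcome_time": "event (or censoring) time in hours since t_lm, in (0, horizon]"
    }
  },
  "scores.csv": {
    "description": "CNN risk scores keyed by landmark row.",
    "columns": {
      "admission_id": "admission identifier",
      "series_id": "at-risk series",
      "t_lm": "landmark time (hours)",
      "cnn_score": "predicted probability of infection within the window, (0, 1)"
    }
  },
  "predictions.csv": {
    "description": "Out-of-fold cumulative-incidence predictions of the cross-validation.",
    "columns": {
      "pred_base": "predicted 48-h (or 24-h) infection risk, base supermodel",
      "pred_deep": "predicted risk of the deep (CNN-augmented) supermodel; NA when the CNN is disabled",
      "repeat_": "cross-validation repetition",
      "fold": "out-of-fold assignment of the row's patient"
    }
  },
  "coefficients.csv": {
    "description": "Cause-specific Cox coefficients of the full-data supermodel refit.",
    "columns": {
      "cause": "infection | death | discharge",
      "covariate": "design column (centered internally)",
      "beta": "log hazard ratio",
      "se": "standard error",
      "hr": "hazard ratio with hr_lo/hr_hi = 95% Wald interval"
    }
  }
}
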