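#' Simulate a synthetic ICU cohort
#'
#' Generates admissions with static covariates, a marked event process of
#' recurrent ICU-acquired infection (ICU-AI) onsets with death and ICU
#' discharge as competing terminal events, 8-hourly clinical series that
#' drift before each onset (CRP rise, fever, falling platelets), and
#' 1-minute vital-sign streams carrying a pre-onset deterioration
#' signature. Time is measured in hours from ICU admission throughout.
#'
#' All hazards are zero during the first 48 h, so every simulated
#' admission satisfies the ICU-stay > 48 h inclusion criterion; infection
#' onsets are therefore always later than 48 h and consecutive onsets are
#' separated by more than the 48 h post-onset blackout during which no new
#' onset is defined.
#'
#' Clinical series and vital streams can be switched off when only the
#' event process is needed (for example when summarising incidence on a
#' large cohort); the event timelines are generated from admission-specific
#' random streams and are identical either way.
#'
#' @param config an [generator_config()] object.
#' @param include_clinical generate the 8-hourly clinical series.
#' @param include_vitals generate the 1-minute vital-sign streams (memory
#'   heavy for large cohorts).
#' @return A list of class `icu_cohort` with elements `admissions`
#'   (data.frame, one row per admission), `timelines` (list), `clinical`
#'   (list of data.frames or `NULL`), `vitals` (list or `NULL`), `truth`
#'   (data.frame of the latent per-admission hazards, for validation
#'   studies only) and `config`.
#' @examples
#' cfg <- generator_config(n_admissions = 20, seed = 42)
#' cohort <- simulate_cohort(cfg, include_vitals = FALSE)
#' summarize_incidence(cohort)$daily_rate_pct
#' @export
simulate_cohort <- function(config, include_clinical = TRUE,
                            include_vitals = TRUE) {
  validate_generator_config(config)
  n <- config$n_admissions

  admissions <- simulate_admissions(n, derive_seed(config$seed, "static"))

  tl_base <- derive_seed(config$seed, "timeline")
  cl_base <- derive_seed(config$seed, "clinical")
  vt_base <- derive_seed(config$seed, "vitals")

  timelines <- vector("list", n)
  truth <- data.frame(admission_id = admissions$admission_id,
                      frailty = NA_real_, lp_inf = NA_real_,
                      r_inf_h = NA_real_, r_disch_h = NA_real_,
                      r_death_h = NA_real_)
  for (i in seq_len(n)) {
    tl <- simulate_timeline(admissions[i, ], config, admission_seed(tl_base, i))
    timelines[[i]] <- tl$timeline
    truth$frailty[i] <- tl$frailty
    truth$lp_inf[i] <- tl$lp_inf
    truth$r_inf_h[i] <- tl$r_inf_h
    truth$r_disch_h[i] <- tl$r_disch_h
    truth$r_death_h[i] <- tl$r_death_h
  }

  clinical <- NULL
  if (include_clinical) {
    clinical <- lapply(seq_len(n), function(i) {
      simulate_clinical_series(timelines[[i]], config, admission_seed(cl_base, i))
    })
  }
  vitals <- NULL
  if (include_vitals) {
    vitals <- lapply(seq_len(n), function(i) {
      simulate_vital_stream(timelines[[i]], config, admission_seed(vt_base, i))
    })
  }

  structure(list(admissions = admissions, timelines = timelines,
                 clinical = clinical, vitals = vitals, truth = truth,
                 config = config),
            class = "icu_cohort")
}

admission_seed <- function(base, i) {
  as.integer((as.double(base) + as.double(i) * 7919) %% 2147483646 + 1)
}

## static covariates drawn from marginals typical of a mixed tertiary ICU
simulate_admissions <- function(n, seed) {
  set.seed(seed)
  m <- .static_covariate_means
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    admission_id = sprintf("A%05d", seq_len(n)),
    age = pmin(95, pmax(18, round(stats::rnorm(n, m[["age"]], 15)))),
    male = stats::rbinom(n, 1, m[["male"]]),
    surgical = stats::rbinom(n, 1, m[["surgical"]]),
    prior_icu = stats::rbinom(n, 1, m[["prior_icu"]]),
    sepsis_admission = stats::rbinom(n, 1, m[["sepsis_admission"]]),
    diabetes = stats::rbinom(n, 1, m[["diabetes"]]),
    immunodeficiency = stats::rbinom(n, 1, m[["immunodeficiency"]]),
    malignancy = stats::rbinom(n, 1, m[["malignancy"]]),
    cardiovascular_insuff = stats::rbinom(n, 1, m[["cardiovascular_insuff"]]),
    renal_insuff = stats::rbinom(n, 1, m[["renal_insuff"]]),
    respiratory_insuff = stats::rbinom(n, 1, m[["respiratory_insuff"]]),
    apache_iv = pmax(10, round(stats::rnorm(n, m[["apache_iv"]], 28))),
    sofa = pmin(24, pmax(0, round(stats::rnorm(n, m[["sofa"]], 3.2)))),
    stringsAsFactors = FALSE
  )
}

## competing exponential event process, piecewise-constant over regimes
simulate_timeline <- function(adm, config, seed) {
  set.seed(seed)
  frailty <- exp(stats::rnorm(1, 0, config$frailty_sigma))
  lp <- 0
  if (length(config$beta_inf)) {
    x <- unlist(adm[names(config$beta_inf)])
    lp <- sum(config$beta_inf * (x - .static_covariate_means[names(config$beta_inf)]))
  }
  r_inf <- config$lambda_inf / 24 * exp(lp)
  r_disch <- config$lambda_disch / 24 * frailty
  r_death <- config$lambda_death / 24 * frailty

  max_t <- config$max_followup_days * 24
  t <- 48
  onsets <- numeric(0)
  infected <- FALSE
  blackout_end <- -Inf
  terminal_event <- "administrative"
  terminal_time <- max_t

  repeat {
    rd <- if (infected) r_disch * config$post_infection_disch_factor else r_disch
    rm <- if (infected) r_death * config$post_infection_death_factor else r_death
    in_blackout <- t < blackout_end
    ri <- if (in_blackout) 0 else r_inf
    boundary <- if (in_blackout) min(blackout_end, max_t) else max_t
    total <- ri + rd + rm
    if (total <= 0) {
      t <- boundary
    } else {
      dt <- stats::rexp(1, total)
      if (t + dt >= boundary) {
        t <- boundary
      } else {
        t <- t + dt
        u <- stats::runif(1) * total
        if (u < ri) {
          onsets <- c(onsets, t)
          infected <- TRUE
          blackout_end <- t + 48
          next
        } else if (u < ri + rd) {
          terminal_event <- "discharge"; terminal_time <- t
          break
        } else {
          terminal_event <- "death"; terminal_time <- t
          break
        }
      }
    }
    if (t >= max_t) { terminal_event <- "administrative"; terminal_time <- max_t; break }
  }

  list(timeline = list(admission_id = adm$admission_id,
                       infection_onsets = onsets,
                       terminal_event = terminal_event,
                       terminal_time = terminal_time),
       frailty = frailty, lp_inf = lp, r_inf_h = r_inf,
       r_disch_h = r_disch, r_death_h = r_death)
}

## additive ramp toward each onset, exponential washout afterwards
drift_profile <- function(times_h, onsets, lead_h) {
  prof <- numeric(length(times_h))
  for (on in onsets) {
    pre <- times_h <= on & times_h >= on - lead_h
    prof[pre] <- pmax(prof[pre], 1 - (on - times_h[pre]) / lead_h)
    post <- times_h > on
    prof[post] <- pmax(prof[post], exp(-(times_h[post] - on) / 24))
  }
  prof
}

simulate_clinical_series <- function(timeline, config, seed) {
  set.seed(seed)
  grid <- seq(0, timeline$terminal_time - 1e-9, by = 8)
  ng <- length(grid)
  out <- data.frame(admission_id = rep(timeline$admission_id, ng),
                    time_h = grid)
  phi <- 0.8
  for (ch in names(.clinical_baselines)) {
    base <- .clinical_baselines[[ch]]
    sd_ch <- .clinical_noise_sd[[ch]]
    noise <- as.numeric(stats::filter(stats::rnorm(ng, 0, sd_ch * sqrt(1 - phi^2)),
                                      phi, method = "recursive"))
    val <- base + noise
    drift <- config$covariate_drift[[ch]]
    if (!is.null(drift)) {
      prof <- drift_profile(grid, timeline$infection_onsets, drift$lead_h)
      if (isTRUE(drift$relative)) {
        val <- val * (1 + drift$delta * prof)
      } else {
        val <- val + drift$delta * prof
      }
    }
    rng <- .clinical_ranges[[ch]]
    val <- pmin(rng[2], pmax(rng[1], val))
    if (ch == "sofa") val <- round(val)
    if (ch %in% .daily_channels) {
      val[grid %% 24 != 0] <- NA_real_  # labs are drawn once daily
    }
    out[[ch]] <- val
  }
  out
}

simulate_vital_stream <- function(timeline, config, seed) {
  set.seed(seed)
  n_min <- max(1L, floor(timeline$terminal_time * 60))
  minute <- seq_len(n_min) - 1L
  t_h <- minute / 60
  channels <- names(.vital_baselines)
  values <- matrix(NA_real_, nrow = n_min, ncol = length(channels),
                   dimnames = list(NULL, channels))
  phase <- stats::runif(1, 0, 2 * pi)
  amp_jit <- stats::runif(length(channels), 1 - config$signature_jitter,
                          1 + config$signature_jitter)
  names(amp_jit) <- channels
  sig <- drift_profile(t_h, timeline$infection_onsets, config$signature_lead_h)
  phi <- 0.98
  for (ch in channels) {
    circ <- .vital_circadian_amp[[ch]] * sin(2 * pi * t_h / 24 + phase)
    sd_ch <- config$vital_noise_sd[[ch]]
    noise <- as.numeric(stats::filter(stats::rnorm(n_min, 0, sd_ch * sqrt(1 - phi^2)),
                                      phi, method = "recursive"))
    amp <- config$signature_amplitudes[[ch]] * amp_jit[[ch]]
    val <- .vital_baselines[[ch]] + circ + noise + amp * sig
    rng <- .vital_ranges[[ch]]
    values[, ch] <- pmin(rng[2], pmax(rng[1], val))
  }
  if (config$missingness_rate > 0) {
    drop <- matrix(stats::runif(n_min * length(channels)) < config$missingness_rate,
                   nrow = n_min)
    values[drop] <- NA_real_
  }
  list(admission_id = timeline$admission_id, minute = minute, values = values)
}

#' Summarise infection incidence in a simulated cohort
#'
#' Computes the at-risk patient-days (in the ICU, past 48 h, and outside
#' any 48-h post-onset blackout), the cause-specific daily incidence of
#' ICU-AI with an exact Poisson 95% confidence interval, the cumulative
#' percentage of admissions with at least one infection, the median ICU
#' day of first and of recurrent onsets, the percentage of patients with
#' recurrent infection, and a per-day event composition table.
#'
#' @param bundle an `icu_cohort` from [simulate_cohort()].
#' @return A list of class `icu_incidence_summary`.
#' @export
summarize_incidence <- function(bundle) {
  stopifnot(inherits(bundle, "icu_cohort"))
  tls <- bundle$timelines
  n <- length(tls)
  if (n == 0L) {
    return(structure(list(degenerate = TRUE, n_admissions = 0L,
                          patient_days_at_risk = 0, n_onsets = 0L,
                          daily_rate_pct = 0, daily_rate_ci_pct = c(0, 0),
                          cumulative_pct_infected = 0,
                          median_first_onset_day = NA_real_,
                          median_recurrent_onset_day = NA_real_,
                          pct_recurrence = 0, by_day = NULL,
                          ci_method = "exact Poisson"),
                     class = "icu_incidence_summary"))
  }
  at_risk_h <- 0
  n_onsets <- 0L
  first_days <- numeric(0)
  recur_days <- numeric(0)
  n_infected <- 0L
  n_recurrent <- 0L
  for (tl in tls) {
    on <- tl$infection_onsets
    term <- tl$terminal_time
    ## at-risk time: [48, term] minus blackouts (onset, onset + 48]
    seg_start <- 48
    for (o in on) {
      at_risk_h <- at_risk_h + (o - seg_start)
      seg_start <- min(o + 48, term)
    }
    at_risk_h <- at_risk_h + max(0, term - seg_start)
    n_onsets <- n_onsets + length(on)
    if (length(on) >= 1L) {
      n_infected <- n_infected + 1L
      first_days <- c(first_days, on[1] / 24)
    }
    if (length(on) >= 2L) {
      n_recurrent <- n_recurrent + 1L
      recur_days <- c(recur_days, on[-1] / 24)
    }
  }
  at_risk_days <- at_risk_h / 24
  rate <- if (at_risk_days > 0) n_onsets / at_risk_days else 0
  ci <- if (n_onsets > 0 && at_risk_days > 0) {
    as.numeric(stats::poisson.test(n_onsets, at_risk_days)$conf.int)
  } else c(0, 0)

  max_day <- ceiling(max(vapply(tls, function(t) t$terminal_time, 0)) / 24)
  by_day <- data.frame(day = seq_len(max_day), n_in_icu = 0L, n_onset = 0L,
                       n_death = 0L, n_discharge = 0L)
  for (tl in tls) {
    last_day <- ceiling(tl$terminal_time / 24)
    by_day$n_in_icu[seq_len(last_day)] <- by_day$n_in_icu[seq_len(last_day)] + 1L
    for (o in tl$infection_onsets) {
      d <- ceiling(o / 24)
      by_day$n_onset[d] <- by_day$n_onset[d] + 1L
    }
    if (tl$terminal_event %in% c("death", "discharge")) {
      col <- paste0("n_", tl$terminal_event)
      by_day[[col]][last_day] <- by_day[[col]][last_day] + 1L
    }
  }

  structure(list(
    degenerate = n_onsets == 0L && at_risk_days == 0,
    n_admissions = n,
    patient_days_at_risk = at_risk_days,
    n_onsets = n_onsets,
    daily_rate_pct = 100 * rate,
    daily_rate_ci_pct = 100 * ci,
    cumulative_pct_infected = 100 * n_infected / n,
    median_first_onset_day = median_or_na(first_days),
    median_recurrent_onset_day = median_or_na(recur_days),
    pct_recurrence = 100 * n_recurrent / n,
    by_day = by_day,
    ci_method = "exact Poisson (person-time offset)"
  ), class = "icu_incidence_summary")
}

#' @export
print.icu_incidence_summary <- function(x, ...) {
  cat("Synthetic ICU cohort incidence summary\n")
  cat(sprintf("  admissions:                %d\n", x$n_admissions))
  cat(sprintf("  at-risk patient-days:      %.1f\n", x$patient_days_at_risk))
  cat(sprintf("  infection onsets:          %d\n", x$n_onsets))
  cat(sprintf("  daily incidence:           %.2f%% (95%% CI %.2f-%.2f, %s)\n",
              x$daily_rate_pct, x$daily_rate_ci_pct[1], x$daily_rate_ci_pct[2],
              x$ci_method))
  cat(sprintf("  admissions ever infected:  %.1f%%\n", x$cumulative_pct_infected))
  cat(sprintf("  median first onset (day):  %.1f\n", x$median_first_onset_day))
  cat(sprintf("  median recurrent onset:    %.1f\n", x$median_recurrent_onset_day))
  cat(sprintf("  patients with recurrence:  %.1f%%\n", x$pct_recurrence))
  invisible(x)
}
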