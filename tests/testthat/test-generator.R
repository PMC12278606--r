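test_that("generator config validation rejects impossible settings", {
  expect_error(generator_config(n_admissions = 0), "positive")
  expect_error(generator_config(lambda_disch = 0, lambda_death = 0),
               "never terminate")
  expect_error(generator_config(missingness_rate = 1), "missingness_rate")
  expect_error(generator_config(frailty_sigma = -0.1), "frailty_sigma")
  expect_error(generator_config(lambda_inf = -1), "hazards")
  expect_error(generator_config(beta_inf = c(not_a_covariate = 1)),
               "unknown covariates")
})

test_that("removing the infection cause empties every timeline", {
  b <- simulate_cohort(generator_config(n_admissions = 40, seed = 1,
                                        lambda_inf = 0),
                       include_clinical = FALSE, include_vitals = FALSE)
  expect_true(all(lengths(lapply(b$timelines, `[[`, "infection_onsets")) == 0))
})

test_that("the seed fully determines the bundle; toggling series does not shift the event process", {
  cfg <- generator_config(n_admissions = 12, seed = 99)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  b3 <- simulate_cohort(cfg, include_clinical = FALSE,
                        include_vitals = FALSE)
  expect_identical(b1$timelines, b3$timelines)
  expect_identical(b1$admissions, b3$admissions)
})

test_that("event-process invariants hold across seeds: inclusion, blackout, ordering", {
  for (s in 1:3) {
    b <- simulate_cohort(generator_config(n_admissions = 300, seed = s),
                         include_clinical = FALSE, include_vitals = FALSE)
    for (tl in b$timelines) {
      expect_gt(tl$terminal_time, 48)
      if (length(tl$infection_onsets)) {
        expect_true(all(tl$infection_onsets > 48))
        expect_true(all(tl$infection_onsets < tl$terminal_time))
        if (length(tl$infection_onsets) > 1) {
          expect_true(all(diff(tl$infection_onsets) > 48))
        }
      }
    }
  }
})

test_that("with no frailty and constant hazards the empirical cause-specific rates converge", {
  cfg <- generator_config(n_admissions = 20000, seed = 123,
                          frailty_sigma = 0, beta_inf = numeric(0),
                          lambda_inf = 0.035, lambda_disch = 0.14,
                          lambda_death = 0.014)
  b <- simulate_cohort(cfg, include_clinical = FALSE,
                       include_vitals = FALSE)
  s <- summarize_incidence(b)
  ## Monte-Carlo half-width at this size is well under 0.002/day
  expect_lt(abs(s$daily_rate_pct / 100 - 0.035), 0.002)
  ## discharge hazard on pre-infection person-time (after an onset the
  ## discharge hazard is deliberately suppressed by the post-infection
  ## factor, so the crude all-time rate is not the right estimand)
  term <- vapply(b$timelines, `[[`, 0, "terminal_time")
  ev <- vapply(b$timelines, `[[`, "", "terminal_event")
  ninf <- lengths(lapply(b$timelines, `[[`, "infection_onsets"))
  pt0 <- sum(term[ninf == 0] - 48) / 24 +
    sum(vapply(b$timelines[ninf > 0],
               function(t) t$infection_onsets[1] - 48, 0)) / 24
  expect_lt(abs(sum(ev[ninf == 0] == "discharge") / pt0 - 0.14), 0.005)
})

test_that("vital streams carry the pre-onset deterioration signature", {
  cfg <- generator_config(n_admissions = 40, seed = 7,
                          vital_noise_sd = c(hr = 0, map = 0, pp = 0,
                                             rr = 0, spo2 = 0),
                          signature_jitter = 0, missingness_rate = 0)
  b <- simulate_cohort(cfg)
  lead <- cfg$signature_lead_h
  checked <- 0
  for (i in seq_along(b$timelines)) {
    tl <- b$timelines[[i]]
    if (!length(tl$infection_onsets)) next
    on <- tl$infection_onsets[1]
    if (on < 2 * lead + 48) next
    v <- b$vitals[[i]]
    in_sig <- v$minute / 60 >= on - lead & v$minute / 60 < on
    in_base <- v$minute / 60 >= on - 2 * lead & v$minute / 60 < on - lead
    diff_hr <- mean(v$values[in_sig, "hr"]) - mean(v$values[in_base, "hr"])
    ## linear ramp to +15 bpm at onset: mean elevation is half the amplitude
    expect_lt(abs(diff_hr - 15 / 2), 0.75)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("incidence summary matches hand enumeration on a built bundle", {
  tls <- list(
    list(admission_id = "A1", infection_onsets = numeric(0),
         terminal_event = "discharge", terminal_time = 240),
    list(admission_id = "A2", infection_onsets = 120,
         terminal_event = "discharge", terminal_time = 240),
    list(admission_id = "A3", infection_onsets = numeric(0),
         terminal_event = "discharge", terminal_time = 240))
  s <- summarize_incidence(bundle_from_timelines(tls))
  ## at-risk: 2 x (240-48)/24 + ((120-48) + (240-168))/24 = 8 + 8 + 6 = 22 d
  expect_equal(s$patient_days_at_risk, 22)
  expect_equal(s$n_onsets, 1L)
  expect_equal(s$daily_rate_pct, 100 / 22)
  expect_equal(s$cumulative_pct_infected, 100 / 3)
  expect_equal(s$median_first_onset_day, 5)
  expect_equal(s$pct_recurrence, 0)
  expect_true(is.na(s$median_recurrent_onset_day))
  expect_equal(s$by_day$n_onset[5], 1L)
  expect_equal(s$by_day$n_in_icu[1], 3L)
  expect_equal(s$by_day$n_discharge[10], 3L)
})

test_that("degenerate bundles are flagged instead of failing", {
  s0 <- summarize_incidence(bundle_from_timelines(list()))
  expect_true(s0$degenerate)
  expect_equal(s0$cumulative_pct_infected, 0)
})

test_that("static covariates respect their ranges and ids are unique", {
  b <- simulate_cohort(generator_config(n_admissions = 500, seed = 11),
                       include_clinical = FALSE, include_vitals = FALSE)
  a <- b$admissions
  expect_false(anyDuplicated(a$admission_id) > 0)
  expect_true(all(a$sofa >= 0 & a$sofa <= 24))
  expect_true(all(a$apache_iv >= 0))
  expect_true(all(a$age >= 18 & a$age <= 95))
})

test_that("clinical series sit on the 8-h grid within physiologic ranges", {
  b <- simulate_cohort(generator_config(n_admissions = 30, seed = 2),
                       include_vitals = FALSE)
  for (cl in b$clinical[1:5]) {
    expect_true(all(diff(cl$time_h) == 8))
    expect_true(all(cl$temperature >= 30 & cl$temperature <= 43,
                    na.rm = TRUE))
    expect_true(all(cl$fio2 >= 0.21 & cl$fio2 <= 1, na.rm = TRUE))
  }
  v <- b <- NULL
})

test_that("vital streams respect ranges and mark gaps as missing", {
  b <- simulate_cohort(generator_config(n_admissions = 5, seed = 3,
                                        missingness_rate = 0.2))
  v <- b$vitals[[1]]
  expect_true(all(v$values[, "spo2"] >= 50 & v$values[, "spo2"] <= 100,
                  na.rm = TRUE))
  expect_true(all(v$values > 0, na.rm = TRUE))
  frac_na <- mean(is.na(v$values))
  expect_gt(frac_na, 0.1)
  expect_lt(frac_na, 0.3)
})
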