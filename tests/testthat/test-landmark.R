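grid48 <- landmark_grid()

test_that("at-risk segmentation handles onsets, blackouts and terminal events", {
  tl <- list(admission_id = "A1", infection_onsets = 120,
             terminal_event = "discharge", terminal_time = 200)
  segs <- segment_at_risk_periods(tl, grid48)
  expect_equal(segs$start_h, c(24, 168))
  expect_equal(segs$end_h, c(120, 200))
  expect_equal(segs$end_reason, c("infection", "discharge"))

  tl2 <- list(admission_id = "A2", infection_onsets = numeric(0),
              terminal_event = "death", terminal_time = 60)
  segs2 <- segment_at_risk_periods(tl2, grid48)
  expect_equal(nrow(segs2), 1L)
  expect_equal(c(segs2$start_h, segs2$end_h), c(24, 60))

  ## terminal event inside the blackout swallows the reset segment
  tl3 <- list(admission_id = "A3", infection_onsets = 100,
              terminal_event = "death", terminal_time = 130)
  segs3 <- segment_at_risk_periods(tl3, grid48)
  expect_equal(nrow(segs3), 1L)
  expect_equal(segs3$end_h, 100)

  expect_error(segment_at_risk_periods(
    list(admission_id = "X", infection_onsets = 90,
         terminal_event = "death", terminal_time = 80), grid48),
    "malformed")
})

test_that("landmark placement follows the 8-h grid and reset anchoring", {
  s0 <- list(series_id = 0L, start_h = 24, end_h = 120)
  expect_equal(place_landmarks(s0, grid48), seq(48, 112, by = 8))
  s1 <- list(series_id = 1L, start_h = 168, end_h = 200)
  expect_equal(place_landmarks(s1, grid48), c(168, 176, 184, 192))
  ## a landmark exactly at the segment end is dropped
  s2 <- list(series_id = 0L, start_h = 24, end_h = 48)
  expect_length(place_landmarks(s2, grid48), 0)
})

test_that("window labelling takes the first event with infection precedence on ties", {
  tl <- list(admission_id = "A1", infection_onsets = 120,
             terminal_event = "discharge", terminal_time = 200)
  expect_equal(label_window(112, tl, grid48),
               list(outcome_type = "infection", outcome_time = 8))
  expect_equal(label_window(48, tl, grid48),
               list(outcome_type = "censored", outcome_time = 48))
  expect_equal(label_window(192, tl, grid48),
               list(outcome_type = "discharge", outcome_time = 8))
  ## exact tie: infection onset at the terminal time of death
  tie <- list(admission_id = "T", infection_onsets = 100,
              terminal_event = "death", terminal_time = 100)
  expect_error(segment_at_risk_periods(tie, grid48), "malformed")
  ## inside the post-onset blackout: not at risk, no label defined
  expect_error(label_window(130, tl, grid48), "outside")
})

test_that("covariate assembly uses the most recent value within lookback", {
  clin <- data.frame(time_h = c(0, 102, 110),
                     crp = c(10, 120, NA), platelets = c(NA, NA, NA))
  out <- assemble_covariates(clin, 112, c("crp", "platelets"))
  expect_equal(unname(out$values["crp"]), 120)  # 102 within [88, 112]
  expect_true(is.na(out$values["platelets"]))
  expect_true(out$missing[["platelets"]])
  expect_false(out$missing[["crp"]])
  ## recency rule between two candidates
  clin2 <- data.frame(time_h = c(102, 110), crp = c(50, 70))
  expect_equal(unname(assemble_covariates(clin2, 112, "crp")$values), 70)
  ## values after the landmark never enter
  clin3 <- data.frame(time_h = c(100, 113), crp = c(60, 9999))
  expect_equal(unname(assemble_covariates(clin3, 112, "crp")$values), 60)
  expect_error(assemble_covariates(clin, 112, "unknown_channel"),
               "unknown channel")
})

test_that("the stacked dataset has one row per (segment, landmark) with correct counts", {
  tl <- list(admission_id = "A1", infection_onsets = 120,
             terminal_event = "discharge", terminal_time = 200)
  b <- bundle_from_timelines(list(tl))
  st <- build_stacked_dataset(b, grid48, channels = character(0),
                              static_covariates = character(0))
  expect_equal(nrow(st$rows), 13L)  # 9 initial-series + 4 reset landmarks
  expect_equal(sum(st$rows$series_id == 0), 9L)
  ## empty cohort keeps the covariate spec intact
  st0 <- build_stacked_dataset(bundle_from_timelines(list()), grid48,
                               channels = character(0),
                               static_covariates = character(0))
  expect_equal(nrow(st0$rows), 0L)
  expect_s3_class(st0, "stacked_dataset")
})

test_that("stacked rows never use covariates observed after the landmark", {
  b <- simulate_cohort(generator_config(n_admissions = 10, seed = 21),
                       include_vitals = FALSE)
  ## poison a future value: time 120 observation must not leak into t_lm 112
  poisoned <- b
  idx <- which(poisoned$clinical[[1]]$time_h == 120)
  poisoned$clinical[[1]]$temperature[idx] <- 9999
  st <- build_stacked_dataset(poisoned, grid48)
  r <- st$rows[st$rows$admission_id == b$timelines[[1]]$admission_id &
                 st$rows$t_lm <= 112, ]
  expect_true(all(r$temperature < 9999, na.rm = TRUE))
})

test_that("no landmark lies in a blackout and infection labels match onsets", {
  b <- simulate_cohort(generator_config(n_admissions = 100, seed = 31),
                       include_vitals = FALSE)
  st <- build_stacked_dataset(b, grid48)
  tmap <- stats::setNames(b$timelines,
                          vapply(b$timelines, `[[`, "", "admission_id"))
  in_blackout <- logical(nrow(st$rows))
  label_ok <- logical(nrow(st$rows))
  for (i in seq_len(nrow(st$rows))) {
    row <- st$rows[i, ]
    on <- tmap[[row$admission_id]]$infection_onsets
    ## blackout is the open interval: landmarking resumes exactly at
    ## onset + 48, so that boundary instant is a valid landmark
    in_blackout[i] <- any(row$t_lm > on & row$t_lm < on + 48)
    label_ok[i] <- row$outcome_type != "infection" ||
      any(on > row$t_lm & on <= row$t_lm + 48)
  }
  expect_false(any(in_blackout))
  expect_true(all(label_ok))
  cens <- st$rows$outcome_type == "censored"
  expect_true(all(st$rows$outcome_time[cens] == 48))
  expect_true(all(st$rows$outcome_time > 0 & st$rows$outcome_time <= 48))
  ## deterministic row count across rebuilds
  st2 <- build_stacked_dataset(b, grid48)
  expect_identical(st$rows, st2$rows)
})

test_that("landmark-time terms are centered and consistent", {
  b <- simulate_cohort(generator_config(n_admissions = 50, seed = 4),
                       include_vitals = FALSE)
  st <- build_stacked_dataset(b, grid48)
  expect_lt(abs(mean(st$rows$s)), 1e-10)
  expect_equal(st$rows$s2, st$rows$s^2)
  expect_equal(st$rows$s, st$rows$t_lm / 24 - st$covariate_spec$s_center)
})

test_that("imputation learns training medians and fills only missing entries", {
  train <- data.frame(crp = c(10, 20, NA, 40), wbc = c(NA, 5, 7, NA))
  state <- fit_imputation(train, c("crp", "wbc"))
  expect_equal(unname(state$medians), c(20, 6))
  test <- data.frame(crp = c(NA, 99), wbc = c(3, NA))
  filled <- apply_imputation(test, state)
  expect_equal(filled$crp, c(20, 99))
  expect_equal(filled$wbc, c(3, 6))
})
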