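test_that("fold plans balance patients and are reproducible", {
  pats <- sprintf("P%03d", 1:53)
  plan <- fold_plan(pats, k = 5, seed = 7)
  tab <- table(plan$fold)
  expect_lte(max(tab) - min(tab), 1L)
  expect_setequal(plan$patient_id, pats)
  plan2 <- fold_plan(sample(rep(pats, 3)), k = 5, seed = 7)
  m1 <- plan$fold[order(plan$patient_id)]
  m2 <- plan2$fold[order(plan2$patient_id)]
  expect_identical(m1, m2)  # row multiplicity does not change assignment
  expect_error(fold_plan(pats[1:3], k = 5), "fewer patients")
  plan_r <- fold_plan(pats, k = 5, repeats = 3, seed = 7)
  expect_length(plan_r$assignments, 3L)
})

test_that("concordance equals the exhaustive pairwise oracle", {
  ## hand-built: infections at u = 8 and 40, one discharge, one censored
  rows <- data.frame(
    outcome_type = c("infection", "infection", "discharge", "censored"),
    outcome_time = c(8, 40, 20, 48))
  pred <- c(0.9, 0.3, 0.5, 0.1)
  got <- harrell_c(pred, rows, horizon_h = 48)
  ## administrative censoring: discharge/censored -> (48, 0)
  oracle <- brute_force_c(c(8, 40, 48, 48), c(1L, 1L, 0L, 0L), pred)
  expect_equal(got$c_index, oracle)
  ## perfectly ordered predictions, no censoring
  r2 <- data.frame(outcome_type = rep("infection", 5),
                   outcome_time = 1:5)
  expect_equal(harrell_c(5:1 / 10, r2)$c_index, 1)
  ## random datasets against the oracle
  for (s in 1:10) {
    set.seed(s)
    n <- sample(20:150, 1)
    r <- data.frame(
      outcome_type = sample(c("infection", "death", "discharge", "censored"),
                            n, replace = TRUE, prob = c(0.3, 0.1, 0.3, 0.3)),
      outcome_time = sample(c(4, 8, 16, 24, 40, 48), n, replace = TRUE))
    r$outcome_time[r$outcome_type == "censored"] <- 48
    p <- round(runif(n), 2)  # force prediction ties
    ev <- as.integer(r$outcome_type == "infection")
    tm <- ifelse(ev == 1L, r$outcome_time, 48)
    expect_equal(harrell_c(p, r)$c_index, brute_force_c(tm, ev, p))
  }
  ## no comparable pairs
  r0 <- data.frame(outcome_type = c("censored", "censored"),
                   outcome_time = c(48, 48))
  expect_true(is.na(harrell_c(c(0.1, 0.2), r0)$c_index))
})

test_that("censoring competing events at the horizon differs from event-time censoring", {
  rows <- data.frame(outcome_type = c("infection", "discharge"),
                     outcome_time = c(30, 10))
  p <- c(0.2, 0.8)
  ## horizon mode: discharge survives the window as a comparable control
  expect_equal(harrell_c(p, rows, competing = "horizon")$c_index, 0)
  ## event-time mode: discharge censored before the infection, no pairs
  expect_true(is.na(harrell_c(p, rows, competing = "event_time")$c_index))
})

test_that("Brier score matches hand arithmetic and decomposes over landmarks", {
  rows <- data.frame(outcome_type = c("censored", "infection", "discharge"),
                     outcome_time = c(48, 10, 20))
  expect_equal(brier_score(c(0.2, 0.7, 0.1), rows),
               (0.04 + 0.09 + 0.01) / 3)
  expect_equal(brier_score(rep(0.5, 3), rows), 0.25)
  expect_equal(brier_score(c(0, 1, 0), rows), 0)
  ## pooled Brier = row-weighted mean of per-landmark Briers (identity)
  set.seed(4)
  n <- 200
  r <- data.frame(outcome_type = sample(c("infection", "censored"), n, TRUE),
                  outcome_time = 48, t_lm = sample(c(48, 56, 64), n, TRUE))
  p <- runif(n)
  pooled <- brier_score(p, r)
  by_lm <- vapply(unique(r$t_lm), function(l) {
    sel <- r$t_lm == l
    c(brier_score(p[sel], r[sel, ]), sum(sel))
  }, c(0, 0))
  expect_equal(pooled, sum(by_lm[1, ] * by_lm[2, ]) / n)
})

test_that("calibration recovers a two-point line exactly", {
  ## 20 rows at predicted 0.1 with 2 infections, 20 at 0.3 with 6
  rows <- data.frame(
    outcome_type = rep(c("infection", "censored", "infection", "censored"),
                       c(2, 18, 6, 14)),
    outcome_time = 48)
  rows$outcome_time[rows$outcome_type == "infection"] <- 24
  pred <- rep(c(0.1, 0.3), each = 20)
  cal <- calibration(pred, rows, n_bins = 2)
  expect_equal(cal$slope, 1, tolerance = 1e-10)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  ## constant predictions cannot be binned
  cal0 <- calibration(rep(0.2, 40), rows)
  expect_true(is.na(cal0$slope))
  expect_match(cal0$reason, "concentrated")
})

test_that("the Aalen-Johansen observed CIF respects competing events", {
  ## half the cohort discharged early: naive event fraction underestimates
  time <- c(rep(10, 50), rep(5, 50))
  ev <- factor(rep(c("infection", "discharge"), each = 50),
               levels = c("censored", "infection", "death", "discharge"))
  cif <- aj_cif(time, ev, 48)
  expect_equal(cif, 0.5)  # all infections occur among those still at risk
  expect_equal(aj_cif(rep(48, 10), factor(rep("censored", 10),
                                          levels = levels(ev)), 48), 0)
})

test_that("cross-validation is deterministic, covers every row once, and respects purity", {
  b <- simulate_cohort(generator_config(n_admissions = 120, seed = 22),
                       include_vitals = FALSE)
  cv1 <- cross_validate(b, k = 5, seed = 6)
  cv2 <- cross_validate(b, k = 5, seed = 6)
  expect_identical(cv1$oof, cv2$oof)
  st <- build_stacked_dataset(b)
  expect_equal(nrow(cv1$oof), nrow(st$rows))
  key_cv <- sort(paste(cv1$oof$admission_id, cv1$oof$series_id, cv1$oof$t_lm))
  key_st <- sort(paste(st$rows$admission_id, st$rows$series_id, st$rows$t_lm))
  expect_identical(key_cv, key_st)
  ## patients never appear in their own training folds
  for (fk in names(cv1$folds)) {
    f <- cv1$folds[[fk]]$fold
    amap <- cv1$plan$assignments[[1]]
    oof_pat <- unique(cv1$oof$patient_id[cv1$oof$fold == f])
    expect_true(all(amap$fold[match(oof_pat, amap$patient_id)] == f))
  }
  expect_true(all(is.finite(cv1$metrics$base$global$c_index)))
})

test_that("an informed predictor degrades monotonically with added noise", {
  b <- simulate_cohort(generator_config(n_admissions = 200, seed = 23),
                       include_clinical = FALSE, include_vitals = FALSE)
  st <- build_stacked_dataset(b, channels = character(0))
  rows <- st$rows
  truth <- b$truth
  base_risk <- truth$r_inf_h[match(rows$admission_id, truth$admission_id)]
  cs <- vapply(c(0, 0.5, 2), function(ns) {
    med <- vapply(1:5, function(s) {
      set.seed(s)
      p <- base_risk * exp(rnorm(length(base_risk), 0, ns))
      harrell_c(p, rows)$c_index
    }, 0)
    median(med)
  }, 0)
  expect_true(all(diff(cs) < 0))
})

test_that("permutation importance separates signal from noise covariates", {
  b <- simulate_cohort(generator_config(n_admissions = 150, seed = 24),
                       include_vitals = FALSE)
  cv <- cross_validate(b, k = 5, seed = 8,
                       channels = c("crp", "temperature", "platelets"),
                       static_covariates = c("age", "male"))
  imp <- importance_heatmaps(cv, n_perm = 5, seed = 2)
  drift <- c("crp", "temperature", "platelets")
  expect_true(names(which.max(imp$delta_c)) %in% drift)
  ## noise covariates barely move the c-index
  expect_lt(max(abs(imp$delta_c[c("age", "male")])), 0.02)
  ## each landmark's Wald column ranks all fitted covariates
  ok_rows <- rowSums(!is.na(imp$wald_rank)) > 0
  expect_true(any(ok_rows))
  for (i in which(ok_rows)[1:3]) {
    rk <- imp$wald_rank[i, !is.na(imp$wald_rank[i, ])]
    expect_setequal(rank(rk), seq_along(rk))
  }
})

test_that("alert analysis computes lead times from the first alert before onset", {
  tl <- list(admission_id = "A1", infection_onsets = 120,
             terminal_event = "discharge", terminal_time = 300)
  oof <- data.frame(admission_id = "A1", series_id = 0L,
                    t_lm = c(48, 56, 64, 72),
                    pred_base = c(0.02, 0.15, 0.2, 0.05))
  rep1 <- alert_analysis(oof, list(tl), threshold = 0.10)
  expect_equal(rep1$lead_median_h, 120 - 56)
  expect_equal(rep1$fraction_above, 0.5)
  expect_equal(rep1$fraction_alerted, 1)
  ## threshold 1: nothing alerts
  rep2 <- alert_analysis(oof, list(tl), threshold = 1)
  expect_equal(rep2$fraction_above, 0)
  expect_equal(rep2$n_alerted, 0L)
  ## threshold 0: every prediction alerts, lead from the first landmark
  rep3 <- alert_analysis(oof, list(tl), threshold = 0)
  expect_equal(rep3$fraction_above, 1)
  expect_equal(rep3$lead_median_h, 120 - 48)
  expect_error(alert_analysis(oof, list(tl), threshold = 1.2), "threshold")
})
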