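test_that("coefficients match direct maximisation of the hand-coded partial likelihood", {
  for (s in 1:3) {
    set.seed(s)
    n <- 40
    X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
    d <- data.frame(outcome_time = rexp(n, 0.05 * exp(0.4 * X[, 1])),
                    outcome_type = ifelse(runif(n) < 0.75, "infection",
                                          "censored"),
                    X)
    fit <- fit_cause_specific(d, "infection",
                              covariate_spec(c("x1", "x2"),
                                             landmark_terms = FALSE))
    oracle <- cox_pl_oracle(d$outcome_time,
                            as.integer(d$outcome_type == "infection"), X)
    expect_lt(max(abs(fit$coef - oracle)), 1e-6)
  }
})

test_that("duplicating every row leaves coefficients stable and halves the variance", {
  d <- gen_exp_ph(150, beta = 0.5, seed = 9)
  sp <- covariate_spec("x", landmark_terms = FALSE)
  f1 <- fit_cause_specific(d, "infection", sp)
  f2 <- fit_cause_specific(rbind(d, d), "infection", sp)
  expect_lt(max(abs(f1$coef - f2$coef)), 0.02)  # Efron ties on duplicates
  expect_equal(unname(diag(f2$vcov) / diag(f1$vcov)), 0.5, tolerance = 0.01)
})

test_that("a covariate permuted against outcomes is rarely significant", {
  rej <- vapply(1:100, function(s) {
    d <- gen_exp_ph(300, beta = 0.8, seed = 1000 + s)
    set.seed(s)
    d$x <- sample(d$x)
    f <- fit_cause_specific(d, "infection",
                            covariate_spec("x", landmark_terms = FALSE))
    unname(wald_chi2(f) > qchisq(0.95, 1))
  }, TRUE)
  expect_lt(mean(rej), 0.12)  # nominal 5% type-I error
})

test_that("fit errors are explicit: zero events, NA, constant covariate, missing columns", {
  d <- gen_exp_ph(50, seed = 2)
  sp <- covariate_spec("x", landmark_terms = FALSE)
  d0 <- d; d0$outcome_type <- "censored"
  expect_error(fit_cause_specific(d0, "infection", sp), "no events")
  dc <- d; dc$x <- 1
  expect_error(fit_cause_specific(dc, "infection", sp), "constant")
  dn <- d; dn$x[1] <- NA
  expect_error(fit_cause_specific(dn, "infection", sp), "missing values")
  expect_error(fit_cause_specific(d, "infection",
                                  covariate_spec("nope", landmark_terms = FALSE)),
               "absent")
})

test_that("CIF predictions reduce to closed forms in degenerate settings", {
  ## all hazards zero
  m0 <- supermodel_from_constant_hazards(0, 0, 0)
  p0 <- predict_cif(m0, data.frame(dummy = 1))
  expect_equal(p0$f_inf, 0)
  expect_equal(p0$surv, 1)
  ## single cause: 1 - exp(-Lambda)
  m1 <- supermodel_from_constant_hazards(0.01, 0, 0, step_h = 0.05)
  p1 <- predict_cif(m1, data.frame(dummy = 1))
  expect_equal(p1$f_inf, 1 - exp(-0.01 * 48), tolerance = 1e-3)
  ## monotone in the horizon
  m <- supermodel_from_constant_hazards(0.01, 0.01, 0.01)
  f24 <- predict_cif(m, data.frame(dummy = 1), horizon_h = 24)$f_inf
  f48 <- predict_cif(m, data.frame(dummy = 1), horizon_h = 48)$f_inf
  expect_gt(f48, f24)
})

test_that("CIFs of the three causes and residual survival always sum to one", {
  b <- simulate_cohort(generator_config(n_admissions = 80, seed = 14),
                       include_vitals = FALSE)
  st <- build_stacked_dataset(b)
  rows <- apply_imputation(st$rows,
                           fit_imputation(st$rows, st$covariate_spec$dynamic))
  sm <- fit_supermodel(rows, covariate_spec(c("age", "crp", "temperature")),
                       horizon_h = 48)
  p <- predict_cif(sm, rows)
  expect_lt(max(abs(p$f_inf + p$f_death + p$f_discharge + p$surv - 1)),
            1e-10)
  expect_true(all(p$f_inf >= 0 & p$f_inf <= 1))
})

test_that("adding a constant to a covariate changes neither coefficients nor predictions", {
  b <- simulate_cohort(generator_config(n_admissions = 60, seed = 15),
                       include_vitals = FALSE)
  st <- build_stacked_dataset(b)
  rows <- apply_imputation(st$rows,
                           fit_imputation(st$rows, st$covariate_spec$dynamic))
  sp <- covariate_spec(c("age", "crp"))
  sm1 <- fit_supermodel(rows, sp, horizon_h = 48)
  rows2 <- rows; rows2$crp <- rows2$crp + 1000
  sm2 <- fit_supermodel(rows2, sp, horizon_h = 48)
  expect_equal(sm1$fits$infection$coef, sm2$fits$infection$coef,
               tolerance = 1e-8)
  expect_equal(predict_cif(sm1, rows)$f_inf, predict_cif(sm2, rows2)$f_inf,
               tolerance = 1e-8)
})

test_that("stratified baseline mode drops the landmark terms and fits per-landmark baselines", {
  b <- simulate_cohort(generator_config(n_admissions = 120, seed = 16),
                       include_vitals = FALSE)
  st <- build_stacked_dataset(b)
  rows <- apply_imputation(st$rows,
                           fit_imputation(st$rows, st$covariate_spec$dynamic))
  sp <- covariate_spec(c("age", "crp"))
  smp <- fit_supermodel(rows, sp, baseline_mode = "pooled", horizon_h = 48)
  sms <- fit_supermodel(rows, sp, baseline_mode = "stratified",
                        horizon_h = 48)
  expect_true(all(c("s", "s2") %in% names(smp$fits$infection$coef)))
  expect_false(any(c("s", "s2") %in% names(sms$fits$infection$coef)))
  expect_gt(length(unique(sms$fits$infection$baseline$stratum)), 1L)
  ps <- predict_cif(sms, rows)
  expect_lt(max(abs(ps$f_inf + ps$f_death + ps$f_discharge + ps$surv - 1)),
            1e-10)
})

test_that("likelihood-ratio p-values are uniform when the score is pure noise", {
  pvals <- vapply(1:150, function(s) {
    d <- gen_exp_ph(250, beta = 0.5, seed = 3000 + s)
    set.seed(s)
    d$cnn_score <- runif(nrow(d))
    base <- fit_cause_specific(d, "infection",
                               covariate_spec("x", landmark_terms = FALSE))
    deep <- fit_cause_specific(d, "infection",
                               covariate_spec("x", landmark_terms = FALSE,
                                              cnn_score = TRUE))
    lr_test(base, deep)$p_value
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  f <- fit_cause_specific(gen_exp_ph(100, seed = 1), "infection",
                          covariate_spec("x", landmark_terms = FALSE))
  expect_error(lr_test(f, f), "not nested")
})

test_that("Wald statistics follow (beta/se)^2 and flag singular fits", {
  fake <- structure(list(coef = c(a = 0.5, b = 0),
                         se = c(a = 0.25, b = 1),
                         vcov = diag(c(0.0625, 1))),
                    class = "cause_specific_fit")
  expect_equal(unname(wald_chi2(fake)), c(4, 0))
  fake$se <- c(a = 0, b = 1)
  expect_error(wald_chi2(fake), "singular")
})
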