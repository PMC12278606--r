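## Independent oracles and fixture builders shared across test files.
## Everything here is deliberately written without reusing the package's
## own computational paths.

## exponential proportional-hazards data with independent censoring,
## shaped like a stacked landmark data.frame (single cause)
gen_exp_ph <- function(n, beta = 0.7, seed = 1, base_rate = 0.05,
                       cens_rate = 0.03) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  t_ev <- stats::rexp(n, base_rate * exp(beta * x))
  t_c <- stats::rexp(n, cens_rate)
  data.frame(outcome_time = pmin(t_ev, t_c),
             outcome_type = ifelse(t_ev <= t_c, "infection", "censored"),
             x = x)
}

## hand-coded Cox log partial likelihood (no ties) and its direct
## numerical maximisation -- the oracle for the fitted coefficients
cox_pl_oracle <- function(time, status, X) {
  negll <- function(beta) {
    lp <- drop(X %*% beta)
    s <- 0
    for (i in which(status == 1L)) {
      rs <- time >= time[i]
      s <- s + lp[i] - log(sum(exp(lp[rs])))
    }
    -s
  }
  stats::optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))$par
}

## exhaustive pairwise Harrell concordance on administratively censored
## (time, event) data; ties in predictions count one half
brute_force_c <- function(time, event, pred) {
  conc <- 0; comp <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1L) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (time[i] < time[j] || (time[i] == time[j] && event[j] == 0L)) {
        comp <- comp + 1
        if (pred[i] > pred[j]) conc <- conc + 1
        else if (pred[i] == pred[j]) conc <- conc + 0.5
      }
    }
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}

## competing-exponential landmark rows with known per-row true CIF
sim_competing_rows <- function(n, w = 48, seed = 1, lambda_other = 0.012,
                               meanlog = log(0.004), sdlog = 0.8) {
  set.seed(seed)
  li <- stats::rlnorm(n, meanlog, sdlog)
  lt <- li + lambda_other
  true_cif <- li / lt * (1 - exp(-lt * w))
  t_inf <- stats::rexp(n, li)
  t_oth <- stats::rexp(n, lambda_other)
  t1 <- pmin(t_inf, t_oth)
  data.frame(
    outcome_time = pmin(t1, w),
    outcome_type = ifelse(t1 > w, "censored",
                          ifelse(t_inf <= t_oth, "infection", "discharge")),
    true_cif = true_cif)
}

## minimal cohort bundle wrapper around hand-built timelines
bundle_from_timelines <- function(timelines) {
  n <- length(timelines)
  structure(list(
    admissions = data.frame(
      patient_id = sprintf("P%d", seq_len(n)),
      admission_id = vapply(timelines, `[[`, "", "admission_id"),
      stringsAsFactors = FALSE),
    timelines = timelines, clinical = NULL, vitals = NULL,
    truth = data.frame(), config = NULL), class = "icu_cohort")
}

## 5-channel white-noise windows with an optional ramp on channel 1
ramp_windows <- function(n, t_minutes, noise_sd = 3, ramp_height = 15,
                         seed = 1) {
  set.seed(seed)
  X <- array(stats::rnorm(5 * t_minutes * n, 0, noise_sd),
             c(5, t_minutes, n))
  y <- stats::rbinom(n, 1, 0.5)
  ramp <- ramp_height * seq(0, 1, length.out = t_minutes)
  for (i in which(y == 1)) X[1, , i] <- X[1, , i] + ramp
  list(X = X, y = y)
}

## small CNN presets that train in seconds
fast_cnn_grid <- function(window_minutes = 160, downsample = 5) {
  list(cnn_config(filters = c(4, 4, 8, 8, 8),
                  window_minutes = window_minutes,
                  downsample = downsample, epochs = 20, batch = 32,
                  patience = 4))
}
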