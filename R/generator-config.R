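#' Configuration for the synthetic ICU cohort generator
#'
#' Builds and validates the full parameter set of the cohort simulator.
#' The shipped defaults are calibrated so that a large simulated cohort
#' reproduces the headline incidence statistics of a mixed tertiary-ICU
#' population: a near-constant cause-specific infection hazard of about
#' 3.5% per at-risk ICU day, roughly 19% of admissions developing at least
#' one ICU-acquired infection (ICU-AI), a median first onset near day 7,
#' recurrent onsets around day 14-15, and 4-5% of patients with more than
#' one infection episode.
#'
#' Event times are drawn from competing exponential cause-specific hazards
#' that are piecewise-constant over regimes: before 48 h all hazards are
#' zero (every admission therefore satisfies the ICU-stay > 48 h inclusion
#' criterion by construction); from 48 h the infection hazard competes with
#' discharge and death; during the 48 h blackout after each onset the
#' infection hazard is suppressed while terminal hazards remain active;
#' after a first infection the discharge hazard is multiplied by
#' `post_infection_disch_factor` (< 1, infected patients stay longer) and
#' the death hazard by `post_infection_death_factor` (> 1). A per-patient
#' log-normal frailty multiplies the two terminal hazards only, which
#' reconciles the constant daily infection risk with the much longer stays
#' of patients who become infected.
#'
#' @param n_admissions number of admissions to simulate.
#' @param seed integer seed; together with the other fields it fully
#'   determines the generated cohort.
#' @param lambda_inf cause-specific ICU-AI hazard per at-risk day.
#' @param lambda_disch baseline discharge hazard per day.
#' @param lambda_death baseline ICU-death hazard per day.
#' @param frailty_sigma SD of the per-patient log-normal multiplier applied
#'   to the terminal-event hazards (0 disables heterogeneity).
#' @param post_infection_disch_factor multiplier (< 1) on the discharge
#'   hazard after a first infection.
#' @param post_infection_death_factor multiplier (> 1) on the death hazard
#'   after a first infection.
#' @param beta_inf named numeric vector of static-covariate effects on the
#'   infection log-hazard; names must be covariate columns of the admission
#'   table. Effects are applied to covariates centered at the generator's
#'   own population means so the marginal rate stays at `lambda_inf`.
#' @param signature_lead_h hours before each onset at which the vital-sign
#'   deterioration signature starts ramping.
#' @param signature_amplitudes named deltas reached at onset for the five
#'   vital channels (`hr`, `map`, `pp`, `rr`, `spo2`).
#' @param signature_jitter relative patient-level jitter on the signature
#'   amplitudes (0.3 means amplitudes are scaled by U(0.7, 1.3)).
#' @param covariate_drift list of pre-onset ramps for the 8-hourly clinical
#'   channels; each element has fields `delta` (additive, or relative when
#'   `relative = TRUE`) and `lead_h`.
#' @param vital_noise_sd named stationary SDs of the AR(1) noise on the five
#'   vital channels.
#' @param missingness_rate fraction of vital-sign minutes dropped at random.
#' @param max_followup_days administrative truncation of follow-up.
#' @return A list of class `icu_generator_config`.
#' @seealso [simulate_cohort()]
#' @export
generator_config <- function(n_admissions = 1000,
                             seed = 1L,
                             lambda_inf = 0.034,
                             lambda_disch = 0.16,
                             lambda_death = 0.018,
                             frailty_sigma = 1.3,
                             post_infection_disch_factor = 0.40,
                             post_infection_death_factor = 1.2,
                             beta_inf = c(age = 0.004, male = 0.35,
                                          surgical = 0.20,
                                          immunodeficiency = 0.25,
                                          apache_iv = 0.006,
                                          sepsis_admission = -0.30),
                             signature_lead_h = 24,
                             signature_amplitudes = c(hr = 15, map = -10,
                                                      pp = -5, rr = 6,
                                                      spo2 = -2),
                             signature_jitter = 0.3,
                             covariate_drift = list(
                               crp = list(delta = 80, lead_h = 48),
                               temperature = list(delta = 1.2, lead_h = 24),
                               platelets = list(delta = -0.30, lead_h = 72,
                                                relative = TRUE)),
                             vital_noise_sd = c(hr = 3, map = 4, pp = 3,
                                                rr = 1.5, spo2 = 0.8),
                             missingness_rate = 0.05,
                             max_followup_days = 22) {
  cfg <- list(
    n_admissions = as.integer(n_admissions),
    seed = as.integer(seed),
    lambda_inf = lambda_inf,
    lambda_disch = lambda_disch,
    lambda_death = lambda_death,
    frailty_sigma = frailty_sigma,
    post_infection_disch_factor = post_infection_disch_factor,
    post_infection_death_factor = post_infection_death_factor,
    beta_inf = beta_inf,
    signature_lead_h = signature_lead_h,
    signature_amplitudes = signature_amplitudes,
    signature_jitter = signature_jitter,
    covariate_drift = covariate_drift,
    vital_noise_sd = vital_noise_sd,
    missingness_rate = missingness_rate,
    max_followup_days = max_followup_days
  )
  class(cfg) <- "icu_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "icu_generator_config"))
  if (is.na(cfg$n_admissions) || cfg$n_admissions < 1L) {
    stop("`n_admissions` must be a positive integer", call. = FALSE)
  }
  haz <- c(cfg$lambda_inf, cfg$lambda_disch, cfg$lambda_death)
  if (any(!is.finite(haz)) || any(haz < 0)) {
    stop("all hazards must be finite and >= 0", call. = FALSE)
  }
  if (cfg$lambda_disch == 0 && cfg$lambda_death == 0) {
    stop("terminal hazards are all zero: admissions would never terminate",
         call. = FALSE)
  }
  if (cfg$frailty_sigma < 0) stop("`frailty_sigma` must be >= 0", call. = FALSE)
  if (cfg$missingness_rate < 0 || cfg$missingness_rate >= 1) {
    stop("`missingness_rate` must be in [0, 1)", call. = FALSE)
  }
  if (cfg$max_followup_days <= 2) {
    stop("`max_followup_days` must exceed the 48 h inclusion window",
         call. = FALSE)
  }
  unknown <- setdiff(names(cfg$beta_inf), names(.static_covariate_means))
  if (length(unknown)) {
    stop("unknown covariates in `beta_inf`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

## Population means of the static covariates under the sampling scheme of
## simulate_admissions(); used to center the linear predictor so that
## lambda_inf remains the (approximate) marginal infection hazard.
.static_covariate_means <- c(
  age = 60, male = 0.64, surgical = 0.43, prior_icu = 0.155,
  sepsis_admission = 0.43, diabetes = 0.161, immunodeficiency = 0.164,
  malignancy = 0.165, cardiovascular_insuff = 0.180, renal_insuff = 0.085,
  respiratory_insuff = 0.078, apache_iv = 80, sofa = 7
)

.vital_baselines <- c(hr = 80, map = 75, pp = 45, rr = 16, spo2 = 97)
.vital_circadian_amp <- c(hr = 3, map = 2, pp = 1, rr = 0.5, spo2 = 0.3)
.vital_ranges <- list(hr = c(20, 220), map = c(30, 180), pp = c(5, 120),
                      rr = c(4, 60), spo2 = c(50, 100))

.clinical_baselines <- c(crp = 60, temperature = 37.0, wbc = 11,
                         platelets = 220, creatinine = 95, fio2 = 0.40,
                         sofa = 7)
.clinical_noise_sd <- c(crp = 18, temperature = 0.35, wbc = 2.2,
                        platelets = 28, creatinine = 18, fio2 = 0.05,
                        sofa = 1.1)
.clinical_ranges <- list(crp = c(0.1, 600), temperature = c(30, 43),
                         wbc = c(0.1, 80), platelets = c(5, 1000),
                         creatinine = c(20, 1200), fio2 = c(0.21, 1),
                         sofa = c(0, 24))
## labs drawn once daily; bedside channels at every 8 h grid point
.daily_channels <- c("crp", "wbc", "platelets", "creatinine")
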