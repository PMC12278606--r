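#' Write a simulated cohort to delimited files
#'
#' Produces `admissions.csv` (one row per admission), `events.csv`
#' (semicolon-delimited onset times, terminal event and time),
#' `clinical.csv` (long format: admission_id, time_h, channel, value) and
#' optionally `vitals.csv` (long format at 1-minute resolution; large),
#' plus `config.json`. Column meanings are documented in the schema file
#' shipped at `system.file("extdata", "file_schemas.json", package =
#' "icualert")`.
#'
#' @param bundle an `icu_cohort`.
#' @param dir output directory (created if needed).
#' @param include_vitals also write the 1-minute vital streams.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(bundle, dir, include_vitals = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(f) file.path(dir, f)
  utils::write.csv(bundle$admissions, p("admissions.csv"), row.names = FALSE)
  files <- c(files, p("admissions.csv"))
  ev <- data.frame(
    admission_id = vapply(bundle$timelines, `[[`, "", "admission_id"),
    onset_times_h = vapply(bundle$timelines, function(t)
      paste(t$infection_onsets, collapse = ";"), ""),
    terminal_event = vapply(bundle$timelines, `[[`, "", "terminal_event"),
    terminal_time_h = vapply(bundle$timelines, `[[`, 0, "terminal_time"),
    stringsAsFactors = FALSE)
  utils::write.csv(ev, p("events.csv"), row.names = FALSE)
  files <- c(files, p("events.csv"))
  if (!is.null(bundle$clinical)) {
    long <- do.call(rbind, lapply(bundle$clinical, function(cl) {
      chans <- setdiff(names(cl), c("admission_id", "time_h"))
      do.call(rbind, lapply(chans, function(ch) {
        data.frame(admission_id = cl$admission_id, time_h = cl$time_h,
                   channel = ch, value = cl[[ch]], stringsAsFactors = FALSE)
      }))
    }))
    long <- long[!is.na(long$value), ]
    utils::write.csv(long, p("clinical.csv"), row.names = FALSE)
    files <- c(files, p("clinical.csv"))
  }
  if (include_vitals && !is.null(bundle$vitals)) {
    vl <- do.call(rbind, lapply(bundle$vitals, function(v) {
      do.call(rbind, lapply(colnames(v$values), function(ch) {
        ok <- !is.na(v$values[, ch])
        data.frame(admission_id = v$admission_id, minute = v$minute[ok],
                   channel = ch, value = v$values[ok, ch],
                   stringsAsFactors = FALSE)
      }))
    }))
    utils::write.csv(vl, p("vitals.csv"), row.names = FALSE)
    files <- c(files, p("vitals.csv"))
  }
  jsonlite::write_json(unclass(bundle$config), p("config.json"),
                       digits = NA, auto_unbox = TRUE)
  files <- c(files, p("config.json"))
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' The latent `truth` table of the generator is not serialised and comes
#' back empty.
#'
#' @param dir directory holding the cohort files.
#' @return An `icu_cohort`.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  admissions <- utils::read.csv(p("admissions.csv"), stringsAsFactors = FALSE)
  ev <- utils::read.csv(p("events.csv"), stringsAsFactors = FALSE)
  timelines <- lapply(seq_len(nrow(ev)), function(i) {
    on <- as.character(ev$onset_times_h[i])
    list(admission_id = ev$admission_id[i],
         infection_onsets = if (is.na(on) || on == "") numeric(0) else
           as.numeric(strsplit(on, ";")[[1]]),
         terminal_event = ev$terminal_event[i],
         terminal_time = ev$terminal_time_h[i])
  })
  clinical <- NULL
  if (file.exists(p("clinical.csv"))) {
    long <- utils::read.csv(p("clinical.csv"), stringsAsFactors = FALSE)
    clinical <- lapply(timelines, function(tl) {
      sub <- long[long$admission_id == tl$admission_id, ]
      grid <- sort(unique(sub$time_h))
      out <- data.frame(admission_id = rep(tl$admission_id, length(grid)),
                        time_h = grid)
      for (ch in unique(long$channel)) {
        s2 <- sub[sub$channel == ch, ]
        out[[ch]] <- s2$value[match(grid, s2$time_h)]
      }
      out
    })
  }
  vitals <- NULL
  if (file.exists(p("vitals.csv"))) {
    vl <- utils::read.csv(p("vitals.csv"), stringsAsFactors = FALSE)
    vitals <- lapply(timelines, function(tl) {
      sub <- vl[vl$admission_id == tl$admission_id, ]
      n_min <- max(1L, floor(tl$terminal_time * 60))
      minute <- seq_len(n_min) - 1L
      vals <- matrix(NA_real_, n_min, length(.vital_channels),
                     dimnames = list(NULL, .vital_channels))
      for (ch in unique(sub$channel)) {
        s2 <- sub[sub$channel == ch, ]
        vals[s2$minute + 1L, ch] <- s2$value
      }
      list(admission_id = tl$admission_id, minute = minute, values = vals)
    })
  }
  config <- NULL
  if (file.exists(p("config.json"))) {
    cj <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
    config <- tryCatch(
      generator_config(
        n_admissions = cj$n_admissions, seed = cj$seed,
        lambda_inf = cj$lambda_inf, lambda_disch = cj$lambda_disch,
        lambda_death = cj$lambda_death, frailty_sigma = cj$frailty_sigma,
        post_infection_disch_factor = cj$post_infection_disch_factor,
        post_infection_death_factor = cj$post_infection_death_factor,
        beta_inf = unlist(cj$beta_inf),
        signature_lead_h = cj$signature_lead_h,
        signature_amplitudes = unlist(cj$signature_amplitudes),
        signature_jitter = cj$signature_jitter,
        covariate_drift = cj$covariate_drift,
        vital_noise_sd = unlist(cj$vital_noise_sd),
        missingness_rate = cj$missingness_rate,
        max_followup_days = cj$max_followup_days),
      error = function(e) NULL)
  }
  structure(list(admissions = admissions, timelines = timelines,
                 clinical = clinical, vitals = vitals,
                 truth = data.frame(), config = config),
            class = "icu_cohort")
}

#' Write / read the stacked landmark dataset
#'
#' `stacked.csv` holds one row per landmark prediction instance; the
#' sidecar `stacked_meta.json` records the landmark grid, covariate
#' specification and centering constant so the dataset round-trips.
#'
#' @param stacked a `stacked_dataset`.
#' @param path path of the CSV file (the sidecar is written next to it).
#' @return Invisibly, `path`.
#' @export
write_stacked <- function(stacked, path) {
  utils::write.csv(stacked$rows, path, row.names = FALSE)
  meta <- list(grid = unclass(stacked$grid),
               covariate_spec = stacked$covariate_spec,
               landmark_levels = stacked$landmark_levels)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stacked
#' @export
read_stacked <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  g <- meta$grid
  structure(list(rows = rows,
                 landmark_levels = as.numeric(meta$landmark_levels),
                 covariate_spec = list(
                   static = meta$covariate_spec$static,
                   dynamic = meta$covariate_spec$dynamic,
                   s_center = meta$covariate_spec$s_center,
                   lookback_h = meta$covariate_spec$lookback_h),
                 grid = landmark_grid(horizon_h = g$horizon_h,
                                      spacing_h = g$spacing_h,
                                      first_landmark_h = g$first_landmark_h,
                                      runin_exclusion_h = g$runin_exclusion_h,
                                      blackout_h = g$blackout_h)),
            class = "stacked_dataset")
}

#' Export a supermodel fit as JSON and coefficient tables
#'
#' @param model an `lmcr_supermodel`.
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_supermodel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coef_tab <- do.call(rbind, lapply(model$fits, function(f) {
    data.frame(cause = f$cause, covariate = names(f$coef),
               beta = unname(f$coef), se = unname(f$se),
               hr = exp(unname(f$coef)),
               hr_lo = exp(unname(f$coef) - 1.96 * unname(f$se)),
               hr_hi = exp(unname(f$coef) + 1.96 * unname(f$se)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(coef_tab, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  js <- lapply(model$fits, function(f) {
    list(cause = f$cause, coef = as.list(f$coef), se = as.list(f$se),
         loglik = f$loglik, loglik_null = f$loglik_null,
         n = f$n, n_events = f$n_events, converged = f$converged,
         baseline_mode = f$baseline_mode)
  })
  jsonlite::write_json(list(horizon_h = model$horizon_h,
                            baseline_mode = model$baseline_mode,
                            fits = js),
                       file.path(dir, "supermodel.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(file.path(dir, c("coefficients.csv", "supermodel.json")))
}
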