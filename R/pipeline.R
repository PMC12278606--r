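#' End-to-end run configuration
#'
#' Bundles the generator, landmark grid, covariate, CNN and
#' cross-validation settings behind one master seed. All module seeds are
#' derived by hashing the master seed with a stage label, so adding or
#' removing a stage never shifts the random streams of the others. The
#' configuration round-trips losslessly through its JSON form.
#'
#' @param generator a [generator_config()].
#' @param grid a [landmark_grid()].
#' @param channels dynamic channels used in the model (`NULL` = all).
#' @param static_covariates static covariates used in the model.
#' @param use_cnn train the CNN vital-sign score and the deep supermodel.
#' @param cnn_grid list of [cnn_config()] candidates.
#' @param k,repeats cross-validation folds and repetitions.
#' @param seed master seed.
#' @param n_perm permutations per covariate for the importance heatmaps
#'   (0 disables the importance stage).
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       grid = landmark_grid(),
                       channels = NULL,
                       static_covariates = c("age", "male", "surgical",
                                             "apache_iv", "sepsis_admission",
                                             "immunodeficiency"),
                       use_cnn = FALSE,
                       cnn_grid = list(cnn_config()),
                       k = 5, repeats = 1, seed = 1L, n_perm = 0) {
  structure(list(generator = generator, grid = grid, channels = channels,
                 static_covariates = static_covariates, use_cnn = use_cnn,
                 cnn_grid = cnn_grid, k = k, repeats = repeats,
                 seed = as.integer(seed), n_perm = n_perm),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  obj <- list(generator = unclass(config$generator),
              grid = unclass(config$grid), channels = config$channels,
              static_covariates = config$static_covariates,
              use_cnn = config$use_cnn,
              cnn_grid = lapply(config$cnn_grid, unclass),
              k = config$k, repeats = config$repeats, seed = config$seed,
              n_perm = config$n_perm)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- o$generator
  cfg_gen <- generator_config(
    n_admissions = gen$n_admissions, seed = gen$seed,
    lambda_inf = gen$lambda_inf, lambda_disch = gen$lambda_disch,
    lambda_death = gen$lambda_death, frailty_sigma = gen$frailty_sigma,
    post_infection_disch_factor = gen$post_infection_disch_factor,
    post_infection_death_factor = gen$post_infection_death_factor,
    beta_inf = unlist(gen$beta_inf),
    signature_lead_h = gen$signature_lead_h,
    signature_amplitudes = unlist(gen$signature_amplitudes),
    signature_jitter = gen$signature_jitter,
    covariate_drift = gen$covariate_drift,
    vital_noise_sd = unlist(gen$vital_noise_sd),
    missingness_rate = gen$missingness_rate,
    max_followup_days = gen$max_followup_days)
  g <- o$grid
  cnn_grid <- lapply(seq_len(if (is.data.frame(o$cnn_grid))
    nrow(o$cnn_grid) else length(o$cnn_grid)), function(i) {
      cc <- if (is.data.frame(o$cnn_grid)) lapply(o$cnn_grid, `[[`, i) else
        o$cnn_grid[[i]]
      cnn_config(kernel = cc$kernel, filters = unlist(cc$filters),
                 pool = cc$pool, dropout = cc$dropout, lr = cc$lr,
                 batch = cc$batch, epochs = cc$epochs,
                 patience = cc$patience,
                 window_minutes = cc$window_minutes,
                 downsample = cc$downsample)
    })
  run_config(generator = cfg_gen,
             grid = landmark_grid(horizon_h = g$horizon_h,
                                  spacing_h = g$spacing_h,
                                  first_landmark_h = g$first_landmark_h,
                                  runin_exclusion_h = g$runin_exclusion_h,
                                  blackout_h = g$blackout_h),
             channels = o$channels,
             static_covariates = o$static_covariates,
             use_cnn = o$use_cnn, cnn_grid = cnn_grid, k = o$k,
             repeats = o$repeats, seed = o$seed, n_perm = o$n_perm)
}

#' Run the full pipeline into an output directory
#'
#' Simulates the cohort, writes its tables, builds the stacked landmark
#' dataset, runs the patient-grouped cross-validation (base and, when
#' configured, deep model with per-fold CNN training), refits the base
#' (and deep, using out-of-fold CNN scores) supermodel on the full data
#' for the coefficient export, and writes the metric report, calibration
#' curve, alert analysis, optional importance heatmaps and a manifest of
#' config hash, seeds and file checksums. Rerunning with an identical
#' configuration reproduces identical checksums.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return Invisibly, the manifest list.
#' @export
run_full <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    stop("output directory is not empty (use overwrite = TRUE to resume over it)",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  message("simulate: n = ", config$generator$n_admissions)
  bundle <- simulate_cohort(config$generator,
                            include_vitals = config$use_cnn)
  write_cohort(bundle, out_dir, include_vitals = FALSE)
  write_run_config(config, p("run_config.json"))

  message("cross-validate: k = ", config$k, " x ", config$repeats,
          if (config$use_cnn) " (with CNN)" else " (base only)")
  cv <- cross_validate(bundle, grid = config$grid,
                       channels = config$channels,
                       static_covariates = config$static_covariates,
                       use_cnn = config$use_cnn,
                       cnn_grid = config$cnn_grid,
                       k = config$k, repeats = config$repeats,
                       seed = derive_seed(config$seed, "cv_stage"))
  message("landmark rows: ", nrow(cv$stacked$rows),
          "; infection rows: ",
          sum(cv$stacked$rows$outcome_type == "infection"))
  write_stacked(cv$stacked, p("stacked.csv"))
  utils::write.csv(cv$oof, p("predictions.csv"), row.names = FALSE)
  if (config$use_cnn) {
    sc <- cv$oof[c("admission_id", "series_id", "t_lm", "cnn_score")]
    utils::write.csv(sc, p("scores.csv"), row.names = FALSE)
  }

  ## full-data refit for the coefficient export
  rows <- apply_imputation(cv$stacked$rows,
                           fit_imputation(cv$stacked$rows, cv$channels))
  spec_base <- covariate_spec(c(config$static_covariates, cv$channels))
  full_base <- fit_supermodel(rows, spec_base,
                              horizon_h = config$grid$horizon_h)
  write_supermodel(full_base, out_dir)
  lr_full <- NULL
  if (config$use_cnn) {
    key <- paste(rows$admission_id, rows$series_id, rows$t_lm)
    okey <- paste(cv$oof$admission_id, cv$oof$series_id, cv$oof$t_lm)
    rows$cnn_score <- cv$oof$cnn_score[match(key, okey)]
    spec_deep <- covariate_spec(c(config$static_covariates, cv$channels),
                                cnn_score = TRUE)
    full_deep <- fit_supermodel(rows, spec_deep,
                                horizon_h = config$grid$horizon_h)
    write_supermodel(full_deep, p("deep"))
    lr_full <- lr_test(full_base, full_deep)
  }

  pred_col <- if (config$use_cnn) "pred_deep" else "pred_base"
  alert <- alert_analysis(cv$oof, bundle$timelines, threshold = 0.10,
                          pred_col = pred_col)
  cal <- calibration(cv$oof[[pred_col]], cv$oof,
                     horizon_h = config$grid$horizon_h)
  if (!is.null(cal$curve)) {
    utils::write.csv(cal$curve, p("calibration_curve.csv"),
                     row.names = FALSE)
  }
  per_lm <- do.call(rbind, lapply(names(cv$metrics), function(m) {
    data.frame(model = m, cv$metrics[[m]]$per_landmark)
  }))
  utils::write.csv(per_lm, p("metrics_by_landmark.csv"), row.names = FALSE)

  if (config$n_perm > 0) {
    imp <- importance_heatmaps(cv, model = if (config$use_cnn) "deep"
                               else "base", n_perm = config$n_perm,
                               seed = derive_seed(config$seed, "importance"))
    utils::write.csv(as.data.frame(imp$wald_rank), p("importance_wald.csv"))
    utils::write.csv(data.frame(covariate = names(imp$delta_c),
                                delta_c = imp$delta_c),
                     p("importance_deltac.csv"), row.names = FALSE)
  }

  report <- list(
    horizon_h = config$grid$horizon_h,
    n_admissions = config$generator$n_admissions,
    seed = config$seed,
    incidence = unclass(summarize_incidence(bundle))[
      c("patient_days_at_risk", "n_onsets", "daily_rate_pct",
        "cumulative_pct_infected", "median_first_onset_day",
        "median_recurrent_onset_day", "pct_recurrence")],
    metrics = lapply(cv$metrics, function(m) m$global),
    lr_tests_by_fold = cv$lr_tests,
    lr_test_full = lr_full,
    alert = unclass(alert)[c("threshold", "fraction_above",
                             "fraction_alerted", "lead_median_h",
                             "lead_iqr_h")])
  report <- Filter(Negate(is.null), report)
  jsonlite::write_json(report, p("report.json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)

  files <- sort(setdiff(dir(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    config_hash = derive_seed(0, paste(readLines(p("run_config.json")),
                                       collapse = "")),
    seed = config$seed,
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(manifest)
}
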