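#' Patient-grouped fold assignment
#'
#' All rows of one patient (all admissions and all reset series) share a
#' fold; fold sizes are balanced within one patient.
#'
#' @param patients character vector of patient identifiers (repeats
#'   allowed; the unique set is assigned).
#' @param k number of folds.
#' @param repeats number of independent repetitions.
#' @param seed integer seed.
#' @return list of class `fold_plan`: `k`, `repeats`, `seed`,
#'   `assignments` (list of data.frames patient_id/fold), plus
#'   `patient_id` and `fold` for the first repetition.
#' @export
fold_plan <- function(patients, k = 5, repeats = 1, seed = 1L) {
  ids <- sort(unique(as.character(patients)))
  if (length(ids) < k) stop("fewer patients than folds", call. = FALSE)
  assignments <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, paste0("foldplan_", r)))
    shuffled <- sample(ids)
    assignments[[r]] <- data.frame(patient_id = shuffled,
                                   fold = rep_len(seq_len(k), length(ids)),
                                   stringsAsFactors = FALSE)
  }
  structure(list(k = k, repeats = repeats, seed = seed,
                 assignments = assignments,
                 patient_id = assignments[[1]]$patient_id,
                 fold = assignments[[1]]$fold),
            class = "fold_plan")
}

## administrative-censoring transform: competing events are treated as
## infection-free through the whole window (censored at the horizon);
## optionally censored at their event time instead
.cindex_frame <- function(rows, horizon_h, competing = c("horizon", "event_time")) {
  competing <- match.arg(competing)
  event <- as.integer(rows$outcome_type == "infection")
  time <- ifelse(event == 1L, rows$outcome_time,
                 if (competing == "horizon") horizon_h else rows$outcome_time)
  if (competing == "horizon") time[event == 0L] <- horizon_h
  data.frame(time = time, event = event)
}

#' Harrell's c-index under administrative censoring of competing events
#'
#' Competing events (death, discharge within the window) are treated as
#' infection-free through the whole window, i.e. censored at the horizon
#' (the `competing = "event_time"` switch censors them at their event
#' time instead). Comparable pairs follow Harrell's rules on the
#' transformed (time, indicator) data; ties in predictions count one
#' half.
#'
#' @param predictions numeric predicted risks, aligned with `rows`.
#' @param rows data.frame with `outcome_type` and `outcome_time`.
#' @param horizon_h prediction-window length.
#' @param competing how competing events are censored.
#' @return list(c_index, n_pairs); `c_index` is `NA` when no pair is
#'   comparable.
#' @export
harrell_c <- function(predictions, rows, horizon_h = 48,
                      competing = c("horizon", "event_time")) {
  stopifnot(length(predictions) == nrow(rows))
  fr <- .cindex_frame(rows, horizon_h, competing)
  res <- .concordance_pairs_cpp(fr$time, as.integer(fr$event),
                                as.numeric(predictions))
  list(c_index = if (res[2] > 0) res[1] / res[2] else NA_real_,
       n_pairs = res[2])
}

#' Brier score of windowed infection predictions
#'
#' Mean squared difference between the predicted probability and the
#' binary indicator of infection within the window; competing events and
#' rows censored at the horizon count as non-events.
#'
#' @inheritParams harrell_c
#' @return numeric scalar in [0, 1].
#' @export
brier_score <- function(predictions, rows) {
  stopifnot(length(predictions) == nrow(rows),
            all(predictions >= 0 & predictions <= 1))
  mean((predictions - as.integer(rows$outcome_type == "infection"))^2)
}

#' Competing-risk calibration of windowed predictions
#'
#' Rows are binned by deciles of predicted risk; the observed event
#' frequency per bin is the nonparametric Aalen-Johansen cumulative
#' incidence of infection at the horizon with death and discharge as
#' competing events. The calibration slope and intercept come from a
#' least-squares fit of bin observed on bin mean predicted, weighted by
#' bin size.
#'
#' @inheritParams harrell_c
#' @param n_bins number of predicted-risk bins.
#' @return list(curve, slope, intercept, reason); slope and intercept are
#'   `NA` with a reason when the predictions cannot be binned (e.g.
#'   constant).
#' @export
calibration <- function(predictions, rows, horizon_h = 48, n_bins = 10) {
  stopifnot(length(predictions) == nrow(rows))
  brk <- unique(stats::quantile(predictions, seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 3) {
    return(list(curve = NULL, slope = NA_real_, intercept = NA_real_,
                reason = "predictions too concentrated to form bins"))
  }
  bin <- cut(predictions, brk, include.lowest = TRUE)
  ev <- factor(rows$outcome_type,
               levels = c("censored", "infection", "death", "discharge"))
  curve <- do.call(rbind, lapply(levels(bin), function(b) {
    idx <- bin == b
    if (!any(idx)) return(NULL)
    obs <- aj_cif(rows$outcome_time[idx], ev[idx], horizon_h)
    data.frame(bin = b, n = sum(idx), mean_pred = mean(predictions[idx]),
               observed = obs)
  }))
  fit <- stats::lm(observed ~ mean_pred, data = curve, weights = curve$n)
  list(curve = curve, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), reason = NULL)
}

#' Aalen-Johansen cumulative incidence of infection at a horizon
#'
#' @param time event/censoring times on window time.
#' @param event factor with levels censored/infection/death/discharge
#'   (first level = censoring).
#' @param horizon_h evaluation time.
#' @return Estimated probability of infection by `horizon_h`.
#' @export
aj_cif <- function(time, event, horizon_h) {
  if (all(event == "infection")) return(1)
  if (all(event == "censored")) return(0)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  state <- which(sf$states == "infection")
  at <- which(sf$time <= horizon_h)
  if (!length(at)) return(0)
  unname(sf$pstate[max(at), state])
}

#' Repeated patient-grouped cross-validation of the landmark pipeline
#'
#' Per fold: imputation medians are learned, the CNN (optionally)
#' trained, and the base and deep supermodels fitted on training-fold
#' patients only; out-of-fold rows are then scored and predicted. Metrics
#' (c-index, Brier, calibration) are reported per fold and summarised as
#' the mean over folds with a normal-approximation 95% confidence
#' interval, globally and per landmark.
#'
#' @param bundle an `icu_cohort` (with vital streams when `use_cnn`).
#' @param grid a [landmark_grid()].
#' @param channels dynamic clinical channels entering the model.
#' @param static_covariates static admission covariates entering the model.
#' @param use_cnn train and include the CNN vital-sign risk score.
#' @param cnn_grid list of [cnn_config()] candidates for the per-fold CNN.
#' @param k folds; `repeats` repetitions of the whole scheme.
#' @param repeats repetitions.
#' @param seed master seed for folds and CNN training.
#' @param baseline_mode passed to [fit_supermodel()].
#' @return list of class `cv_result`: `oof` (out-of-fold predictions with
#'   keys and outcomes), `folds` (per-fold fitted objects), `metrics`
#'   (per model), `lr_tests`, `plan`, `grid`.
#' @export
cross_validate <- function(bundle, grid = landmark_grid(),
                           channels = NULL,
                           static_covariates = c("age", "male", "surgical",
                                                 "apache_iv", "sepsis_admission",
                                                 "immunodeficiency"),
                           use_cnn = FALSE,
                           cnn_grid = list(cnn_config()),
                           k = 5, repeats = 1, seed = 1L,
                           baseline_mode = "pooled") {
  stacked <- build_stacked_dataset(bundle, grid, channels = channels,
                                   static_covariates = static_covariates)
  rows <- stacked$rows
  channels <- stacked$covariate_spec$dynamic
  spec_base <- covariate_spec(c(static_covariates, channels))
  spec_deep <- covariate_spec(c(static_covariates, channels),
                              cnn_score = TRUE)
  plan <- fold_plan(rows$patient_id, k = k, repeats = repeats,
                    seed = derive_seed(seed, "cv"))
  w <- grid$horizon_h

  windows <- NULL
  if (use_cnn) {
    wm <- cnn_grid[[1]]$window_minutes
    windows <- build_vital_windows(bundle, rows, window_minutes = wm)
  }

  oof <- list(); folds <- list(); lr_tests <- list()
  fold_metrics <- list()
  for (r in seq_len(repeats)) {
    amap <- plan$assignments[[r]]
    fold_of_row <- amap$fold[match(rows$patient_id, amap$patient_id)]
    for (f in seq_len(k)) {
      tr <- which(fold_of_row != f)
      te <- which(fold_of_row == f)
      if (sum(rows$outcome_type[tr] == "infection") == 0L ||
          sum(rows$outcome_type[te] == "infection") == 0L) {
        stop("a fold contains no infection events; enlarge the cohort",
             call. = FALSE)
      }
      imp <- fit_imputation(rows[tr, ], channels)
      rows_tr <- apply_imputation(rows[tr, ], imp)
      rows_te <- apply_imputation(rows[te, ], imp)

      cnn <- NULL
      if (use_cnn) {
        lab_tr <- as.integer(rows$outcome_type[tr] == "infection")
        cnn <- train_cnn(windows[, , tr, drop = FALSE], lab_tr,
                         grid = cnn_grid, groups = rows$patient_id[tr],
                         k = min(5, k),
                         seed = derive_seed(seed, sprintf("cnn_%d_%d", r, f)))
        rows_tr$cnn_score <- score_windows(cnn, windows[, , tr, drop = FALSE])
        rows_te$cnn_score <- score_windows(cnn, windows[, , te, drop = FALSE])
      }

      base <- fit_supermodel(rows_tr, spec_base, baseline_mode,
                             horizon_h = w)
      pred_b <- predict_cif(base, rows_te)$f_inf
      deep <- NULL; pred_d <- rep(NA_real_, length(te))
      if (use_cnn) {
        deep <- fit_supermodel(rows_tr, spec_deep, baseline_mode,
                               horizon_h = w)
        pred_d <- predict_cif(deep, rows_te)$f_inf
        lr_tests[[length(lr_tests) + 1L]] <-
          c(repeat_ = r, fold = f, unlist(lr_test(base, deep)))
      }
      key <- sprintf("r%d_f%d", r, f)
      folds[[key]] <- list(repeat_ = r, fold = f, base = base, deep = deep,
                           imputation = imp,
                           cnn_fingerprint = if (use_cnn) cnn$fingerprint)
      oof[[key]] <- data.frame(rows_te[c("admission_id", "patient_id",
                                         "series_id", "t_lm", "s", "s2",
                                         "outcome_type", "outcome_time")],
                               pred_base = pred_b, pred_deep = pred_d,
                               repeat_ = r, fold = f,
                               stringsAsFactors = FALSE)
      oof[[key]][channels] <- rows_te[channels]
      if (use_cnn) oof[[key]]$cnn_score <- rows_te$cnn_score
      oof[[key]][static_covariates] <- rows_te[static_covariates]

      for (mdl in c("base", if (use_cnn) "deep")) {
        p <- if (mdl == "base") pred_b else pred_d
        cal <- calibration(p, rows_te, horizon_h = w)
        per_lm <- vapply(stacked$landmark_levels, function(l) {
          sel <- rows_te$t_lm == l
          if (sum(sel) < 2) return(NA_real_)
          harrell_c(p[sel], rows_te[sel, ], horizon_h = w)$c_index
        }, 0)
        fold_metrics[[length(fold_metrics) + 1L]] <- list(
          model = mdl, repeat_ = r, fold = f,
          c_index = harrell_c(p, rows_te, horizon_h = w)$c_index,
          brier = brier_score(p, rows_te),
          cal_slope = cal$slope, cal_intercept = cal$intercept,
          per_landmark_c = stats::setNames(per_lm,
                                           stacked$landmark_levels))
      }
    }
  }
  oof <- do.call(rbind, oof)
  rownames(oof) <- NULL
  metrics <- summarise_fold_metrics(fold_metrics, stacked$landmark_levels)
  structure(list(oof = oof, folds = folds, metrics = metrics,
                 lr_tests = if (length(lr_tests))
                   as.data.frame(do.call(rbind, lr_tests)),
                 plan = plan, grid = grid, stacked = stacked,
                 channels = channels, static_covariates = static_covariates),
            class = "cv_result")
}

## fold-level mean with normal-approximation 95% CI
.mean_ci <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_))
  m <- mean(x)
  half <- if (length(x) > 1) 1.96 * stats::sd(x) / sqrt(length(x)) else NA_real_
  c(mean = m, lo = m - half, hi = m + half)
}

summarise_fold_metrics <- function(fold_metrics, landmark_levels) {
  out <- list()
  for (mdl in unique(vapply(fold_metrics, `[[`, "", "model"))) {
    fm <- Filter(function(z) z$model == mdl, fold_metrics)
    glob <- lapply(c("c_index", "brier", "cal_slope", "cal_intercept"),
                   function(nm) .mean_ci(vapply(fm, `[[`, 0, nm)))
    names(glob) <- c("c_index", "brier", "cal_slope", "cal_intercept")
    per_lm <- t(vapply(seq_along(landmark_levels), function(i) {
      .mean_ci(vapply(fm, function(z) z$per_landmark_c[i], 0))
    }, c(mean = 0, lo = 0, hi = 0)))
    out[[mdl]] <- list(global = glob,
                       per_landmark = data.frame(t_lm = landmark_levels,
                                                 per_lm),
                       n_folds = length(fm))
  }
  out
}

#' Wald-rank and permutation c-index importance heatmaps
#'
#' The Wald view fits the infection-cause Cox model separately on the
#' rows of each landmark level and ranks covariates by their Wald
#' chi-square. The c-index view permutes each covariate across the
#' out-of-fold rows (within fold, using that fold's fitted model for
#' re-prediction) and reports the mean resulting drop in the global
#' out-of-fold c-index over `n_perm` seeded permutations.
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @param model `"base"` or `"deep"`.
#' @param n_perm permutations per covariate.
#' @param seed integer seed for the permutations.
#' @return list of class `importance_report`: `wald_rank` (landmark x
#'   covariate matrix of ranks), `wald_chi2`, `delta_c` (named vector),
#'   `excluded` (covariates dropped, with reasons).
#' @export
importance_heatmaps <- function(cv, model = c("base", "deep"), n_perm = 20,
                                seed = 1L) {
  model <- match.arg(model)
  covars <- c(cv$static_covariates, cv$channels,
              if (model == "deep") "cnn_score")
  rows_all <- if (model == "deep") cv$oof else cv$oof
  ## per-landmark Wald ranking on imputed full data
  imp <- fit_imputation(cv$stacked$rows, cv$channels)
  full <- apply_imputation(cv$stacked$rows, imp)
  lms <- cv$stacked$landmark_levels
  fit_covars <- setdiff(covars, "cnn_score")
  wald <- matrix(NA_real_, length(lms), length(fit_covars),
                 dimnames = list(as.character(lms), fit_covars))
  excluded <- list()
  for (i in seq_along(lms)) {
    sub <- full[full$t_lm == lms[i], ]
    keep <- fit_covars[vapply(fit_covars, function(cv_)
      stats::sd(sub[[cv_]]) > 0, TRUE)]
    dropped <- setdiff(fit_covars, keep)
    for (d in dropped) excluded[[d]] <- "constant at some landmark"
    if (sum(sub$outcome_type == "infection") < 2L || !length(keep)) next
    ft <- tryCatch(
      fit_cause_specific(sub, "infection",
                         covariate_spec(keep, landmark_terms = FALSE)),
      error = function(e) NULL)
    if (is.null(ft)) next
    wald[i, keep] <- wald_chi2(ft)[keep]
  }
  wald_rank <- t(apply(-wald, 1, rank, na.last = "keep"))

  ## permutation delta-c on out-of-fold predictions
  pred_col <- paste0("pred_", model)
  base_c <- harrell_c(rows_all[[pred_col]], rows_all,
                      horizon_h = cv$grid$horizon_h)$c_index
  delta_c <- stats::setNames(rep(NA_real_, length(covars)), covars)
  for (cv_name in covars) {
    if (!cv_name %in% names(rows_all)) next
    if (stats::sd(rows_all[[cv_name]]) == 0) {
      excluded[[cv_name]] <- "constant in out-of-fold rows"
      next
    }
    drops <- numeric(n_perm)
    for (p_i in seq_len(n_perm)) {
      set.seed(derive_seed(seed, sprintf("perm_%s_%d", cv_name, p_i)))
      perm_rows <- rows_all
      perm_rows[[cv_name]] <- sample(perm_rows[[cv_name]])
      preds <- numeric(nrow(perm_rows))
      for (fk in names(cv$folds)) {
        fm <- cv$folds[[fk]][[model]]
        sel <- perm_rows$repeat_ == cv$folds[[fk]]$repeat_ &
          perm_rows$fold == cv$folds[[fk]]$fold
        preds[sel] <- predict_cif(fm, perm_rows[sel, ])$f_inf
      }
      drops[p_i] <- base_c - harrell_c(preds, perm_rows,
                                       horizon_h = cv$grid$horizon_h)$c_index
    }
    delta_c[cv_name] <- mean(drops)
  }
  structure(list(wald_chi2 = wald, wald_rank = wald_rank,
                 delta_c = delta_c, baseline_c = base_c,
                 excluded = excluded),
            class = "importance_report")
}

#' Alert and lead-time analysis of out-of-fold predictions
#'
#' Flags every prediction above `threshold`, and for each admission's
#' first infection computes the lead time between the first alert (at a
#' landmark strictly before onset, within the initial series) and the
#' onset.
#'
#' @param oof out-of-fold prediction data.frame (needs `admission_id`,
#'   `series_id`, `t_lm` and a prediction column).
#' @param timelines list of event timelines of the same cohort.
#' @param threshold alert threshold on predicted risk, in [0, 1].
#' @param pred_col which prediction column to use.
#' @return list of class `alert_report`.
#' @export
alert_analysis <- function(oof, timelines, threshold = 0.10,
                           pred_col = "pred_base") {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  p <- oof[[pred_col]]
  frac_above <- mean(p > threshold)
  leads <- numeric(0); n_first_inf <- 0L
  for (tl in timelines) {
    if (!length(tl$infection_onsets)) next
    n_first_inf <- n_first_inf + 1L
    onset <- tl$infection_onsets[1]
    sel <- oof$admission_id == tl$admission_id & oof$series_id == 0L &
      oof$t_lm < onset & p > threshold
    if (any(sel)) leads <- c(leads, onset - min(oof$t_lm[sel]))
  }
  structure(list(threshold = threshold,
                 fraction_above = frac_above,
                 n_first_infections = n_first_inf,
                 n_alerted = length(leads),
                 fraction_alerted = if (n_first_inf > 0)
                   length(leads) / n_first_inf else NA_real_,
                 lead_median_h = median_or_na(leads),
                 lead_iqr_h = if (length(leads))
                   unname(stats::quantile(leads, c(0.25, 0.75)))
                 else c(NA_real_, NA_real_),
                 leads_h = leads),
            class = "alert_report")
}
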