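#' Landmark grid definition
#'
#' Defines the dynamic-prediction scheme: predictions are issued on an
#' 8-hourly grid of landmark times, each looking into a sliding window of
#' `horizon_h` hours; data from the first 24 h of ICU stay are excluded
#' (run-in), the first landmark of an admission is placed at 48 h, and the
#' 48 h after every infection onset form a blackout during which no data
#' are used and no new onset is defined. After the blackout the series is
#' "reset" and landmarking resumes, with the reset series treated as an
#' independent period of event-free stay.
#'
#' @param horizon_h prediction-window length in hours, 24 or 48.
#' @param spacing_h landmark spacing in hours.
#' @param first_landmark_h first landmark of the initial series.
#' @param runin_exclusion_h run-in period whose data are discarded.
#' @param blackout_h post-onset exclusion period.
#' @return A list of class `landmark_grid`.
#' @export
landmark_grid <- function(horizon_h = 48, spacing_h = 8,
                          first_landmark_h = 48, runin_exclusion_h = 24,
                          blackout_h = 48) {
  stopifnot(horizon_h > 0, spacing_h > 0,
            first_landmark_h >= runin_exclusion_h)
  structure(list(horizon_h = horizon_h, spacing_h = spacing_h,
                 first_landmark_h = first_landmark_h,
                 runin_exclusion_h = runin_exclusion_h,
                 blackout_h = blackout_h),
            class = "landmark_grid")
}

#' Decompose an event timeline into at-risk segments
#'
#' Segment 0 runs from the end of the run-in exclusion to the first
#' infection onset (or the terminal event); segment k (k >= 1) starts at
#' the end of the blackout following the k-th onset and runs to the next
#' onset or the terminal event. A segment entirely swallowed by the
#' blackout (terminal event before blackout end) is omitted.
#'
#' @param timeline a timeline list with `infection_onsets`,
#'   `terminal_event`, `terminal_time` and `admission_id`.
#' @param grid a [landmark_grid()].
#' @return data.frame with columns `admission_id`, `series_id`, `start_h`,
#'   `end_h`, `end_reason`.
#' @export
segment_at_risk_periods <- function(timeline, grid = landmark_grid()) {
  on <- timeline$infection_onsets
  term <- timeline$terminal_time
  if (length(on) && any(on >= term)) {
    stop("malformed timeline: infection onset at or after terminal time",
         call. = FALSE)
  }
  if (length(on) > 1L && any(diff(on) <= grid$blackout_h)) {
    stop("malformed timeline: onsets within the blackout of a previous onset",
         call. = FALSE)
  }
  starts <- c(grid$runin_exclusion_h, on + grid$blackout_h)
  ends <- c(on, term)
  reasons <- c(rep("infection", length(on)), timeline$terminal_event)
  keep <- starts < ends
  data.frame(admission_id = rep(timeline$admission_id, sum(keep)),
             series_id = which(keep) - 1L,
             start_h = starts[keep], end_h = ends[keep],
             end_reason = reasons[keep], stringsAsFactors = FALSE)
}

#' Landmark times within one at-risk segment
#'
#' For the initial series (series 0) landmarks sit on the admission-wide
#' grid `first_landmark_h, first_landmark_h + spacing_h, ...`; for a reset
#' series the clock restarts at the segment start (the blackout end). A
#' landmark coinciding exactly with the segment end is dropped: the
#' patient is no longer at risk there.
#'
#' @param segment one row of [segment_at_risk_periods()] output (or any
#'   list with `series_id`, `start_h`, `end_h`).
#' @param grid a [landmark_grid()].
#' @return Numeric vector of landmark times in hours (possibly empty).
#' @export
place_landmarks <- function(segment, grid = landmark_grid()) {
  anchor <- if (segment$series_id == 0L) grid$first_landmark_h else segment$start_h
  if (anchor >= segment$end_h) return(numeric(0))
  lms <- seq(anchor, segment$end_h, by = grid$spacing_h)
  lms[lms < segment$end_h]
}

#' Label the prediction window of one landmark
#'
#' The first event in `(t_LM, t_LM + horizon]` determines the outcome; on
#' exact ties infection takes precedence over death, death over discharge.
#' With no event in the window the row is censored at the horizon.
#'
#' @param t_lm landmark time (hours); must lie in an at-risk segment.
#' @param timeline event timeline of the admission.
#' @param grid a [landmark_grid()].
#' @return list(outcome_type, outcome_time) with `outcome_time` relative
#'   to `t_lm` and capped at the horizon.
#' @export
label_window <- function(t_lm, timeline, grid = landmark_grid()) {
  segs <- segment_at_risk_periods(timeline, grid)
  inside <- any(t_lm >= segs$start_h & t_lm < segs$end_h)
  if (!inside) stop("t_lm lies outside every at-risk segment", call. = FALSE)
  w <- grid$horizon_h
  cand_t <- numeric(0); cand_e <- character(0)
  on <- timeline$infection_onsets
  hit <- on[on > t_lm & on <= t_lm + w]
  if (length(hit)) { cand_t <- c(cand_t, hit[1]); cand_e <- c(cand_e, "infection") }
  if (timeline$terminal_event %in% c("death", "discharge") &&
      timeline$terminal_time > t_lm && timeline$terminal_time <= t_lm + w) {
    cand_t <- c(cand_t, timeline$terminal_time)
    cand_e <- c(cand_e, timeline$terminal_event)
  }
  if (!length(cand_t)) return(list(outcome_type = "censored", outcome_time = w))
  prec <- c(infection = 1, death = 2, discharge = 3)
  k <- order(cand_t, prec[cand_e])[1]
  list(outcome_type = cand_e[k], outcome_time = cand_t[k] - t_lm)
}

#' Last-observation covariate assembly at a landmark
#'
#' For each dynamic channel the most recent observation in
#' `[t_lm - lookback_h, t_lm]` is used (never anything later than `t_lm`);
#' when none exists the value is `NA` and flagged so a training-fold
#' median can be imputed downstream without leakage.
#'
#' @param clinical data.frame of the admission's 8-hourly series
#'   (column `time_h` plus channels).
#' @param t_lm landmark time in hours.
#' @param channels character vector of channel names to assemble.
#' @param lookback_h staleness limit for dynamic values.
#' @return list(values = named numeric, missing = named logical).
#' @export
assemble_covariates <- function(clinical, t_lm, channels,
                                lookback_h = 24) {
  bad <- setdiff(channels, names(clinical))
  if (length(bad)) {
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx <- clinical$time_h <= t_lm & clinical$time_h >= t_lm - lookback_h
  vals <- stats::setNames(rep(NA_real_, length(channels)), channels)
  for (ch in channels) {
    obs <- clinical[[ch]][idx]
    tt <- clinical$time_h[idx]
    ok <- !is.na(obs)
    if (any(ok)) vals[ch] <- obs[ok][which.max(tt[ok])]
  }
  list(values = vals, missing = is.na(vals))
}

#' Build the stacked landmark dataset
#'
#' One row per (at-risk segment, landmark): outcome label within the
#' sliding window, static covariates, last-observed dynamic covariates
#' with missingness flags, the landmark-time terms `s` (days, centered at
#' the stacked mean) and `s2 = s^2`, and optionally a CNN vital-sign risk
#' score joined by (admission_id, series_id, t_LM). Rows are ordered by
#' admission, series and landmark time.
#'
#' @param bundle an `icu_cohort`.
#' @param grid a [landmark_grid()].
#' @param channels dynamic channels to carry (default: all clinical
#'   channels of the bundle).
#' @param static_covariates names of admission-table columns to carry.
#' @param lookback_h staleness limit for dynamic values.
#' @param cnn_scores optional data.frame with columns `admission_id`,
#'   `series_id`, `t_lm`, `cnn_score`.
#' @return A list of class `stacked_dataset` with elements `rows`
#'   (data.frame), `landmark_levels`, `covariate_spec` (names, dynamic
#'   channels, s-centering constant) and `grid`.
#' @export
build_stacked_dataset <- function(bundle, grid = landmark_grid(),
                                  channels = NULL,
                                  static_covariates = c(
                                    "age", "male", "surgical", "prior_icu",
                                    "sepsis_admission", "diabetes",
                                    "immunodeficiency", "malignancy",
                                    "cardiovascular_insuff", "renal_insuff",
                                    "respiratory_insuff", "apache_iv"),
                                  lookback_h = 24,
                                  cnn_scores = NULL) {
  stopifnot(inherits(bundle, "icu_cohort"), inherits(grid, "landmark_grid"))
  if (is.null(channels)) {
    channels <- if (is.null(bundle$clinical)) character(0) else
      setdiff(names(bundle$clinical[[1]]), c("admission_id", "time_h"))
  }
  if (length(channels) && is.null(bundle$clinical)) {
    stop("bundle has no clinical series but dynamic channels were requested",
         call. = FALSE)
  }
  acc <- list(admission_id = list(), series_id = list(), t_lm = list(),
              outcome_type = list(), outcome_time = list(),
              cov = list(), miss = list())
  for (i in seq_along(bundle$timelines)) {
    tl <- bundle$timelines[[i]]
    segs <- segment_at_risk_periods(tl, grid)
    if (nrow(segs) == 0L) next
    lm_list <- lapply(seq_len(nrow(segs)), function(j)
      place_landmarks(segs[j, ], grid))
    n_lm <- lengths(lm_list)
    if (sum(n_lm) == 0L) next
    t_lms <- unlist(lm_list)
    labs <- lapply(t_lms, label_window, timeline = tl, grid = grid)
    k <- length(acc$t_lm) + 1L
    acc$admission_id[[k]] <- rep(tl$admission_id, length(t_lms))
    acc$series_id[[k]] <- rep(segs$series_id, n_lm)
    acc$t_lm[[k]] <- t_lms
    acc$outcome_type[[k]] <- vapply(labs, `[[`, "", "outcome_type")
    acc$outcome_time[[k]] <- vapply(labs, `[[`, 0, "outcome_time")
    if (length(channels)) {
      cl <- bundle$clinical[[i]]
      cv <- t(vapply(t_lms, function(t_lm) {
        assemble_covariates(cl, t_lm, channels, lookback_h)$values
      }, stats::setNames(numeric(length(channels)), channels)))
      acc$cov[[k]] <- cv
      acc$miss[[k]] <- is.na(cv)
    }
  }
  if (length(acc$t_lm)) {
    rows <- data.frame(admission_id = unlist(acc$admission_id),
                       series_id = unlist(acc$series_id),
                       t_lm = unlist(acc$t_lm),
                       stringsAsFactors = FALSE)
    if (length(channels)) {
      cov <- do.call(rbind, acc$cov)
      miss <- do.call(rbind, acc$miss)
      for (ci in seq_along(channels)) {
        rows[[channels[ci]]] <- cov[, ci]
        rows[[paste0("miss_", channels[ci])]] <- miss[, ci]
      }
    }
    rows$outcome_type <- unlist(acc$outcome_type)
    rows$outcome_time <- unlist(acc$outcome_time)
  } else {
    rows <- data.frame(admission_id = character(0), series_id = integer(0),
                       t_lm = numeric(0), outcome_type = character(0),
                       outcome_time = numeric(0))
  }
  if (anyDuplicated(rows[c("admission_id", "series_id", "t_lm")])) {
    stop("duplicate (admission, series, landmark) rows", call. = FALSE)
  }
  ## static covariates
  if (nrow(rows)) {
    m <- match(rows$admission_id, bundle$admissions$admission_id)
    for (sc in static_covariates) rows[[sc]] <- bundle$admissions[[sc]][m]
    rows$patient_id <- bundle$admissions$patient_id[m]
  } else {
    for (sc in static_covariates) rows[[sc]] <- numeric(0)
    rows$patient_id <- character(0)
  }
  ## landmark-time terms, centered on the stacked mean before squaring
  s_center <- if (nrow(rows)) mean(rows$t_lm / 24) else 0
  rows$s <- rows$t_lm / 24 - s_center
  rows$s2 <- rows$s^2
  if (!is.null(cnn_scores)) {
    key <- paste(rows$admission_id, rows$series_id, rows$t_lm)
    skey <- paste(cnn_scores$admission_id, cnn_scores$series_id,
                  cnn_scores$t_lm)
    rows$cnn_score <- cnn_scores$cnn_score[match(key, skey)]
  }
  rows <- rows[order(rows$admission_id, rows$series_id, rows$t_lm), ]
  rownames(rows) <- NULL
  structure(list(rows = rows,
                 landmark_levels = sort(unique(rows$t_lm)),
                 covariate_spec = list(static = static_covariates,
                                       dynamic = channels,
                                       s_center = s_center,
                                       lookback_h = lookback_h),
                 grid = grid),
            class = "stacked_dataset")
}

#' Fill missing dynamic covariates with training-set medians
#'
#' Imputation constants are learned on the training rows only (typically
#' the training folds of a cross-validation) and applied to any dataset,
#' so no information flows from evaluation rows into the imputation.
#'
#' @param train_rows data.frame used to learn per-channel medians.
#' @param channels dynamic channel names.
#' @return list of class `imputation_state` with the per-channel medians.
#' @export
fit_imputation <- function(train_rows, channels) {
  med <- vapply(channels, function(ch) {
    stats::median(train_rows[[ch]], na.rm = TRUE)
  }, 0)
  structure(list(medians = med, channels = channels),
            class = "imputation_state")
}

#' @rdname fit_imputation
#' @param rows data.frame whose missing channel values are filled.
#' @param state an `imputation_state`.
#' @export
apply_imputation <- function(rows, state) {
  for (ch in state$channels) {
    na <- is.na(rows[[ch]])
    if (any(na)) rows[[ch]][na] <- state$medians[[ch]]
  }
  rows
}
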