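#' Covariate specification for the landmark supermodel
#'
#' Defines which covariates enter the cause-specific Cox models, whether
#' the landmark-time terms `s` and `s2` are included, and whether the CNN
#' vital-sign risk score is an additional predictor (the "deep" model; the
#' base and deep specifications differ only by that score, which is what
#' makes the likelihood-ratio comparison between them nested). No
#' predictor reduction is performed.
#'
#' @param covariates character vector of covariate column names.
#' @param landmark_terms include `s` and `s2` (dropped automatically per
#'   cause in stratified baseline mode, where they are constant within a
#'   landmark stratum and not identifiable).
#' @param cnn_score include the CNN risk score.
#' @return list of class `covariate_spec`.
#' @export
covariate_spec <- function(covariates, landmark_terms = TRUE,
                           cnn_score = FALSE) {
  structure(list(covariates = covariates, landmark_terms = landmark_terms,
                 cnn_score = cnn_score),
            class = "covariate_spec")
}

spec_design_columns <- function(spec, baseline_mode) {
  cols <- spec$covariates
  if (spec$cnn_score) cols <- c(cols, "cnn_score")
  if (spec$landmark_terms && baseline_mode == "pooled") cols <- c(cols, "s", "s2")
  cols
}

#' Fit one cause-specific Cox model on the stacked landmark data
#'
#' Maximises the Cox partial likelihood on window time (hours since the
#' landmark), treating the competing causes as censored at their event
#' times, with Efron tie handling. Rows from different landmarks of one
#' patient are treated as independent contributions, as the stacked
#' landmark supermodel prescribes; robust patient-clustered standard
#' errors are available as an option. The baseline cumulative hazard is a
#' Breslow-type estimate evaluated at the covariate means (covariates are
#' centered internally): either pooled across landmarks (with `s`, `s2`
#' carrying the landmark-time variation) or stratified on the landmark
#' level (one baseline per landmark; `s`, `s2` dropped as non-identifiable
#' within strata).
#'
#' @param stacked a `stacked_dataset` or a data.frame with columns
#'   `outcome_time`, `outcome_type`, the `spec` covariates and (for
#'   stratified mode) `t_lm`.
#' @param cause one of `"infection"`, `"death"`, `"discharge"`.
#' @param spec a [covariate_spec()].
#' @param baseline_mode `"pooled"` (default) or `"stratified"`.
#' @param robust also compute patient-clustered robust standard errors
#'   (requires a `patient_id` column).
#' @return list of class `cause_specific_fit`: coefficients, covariance,
#'   Breslow baseline, log partial likelihoods, event count, centering
#'   constants, training covariate ranges and convergence information.
#' @export
fit_cause_specific <- function(stacked, cause,
                               spec, baseline_mode = c("pooled", "stratified"),
                               robust = FALSE) {
  baseline_mode <- match.arg(baseline_mode)
  rows <- if (inherits(stacked, "stacked_dataset")) stacked$rows else stacked
  cols <- spec_design_columns(spec, baseline_mode)
  miss <- setdiff(cols, names(rows))
  if (length(miss)) {
    stop("design columns absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  status <- as.integer(rows$outcome_type == cause)
  if (sum(status) == 0L) {
    stop(sprintf("no events of cause '%s' in the data", cause), call. = FALSE)
  }
  X <- as.matrix(rows[cols])
  if (anyNA(X)) stop("covariates contain missing values; impute first", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant covariate(s) in design: ",
         paste(cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  df <- data.frame(.time = rows$outcome_time, .status = status, Xc,
                   check.names = FALSE)
  rhs <- paste(sprintf("`%s`", cols), collapse = " + ")
  if (baseline_mode == "stratified") {
    df$.lm <- factor(rows$t_lm)
    rhs <- paste(rhs, "+ strata(.lm)")
  }
  if (robust) {
    df$.pid <- rows$patient_id
    rhs <- paste(rhs, "+ cluster(.pid)")
  }
  fml <- stats::as.formula(paste("survival::Surv(.time, .status) ~", rhs))
  fit <- survival::coxph(fml, data = df, ties = "efron", model = FALSE,
                         x = FALSE, y = TRUE)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design; aliased covariates: ",
         paste(cols[is.na(stats::coef(fit))], collapse = ", "), call. = FALSE)
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  baseline <- data.frame(time = bh$time, cumhaz = bh$hazard,
                         stratum = if (baseline_mode == "stratified")
                           as.character(bh$strata) else "pooled")
  structure(list(cause = cause,
                 coef = stats::coef(fit),
                 vcov = stats::vcov(fit),
                 se = sqrt(diag(stats::vcov(fit))),
                 baseline = baseline,
                 baseline_mode = baseline_mode,
                 loglik_null = fit$loglik[1],
                 loglik = fit$loglik[2],
                 n = nrow(df), n_events = sum(status),
                 centers = centers,
                 ranges = apply(X, 2, range),
                 iter = fit$iter,
                 converged = is.null(fit$fail),
                 design_columns = cols),
            class = "cause_specific_fit")
}

#' Fit the full landmark competing-risk supermodel
#'
#' Fits the three cause-specific Cox models (infection, death, discharge)
#' on the same stacked rows.
#'
#' @inheritParams fit_cause_specific
#' @param horizon_h prediction-window length carried for CIF predictions;
#'   defaults to the grid horizon of the stacked dataset.
#' @return list of class `lmcr_supermodel` with one `cause_specific_fit`
#'   per cause.
#' @export
fit_supermodel <- function(stacked, spec, baseline_mode = c("pooled", "stratified"),
                           horizon_h = NULL, robust = FALSE) {
  baseline_mode <- match.arg(baseline_mode)
  if (is.null(horizon_h)) {
    horizon_h <- if (inherits(stacked, "stacked_dataset"))
      stacked$grid$horizon_h else
        stop("`horizon_h` required when fitting from a plain data.frame")
  }
  fits <- lapply(c(infection = "infection", death = "death",
                   discharge = "discharge"),
                 function(cs) fit_cause_specific(stacked, cs, spec,
                                                 baseline_mode, robust))
  structure(list(fits = fits, spec = spec, baseline_mode = baseline_mode,
                 horizon_h = horizon_h),
            class = "lmcr_supermodel")
}

## baseline hazard increments of one cause on a common time grid
.baseline_increments <- function(fit, times, stratum) {
  b <- fit$baseline[fit$baseline$stratum == stratum, ]
  cum <- stats::approx(c(0, b$time), c(0, b$cumhaz), xout = times,
                       method = "constant", rule = 2, f = 0)$y
  diff(c(0, cum))
}

#' Predict the cumulative incidence of infection within the window
#'
#' Combines the three cause-specific fits into the cumulative incidence
#' function (CIF) of ICU-AI on window time: with discrete Breslow
#' increments \eqn{\Delta\Lambda_k(u_j|x)} the all-cause survival is the
#' product integral \eqn{S(u_j) = \prod_{u_i \le u_j}(1 - \sum_k
#' \Delta\Lambda_k(u_i|x))} and \eqn{F_{inf}(w) = \sum_{u_j \le w}
#' S(u_j^-)\,\Delta\Lambda_{inf}(u_j|x)}. By construction the CIFs of the
#' three causes and the residual survival sum to one.
#'
#' @param model an `lmcr_supermodel`.
#' @param rows data.frame of landmark rows with the model's covariates
#'   (already imputed).
#' @param horizon_h optional override of the model's horizon.
#' @return data.frame with `f_inf`, `f_death`, `f_discharge`, `surv` and
#'   `outside_support` (TRUE when some covariate falls outside its
#'   training range; the prediction is still returned).
#' @export
predict_cif <- function(model, rows, horizon_h = NULL) {
  stopifnot(inherits(model, "lmcr_supermodel"))
  w <- horizon_h %||% model$horizon_h
  n <- nrow(rows)
  causes <- c("infection", "death", "discharge")
  ## linear predictors against each fit's own centering
  risk <- matrix(1, n, 3, dimnames = list(NULL, causes))
  outside <- rep(FALSE, n)
  for (k in causes) {
    f <- model$fits[[k]]
    if (length(f$coef)) {
      X <- as.matrix(rows[f$design_columns])
      if (anyNA(X)) stop("missing covariate values in prediction rows", call. = FALSE)
      Xc <- sweep(X, 2, f$centers)
      risk[, k] <- exp(drop(Xc %*% f$coef))
      lo <- matrix(f$ranges[1, ], n, ncol(X), byrow = TRUE)
      hi <- matrix(f$ranges[2, ], n, ncol(X), byrow = TRUE)
      outside <- outside | apply(X < lo | X > hi, 1, any)
    }
  }
  strata <- if (model$baseline_mode == "stratified")
    as.character(factor(rows$t_lm)) else rep("pooled", n)
  out <- data.frame(f_inf = numeric(n), f_death = numeric(n),
                    f_discharge = numeric(n), surv = numeric(n),
                    outside_support = outside)
  for (st in unique(strata)) {
    idx <- which(strata == st)
    times <- sort(unique(unlist(lapply(causes, function(k) {
      b <- model$fits[[k]]$baseline
      b$time[b$stratum == st & b$time <= w]
    }))))
    if (!length(times)) {
      out$surv[idx] <- 1
      next
    }
    dL <- vapply(causes, function(k)
      .baseline_increments(model$fits[[k]], times, st),
      numeric(length(times)))
    dL <- matrix(dL, nrow = length(times), ncol = 3,
                 dimnames = list(NULL, causes))
    ## per-row all-cause increments: tot[i, j] = sum_k dL[j, k] * risk[i, k];
    ## steps whose all-cause increment exceeds 1 are scaled back so the
    ## product integral stays a probability and CIF additivity is exact
    tot <- risk[idx, , drop = FALSE] %*% t(dL)        # n_idx x n_times
    clip <- ifelse(tot > 1, 1 / tot, 1)
    tot <- tot * clip
    Smat <- t(apply(1 - tot, 1, cumprod))
    if (length(times) == 1L) Smat <- matrix(Smat, ncol = 1)
    Slag <- cbind(1, Smat[, -ncol(Smat), drop = FALSE])
    for (k in causes) {
      Hk <- outer(risk[idx, k], dL[, k]) * clip
      col <- c(infection = "f_inf", death = "f_death",
               discharge = "f_discharge")[[k]]
      out[[col]][idx] <- rowSums(Slag * Hk)
    }
    out$surv[idx] <- Smat[, ncol(Smat)]
  }
  out
}

#' Likelihood-ratio comparison of the base and deep supermodels
#'
#' Compares the infection-cause partial likelihoods of two nested
#' supermodels whose specifications differ only by the CNN risk score
#' (one added parameter).
#'
#' @param base,deep `lmcr_supermodel` fits on the same rows (bare
#'   infection-cause `cause_specific_fit` objects are also accepted).
#' @return list(statistic, df, p_value).
#' @export
lr_test <- function(base, deep) {
  b <- if (inherits(base, "cause_specific_fit")) base else base$fits$infection
  d <- if (inherits(deep, "cause_specific_fit")) deep else deep$fits$infection
  extra <- setdiff(d$design_columns, b$design_columns)
  if (!identical(sort(c(b$design_columns, "cnn_score")),
                 sort(d$design_columns)) ||
      !identical(extra, "cnn_score")) {
    stop("models are not nested base + cnn_score", call. = FALSE)
  }
  if (b$n != d$n || b$n_events != d$n_events) {
    stop("base and deep models were not fitted on the same rows", call. = FALSE)
  }
  stat <- max(0, 2 * (d$loglik - b$loglik))
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Wald chi-square statistics of a cause-specific fit
#'
#' @param fit a `cause_specific_fit`.
#' @return named numeric vector of \eqn{(\hat\beta/SE)^2}, one per
#'   covariate, in the fit's covariate order.
#' @export
wald_chi2 <- function(fit) {
  stopifnot(inherits(fit, "cause_specific_fit"))
  if (any(!is.finite(fit$se)) || any(fit$se == 0)) {
    stop("singular covariance; cannot compute Wald statistics for: ",
         paste(names(fit$coef)[!is.finite(fit$se) | fit$se == 0],
               collapse = ", "), call. = FALSE)
  }
  (fit$coef / fit$se)^2
}

#' Supermodel with known constant cause-specific hazards
#'
#' Builds an `lmcr_supermodel` whose baseline cumulative hazards are the
#' straight lines \eqn{\Lambda_k(u) = \lambda_k u} discretised on a fine
#' grid, with no covariates. Used to validate CIF predictions against the
#' closed-form competing-exponential solution
#' \eqn{F_k(w) = \lambda_k/\lambda_{tot}\,(1 - e^{-\lambda_{tot} w})}.
#'
#' @param lambda_inf,lambda_death,lambda_disch hazards per hour.
#' @param horizon_h window length in hours.
#' @param step_h discretisation step of the baseline grid.
#' @return An `lmcr_supermodel` with empty coefficient vectors.
#' @export
supermodel_from_constant_hazards <- function(lambda_inf, lambda_death,
                                             lambda_disch, horizon_h = 48,
                                             step_h = 0.1) {
  times <- seq(step_h, horizon_h, by = step_h)
  mk <- function(cause, lam) {
    structure(list(cause = cause, coef = numeric(0),
                   vcov = matrix(0, 0, 0), se = numeric(0),
                   baseline = data.frame(time = times, cumhaz = lam * times,
                                         stratum = "pooled"),
                   baseline_mode = "pooled",
                   loglik_null = NA_real_, loglik = NA_real_,
                   n = 0L, n_events = 0L, centers = numeric(0),
                   ranges = matrix(numeric(0), 2, 0), iter = 0L,
                   converged = TRUE, design_columns = character(0)),
              class = "cause_specific_fit")
  }
  structure(list(fits = list(infection = mk("infection", lambda_inf),
                             death = mk("death", lambda_death),
                             discharge = mk("discharge", lambda_disch)),
                 spec = covariate_spec(character(0), landmark_terms = FALSE),
                 baseline_mode = "pooled", horizon_h = horizon_h),
            class = "lmcr_supermodel")
}
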