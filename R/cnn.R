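#' Configuration of the 1-D convolutional vital-sign network
#'
#' The network maps a 5-channel window of 1-minute vital signs ending at
#' a landmark to a probability of infection onset within the prediction
#' window. It consists of five blocks of three hidden layers each
#' (same-padding 1-D convolution with ReLU, max-pooling, dropout),
#' followed by flattening and a fully-connected output layer with a
#' sigmoid activation. Training uses Adam on a class-weighted binary
#' cross-entropy with early stopping on a validation split.
#'
#' @param kernel convolution kernel size (odd).
#' @param filters integer vector of length 5: filters per block.
#' @param pool max-pooling size per block.
#' @param dropout dropout rate after each pooling layer.
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param window_minutes length of the input window in minutes.
#' @param downsample average every `downsample` consecutive minutes
#'   before feeding the network (1 = raw 1-minute resolution).
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(kernel = 7, filters = c(16, 16, 32, 32, 64),
                       pool = 2, dropout = 0.2, lr = 1e-3, batch = 64,
                       epochs = 30, patience = 3, window_minutes = 480,
                       downsample = 1) {
  stopifnot(length(filters) == 5, kernel %% 2 == 1, pool >= 2,
            dropout >= 0, dropout < 1, window_minutes %% downsample == 0)
  t_in <- window_minutes / downsample
  if (floor(t_in / pool^5) < 1) {
    stop("input length ", t_in, " too short for 5 pooling layers", call. = FALSE)
  }
  structure(list(n_blocks = 5L, block_layers = c("conv", "pool", "dropout"),
                 output = "dense_sigmoid",
                 kernel = as.integer(kernel), filters = as.integer(filters),
                 pool = as.integer(pool), dropout = dropout, lr = lr,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 window_minutes = as.integer(window_minutes),
                 downsample = as.integer(downsample)),
            class = "cnn_config")
}

.vital_channels <- c("hr", "map", "pp", "rr", "spo2")

#' Extract and clean one vital-sign window
#'
#' Returns the 5 x T matrix of the window `[t_lm - window_minutes, t_lm)`
#' at 1-minute resolution. Gaps of at most 5 minutes are filled by linear
#' interpolation, longer gaps by carry-forward of the last observed
#' value, and leading gaps by the within-window channel median (falling
#' back to the population channel baseline when a channel is entirely
#' missing). The gap mask marks every originally missing minute.
#'
#' @param stream a vital stream (list with `minute` and a T x 5 `values`
#'   matrix) as produced by [simulate_cohort()].
#' @param t_lm landmark time in hours.
#' @param window_minutes window length.
#' @return list(values = 5 x T matrix, gap_mask = 5 x T logical).
#' @export
extract_window <- function(stream, t_lm, window_minutes = 480) {
  miss_ch <- setdiff(.vital_channels, colnames(stream$values))
  if (length(miss_ch)) {
    stop("stream is missing channel(s): ", paste(miss_ch, collapse = ", "),
         call. = FALSE)
  }
  end_min <- round(t_lm * 60)
  want <- seq(end_min - window_minutes, end_min - 1L)
  pos <- match(want, stream$minute)
  raw <- matrix(NA_real_, nrow = length(.vital_channels),
                ncol = window_minutes,
                dimnames = list(.vital_channels, NULL))
  ok <- !is.na(pos)
  for (ch in .vital_channels) raw[ch, ok] <- stream$values[pos[ok], ch]
  gap_mask <- is.na(raw)
  vals <- raw
  for (ch in .vital_channels) {
    x <- vals[ch, ]
    if (anyNA(x)) {
      x <- zoo::na.approx(x, na.rm = FALSE, maxgap = 5)
      x <- zoo::na.locf(x, na.rm = FALSE)
      if (anyNA(x)) {
        fill <- stats::median(x, na.rm = TRUE)
        if (is.na(fill)) fill <- .vital_baselines[[ch]]
        x[is.na(x)] <- fill
      }
    }
    vals[ch, ] <- x
  }
  list(values = vals, gap_mask = gap_mask)
}

#' Extract the vital windows for a set of landmark rows
#'
#' @param bundle an `icu_cohort` with vital streams.
#' @param keys data.frame with `admission_id` and `t_lm` (one window per
#'   row).
#' @param window_minutes window length in minutes.
#' @return 3-d array (5 channels x window_minutes x nrow(keys)).
#' @export
build_vital_windows <- function(bundle, keys, window_minutes = 480) {
  if (is.null(bundle$vitals)) {
    stop("bundle was simulated without vital streams", call. = FALSE)
  }
  id_map <- match(keys$admission_id,
                  vapply(bundle$vitals, `[[`, "", "admission_id"))
  arr <- array(NA_real_, c(length(.vital_channels), window_minutes,
                           nrow(keys)))
  dimnames(arr)[[1]] <- .vital_channels
  for (i in seq_len(nrow(keys))) {
    arr[, , i] <- extract_window(bundle$vitals[[id_map[i]]], keys$t_lm[i],
                                 window_minutes)$values
  }
  arr
}

## channel-wise standardisation + block-mean downsampling
.prep_windows <- function(windows, config, constants) {
  d <- dim(windows)
  if (config$downsample > 1L) {
    t_out <- d[2] %/% config$downsample
    w2 <- array(0, c(d[1], t_out, d[3]))
    idx <- rep(seq_len(t_out), each = config$downsample)
    for (c_i in seq_len(d[1])) {
      m <- windows[c_i, seq_len(t_out * config$downsample), , drop = FALSE]
      dim(m) <- c(t_out * config$downsample, d[3])
      w2[c_i, , ] <- rowsum(m, idx) / config$downsample
    }
    windows <- w2
    d <- dim(windows)
  }
  for (c_i in seq_len(d[1])) {
    windows[c_i, , ] <- (windows[c_i, , ] - constants$mean[c_i]) /
      constants$sd[c_i]
  }
  windows
}

.channel_constants <- function(windows) {
  mu <- apply(windows, 1, mean)
  sd_ <- apply(windows, 1, stats::sd)
  sd_[sd_ == 0] <- 1
  list(mean = mu, sd = sd_)
}

.fit_cnn_once <- function(windows, labels, config, val_idx, seed) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  w1 <- length(labels) / (2 * n_pos)
  w0 <- length(labels) / (2 * n_neg)
  .cnn_train_cpp(windows, as.numeric(labels), config$kernel,
                 config$filters, config$pool, config$dropout, config$lr,
                 config$batch, config$epochs, config$patience, w0, w1,
                 as.integer(val_idx - 1L), as.integer(seed))
}

#' Train the CNN risk score with cross-validated model selection
#'
#' Every candidate configuration is evaluated by the mean validation AUC
#' over k patient-grouped folds; the best configuration (ties broken by
#' grid order) is refitted on all training data with an internal
#' early-stopping split. Channel standardisation constants are computed
#' from training data only and stored with the model.
#'
#' @param windows 5 x T x N array from [build_vital_windows()].
#' @param labels binary vector: infection within the prediction window.
#' @param grid list of [cnn_config()] candidates.
#' @param groups patient identifiers used to keep all windows of one
#'   patient in the same fold.
#' @param k number of selection folds.
#' @param seed integer seed governing folds, initialisation, shuffling
#'   and dropout.
#' @return list of class `cnn_model`: weights, config, preprocessing
#'   constants, selection report and training-group fingerprint.
#' @export
train_cnn <- function(windows, labels, grid = list(cnn_config()),
                      groups = NULL, k = 5, seed = 1L) {
  labels <- as.integer(labels)
  n <- dim(windows)[3]
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L) {
    stop("labels are single-class; cannot train", call. = FALSE)
  }
  if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
  if (is.null(groups)) groups <- as.character(seq_len(n))
  plan <- fold_plan(groups, k = k, seed = derive_seed(seed, "cnn_folds"))
  fold <- plan$fold[match(groups, plan$patient_id)]

  report <- data.frame(config = seq_along(grid), mean_auc = NA_real_)
  fold_auc <- matrix(NA_real_, length(grid), k)
  for (g in if (length(grid) == 1L) integer(0) else seq_along(grid)) {
    cfg <- grid[[g]]
    for (f in seq_len(k)) {
      tr <- which(fold != f); va <- which(fold == f)
      if (length(unique(labels[tr])) < 2L || length(unique(labels[va])) < 2L) next
      const <- .channel_constants(windows[, , tr, drop = FALSE])
      Xall <- .prep_windows(windows, cfg, const)
      fit <- .fit_cnn_once(Xall[, , c(tr, va), drop = FALSE],
                           labels[c(tr, va)], cfg,
                           val_idx = length(tr) + seq_along(va),
                           seed = derive_seed(seed, sprintf("cv_%d_%d", g, f)))
      p <- .cnn_predict_cpp(fit$weights, Xall[, , va, drop = FALSE],
                            cfg$kernel, cfg$filters, cfg$pool)
      fold_auc[g, f] <- auc_score(p, labels[va])
    }
    report$mean_auc[g] <- mean(fold_auc[g, ], na.rm = TRUE)
  }
  ## a single-config grid needs no selection pass
  best <- if (length(grid) == 1L) 1L else which.max(report$mean_auc)
  cfg <- grid[[best]]

  ## refit on everything with an internal grouped early-stopping split
  const <- .channel_constants(windows)
  Xall <- .prep_windows(windows, cfg, const)
  hold <- fold == ((best %% k) + 1L)
  ord <- c(which(!hold), which(hold))
  fit <- .fit_cnn_once(Xall[, , ord, drop = FALSE], labels[ord], cfg,
                       val_idx = sum(!hold) + seq_len(sum(hold)),
                       seed = derive_seed(seed, "refit"))
  structure(list(weights = fit$weights, config = cfg, constants = const,
                 selection = cbind(report, fold_auc = I(fold_auc)),
                 best_config = best,
                 best_epoch = fit$best_epoch,
                 fingerprint = derive_seed(0, paste(sort(unique(groups)),
                                                    collapse = "|"))),
            class = "cnn_model")
}

#' Score vital-sign windows with a trained CNN
#'
#' Scoring uses the preprocessing constants stored in the model, never
#' statistics of the scored data, and is deterministic (dropout off).
#'
#' @param model a `cnn_model`.
#' @param windows 5 x T x N array (or a single 5 x T matrix).
#' @return numeric vector of probabilities in (0, 1).
#' @export
score_windows <- function(model, windows) {
  if (length(dim(windows)) == 2L) {
    windows <- array(windows, c(dim(windows), 1L))
  }
  if (dim(windows)[2] != model$config$window_minutes) {
    stop("window length ", dim(windows)[2], " does not match model input ",
         model$config$window_minutes, call. = FALSE)
  }
  X <- .prep_windows(windows, model$config, model$constants)
  p <- .cnn_predict_cpp(model$weights, X, model$config$kernel,
                        model$config$filters, model$config$pool)
  pmin(1 - 1e-12, pmax(1e-12, as.numeric(p)))
}

#' @rdname score_windows
#' @param window a single 5 x T matrix.
#' @export
score_window <- function(model, window) score_windows(model, window)[1]

#' Save / load a CNN model as a single JSON archive
#'
#' @param model a `cnn_model`.
#' @param path file path.
#' @export
save_cnn_model <- function(model, path) {
  obj <- list(weights = model$weights,
              config = unclass(model$config),
              constants = model$constants,
              best_epoch = model$best_epoch,
              fingerprint = model$fingerprint)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_cnn_model
#' @export
load_cnn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- cnn_config(kernel = cfg$kernel, filters = cfg$filters,
                       pool = cfg$pool, dropout = cfg$dropout, lr = cfg$lr,
                       batch = cfg$batch, epochs = cfg$epochs,
                       patience = cfg$patience,
                       window_minutes = cfg$window_minutes,
                       downsample = cfg$downsample)
  weights <- list(conv_w = lapply(obj$weights$conv_w, as.matrix),
                  conv_b = lapply(obj$weights$conv_b, as.numeric),
                  dense_w = as.numeric(obj$weights$dense_w),
                  dense_b = as.numeric(obj$weights$dense_b))
  structure(list(weights = weights, config = config,
                 constants = list(mean = as.numeric(obj$constants$mean),
                                  sd = as.numeric(obj$constants$sd)),
                 selection = NULL, best_config = NA_integer_,
                 best_epoch = obj$best_epoch,
                 fingerprint = obj$fingerprint),
            class = "cnn_model")
}
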