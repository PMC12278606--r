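#' @useDynLib icualert, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a module-specific seed from a master seed
#'
#' Seeds for the different stochastic stages (cohort simulation, fold
#' assignment, network initialisation, permutation importance) are derived
#' by hashing the master seed together with a stage label, so that adding
#' a stage never shifts the random streams of the others.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %/% 1 + 1)
}

## rank-based AUC (Mann-Whitney); ties handled by midranks
auc_score <- function(score, label) {
  label <- as.integer(label)
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## weighted quantile-free median helper that tolerates empty input
median_or_na <- function(x) if (length(x) == 0L) NA_real_ else stats::median(x)

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("`%s` must be a single probability strictly inside (0, 1)", name),
         call. = FALSE)
  }
}
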