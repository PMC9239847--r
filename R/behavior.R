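## Brain-behavior link: partial regression of word-recognition performance
## on tracking estimates with SNR-proxy confounds, BIC-based Bayes factors,
## and Velleman-Welsch partial residuals.

#' Z-score a variable across participants
#'
#' Mean 0, s.d. 1 with the 1/(n-1) convention.
#'
#' @param values numeric vector (>= 3 values, nonzero variance).
#' @param name variable name used in error messages.
#' @return standardized numeric vector.
#' @export
zscore_across_participants <- function(values, name = deparse(substitute(values))) {
  if (length(values) < 3L) stop("zscore_across_participants: need at least 3 participants", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop(sprintf("zscore_across_participants: '%s' has zero variance", name), call. = FALSE)
  (values - mean(values)) / s
}

#' Z-score per band, then average across bands
#'
#' Confound variables measured per frequency band are standardized within
#' each band and then averaged across bands, yielding one SNR-proxy value
#' per participant.
#'
#' @param values numeric vector (participant-major) or matrix
#'   (participants x bands).
#' @param bands band labels (one per column/value).
#' @return numeric vector, one value per participant.
#' @export
zscore_bands_average <- function(values, bands = NULL) {
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  z <- apply(values, 2L, zscore_across_participants, name = "confound")
  if (!is.matrix(z)) z <- matrix(z, ncol = ncol(values))
  rowMeans(z)
}

#' Partial regression of performance on tracking variables
#'
#' Ordinary least squares of the z-scored outcome on all z-scored target
#' variables and (pre-standardized) confounds jointly; per-predictor
#' t-based p-values, overall R-squared, and a BIC-based Bayes factor for
#' the target set (full model vs the model without the targets).
#'
#' @param data data.frame, one row per participant.
#' @param outcome name of the outcome column (percent correct).
#' @param targets character vector of target predictor columns (z-scored
#'   internally).
#' @param confounds character vector of confound columns (z-scored
#'   internally; use [zscore_bands_average()] upstream for per-band
#'   confounds, in which case set `confounds_standardized = TRUE`).
#' @param confounds_standardized if TRUE the confound columns are used as
#'   given (already standardized/averaged).
#' @return object of class `ct_regression`: list with `coefficients`
#'   (data.frame term/beta/se/t/p), `r_squared`, `bf_targets`, `fit`,
#'   `reduced_fit`, `data` (the standardized design).
#' @export
partial_regression <- function(data, outcome, targets, confounds = character(0),
                               confounds_standardized = FALSE) {
  stopifnot(outcome %in% names(data), all(targets %in% names(data)),
            all(confounds %in% names(data)))
  n <- nrow(data)
  preds <- c(targets, confounds)
  if (n <= length(preds) + 1L)
    stop("partial_regression: need n_participants > n_predictors + 1", call. = FALSE)
  zd <- data.frame(row.names = seq_len(n))
  zd[[outcome]] <- zscore_across_participants(data[[outcome]], outcome)
  for (v in targets) zd[[v]] <- zscore_across_participants(data[[v]], v)
  for (v in confounds)
    zd[[v]] <- if (confounds_standardized) data[[v]] else zscore_across_participants(data[[v]], v)
  X <- as.matrix(zd[, preds, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    drop_idx <- setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)])
    stop("partial_regression: rank-deficient design; collinear columns: ",
         paste(c("(intercept)", preds)[drop_idx], collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste(outcome, "~", paste(preds, collapse = " + ")))
  fit <- stats::lm(fml, data = zd)
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      beta = sm$coefficients[, 1],
                      se = sm$coefficients[, 2],
                      t = sm$coefficients[, 3],
                      p = sm$coefficients[, 4],
                      row.names = NULL)
  red_fml <- stats::as.formula(paste(outcome, "~",
                                     if (length(confounds)) paste(confounds, collapse = " + ") else "1"))
  reduced <- stats::lm(red_fml, data = zd)
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 bf_targets = bayes_factor_bic(fit, reduced),
                 fit = fit, reduced_fit = reduced, data = zd,
                 targets = targets, confounds = confounds, outcome = outcome),
            class = "ct_regression")
}

#' @export
print.ct_regression <- function(x, ...) {
  cat(sprintf("<ct_regression> %s ~ %s | R^2 = %.3f, BF(targets) = %.3g\n",
              x$outcome, paste(c(x$targets, x$confounds), collapse = " + "),
              x$r_squared, x$bf_targets))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' BIC-based Bayes factor between nested linear models
#'
#' BF = exp((BIC_reduced - BIC_full) / 2); BF > 1 favors the full model.
#'
#' @param full_model,reduced_model fitted `lm` objects on identical data,
#'   the reduced model nested in the full one.
#' @return Bayes factor (positive scalar).
#' @export
bayes_factor_bic <- function(full_model, reduced_model) {
  tf <- attr(stats::terms(full_model), "term.labels")
  tr <- attr(stats::terms(reduced_model), "term.labels")
  if (!all(tr %in% tf))
    stop("bayes_factor_bic: models are not nested", call. = FALSE)
  if (stats::nobs(full_model) != stats::nobs(reduced_model))
    stop("bayes_factor_bic: models fit on different data", call. = FALSE)
  exp((stats::BIC(reduced_model) - stats::BIC(full_model)) / 2)
}

#' Partial residuals for a target predictor
#'
#' Velleman-Welsch partial residuals: full-model residuals plus the
#' target's fitted contribution beta * x.  Regressing them on the target
#' recovers the model coefficient exactly.
#'
#' @param result a `ct_regression` from [partial_regression()] (or a
#'   fitted `lm`).
#' @param target name of a predictor in the model.
#' @return data.frame with `x` (the target values) and `partial_residual`.
#' @export
partial_residuals <- function(result, target) {
  fit <- if (inherits(result, "ct_regression")) result$fit else result
  cf <- stats::coef(fit)
  if (!target %in% names(cf))
    stop(sprintf("partial_residuals: '%s' is not a model predictor", target), call. = FALSE)
  x <- stats::model.matrix(fit)[, target]
  data.frame(x = x,
             partial_residual = stats::residuals(fit) + cf[[target]] * x)
}
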