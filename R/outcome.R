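#' Weighted pooled logistic regression
#'
#' Maximises the weight-multiplied Bernoulli log-likelihood over stacked
#' person-wave observations by iteratively reweighted least squares.
#' This is the outcome model of the double-robust marginal structural
#' estimator: the stabilised weights enter as per-observation
#' multipliers of the log-likelihood, and covariate adjustment in the
#' same model provides the second chance at correct specification.
#' Deterministic given its inputs.
#'
#' @param design Numeric matrix (or data frame coerced with
#'   [data.matrix()]) including an intercept column if one is wanted.
#' @param y Binary response vector (0/1).
#' @param w Positive weights (default all 1). Rescaling all weights by a
#'   constant leaves the coefficients unchanged.
#' @param tol Convergence tolerance on the relative deviance change.
#' @param maxit Maximum IRLS iterations.
#' @return Object of class `msm_fit`: named `coefficients`, `converged`,
#'   `iterations`, `score_norm`, `loglik`, and the linear predictor
#'   `eta`.
#' @export
#' @examples
#' X <- cbind(1, c(0, 0, 1, 1, 0, 1))
#' y <- c(0, 1, 1, 1, 0, 1)
#' weighted_logistic(X, y)
weighted_logistic <- function(design, y, w = NULL, tol = 1e-10,
                              maxit = 100L) {
  X <- if (is.data.frame(design)) data.matrix(design) else as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (is.null(w)) w <- rep(1, length(y))
  if (any(w <= 0)) stop("weights must be > 0", call. = FALSE)
  if (nrow(X) != length(y) || length(w) != length(y)) {
    stop("design, y and w must have matching lengths", call. = FALSE)
  }
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate outcome: all responses identical, the intercept ",
         "diverges (separation)", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  f <- cpp_irls(X, seq_len(ncol(X)) - 1L, y, w, tol = tol,
                maxit = as.integer(maxit))
  if (isTRUE(f$separated) || !isTRUE(f$converged)) {
    culprit <- colnames(X)[which.max(abs(f$coef))]
    stop("logistic fit did not converge after ", f$iterations,
         " iterations (largest coefficient on '", culprit,
         "'); the data may be separated or degenerate", call. = FALSE)
  }
  mu <- plogis(drop(f$eta))
  if (all(mu[y == 1] > 1 - 1e-8) && all(mu[y == 0] < 1e-8)) {
    stop("perfect separation: fitted probabilities are all 0 or 1",
         call. = FALSE)
  }
  structure(list(
    coefficients = setNames(drop(f$coef), colnames(X)),
    converged = f$converged, iterations = f$iterations,
    score_norm = f$score_norm, loglik = f$loglik, eta = drop(f$eta)
  ), class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("<msm_fit> weighted pooled logistic,", length(x$coefficients),
      "coefficients,", x$iterations, "IRLS iterations\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Marginal standardisation of a fitted outcome model
#'
#' Predicts every observation twice, with the exposure forced to 1 then
#' to 0 while all other columns (including mediator columns in CDE mode)
#' keep their observed values, and weight-averages the predicted risks.
#' Reports the marginal odds ratio, the absolute risk difference in
#' percentage points, the standardised prevalence in the unexposed, and
#' the population attributable fraction computed from the observed
#' (weighted) prevalence and the standardised unexposed prevalence.
#'
#' @param fit An `msm_fit` from [weighted_logistic()].
#' @param design The design matrix the model was fitted on.
#' @param exposure Name (or index) of the exposure column in `design`.
#' @param w Weights used for averaging (typically the fit weights).
#' @param y Optional observed outcome; enables the PAF.
#' @return Object of class `marginal_estimates`.
#' @export
marginal_standardise <- function(fit, design, exposure, w = NULL, y = NULL) {
  X <- if (is.data.frame(design)) data.matrix(design) else as.matrix(design)
  if (is.character(exposure)) {
    exposure <- match(exposure, colnames(X))
    if (is.na(exposure)) stop("exposure column not found in design",
                              call. = FALSE)
  }
  if (is.null(w)) w <- rep(1, nrow(X))
  beta <- fit$coefficients
  a <- X[, exposure]
  eta_obs <- drop(X %*% beta)
  b_a <- beta[exposure]
  r1 <- weighted.mean(plogis(eta_obs + (1 - a) * b_a), w)
  r0 <- weighted.mean(plogis(eta_obs - a * b_a), w)
  paf_pct <- NA_real_
  prev_total <- NA_real_
  if (!is.null(y)) {
    prev_total <- weighted.mean(y, w)
    paf_pct <- paf(prev_total, r0)
  }
  structure(list(
    risk_exposed = r1, risk_unexposed = r0,
    odds_ratio = (r1 / (1 - r1)) / (r0 / (1 - r0)),
    risk_difference_pp = 100 * (r1 - r0),
    prevalence_unexposed_pp = 100 * r0,
    prev_total = prev_total, paf_pct = paf_pct,
    conditional_or = exp(unname(b_a)), n = nrow(X)
  ), class = "marginal_estimates")
}

#' @export
print.marginal_estimates <- function(x, ...) {
  cat(sprintf("<marginal_estimates> OR %.3f  RD %.2f pp  unexposed %.2f%%\n",
              x$odds_ratio, x$risk_difference_pp, x$prevalence_unexposed_pp))
  if (!is.na(x$paf_pct)) cat(sprintf("  PAF %.2f%%\n", x$paf_pct))
  invisible(x)
}

#' Population attributable fraction
#'
#' `100 * (prev_total - prev_unexposed) / prev_total`: the percentage of
#' the outcome burden in the total population attributable to the
#' exposure. Negative for protective exposures.
#'
#' @param prev_total Outcome prevalence in the total population (> 0).
#' @param prev_unexposed Prevalence in the unexposed.
#' @return PAF in percent.
#' @export
#' @examples
#' paf(0.20, 0.18) # 10
paf <- function(prev_total, prev_unexposed) {
  if (any(prev_total <= 0)) {
    stop("prev_total must be > 0", call. = FALSE)
  }
  100 * (prev_total - prev_unexposed) / prev_total
}
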