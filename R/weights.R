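new_weight_set <- function(sw_a, sw_m, mode, models, truncation = NULL) {
  w <- sw_a * sw_m
  structure(list(
    sw_a = sw_a, sw_m = sw_m, w = w, mode = mode, models = models,
    truncation = truncation,
    summary = c(mean = mean(w), max = max(w), min = min(w),
                fraction_truncated = if (is.null(truncation)) 0
                else truncation$fraction)
  ), class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("<weight_set> mode:", x$mode, " n:", length(x$w), "\n")
  cat(sprintf("  mean %.4f  min %.4f  max %.4f  truncated %.2f%%\n",
              x$summary["mean"], x$summary["min"], x$summary["max"],
              100 * x$summary["fraction_truncated"]))
  invisible(x)
}

#' Stabilised inverse-probability-of-treatment weights for the exposure
#'
#' Fits the exposure (non-employment) denominator model on the baseline
#' confounders, age and squared age, and every lag-1 covariate
#' (including lagged exposure, lagged log income, lagged caseness and
#' lagged MCS), and a marginal (intercept-only) stabilising numerator,
#' so the weighted pseudo-population balances every covariate in the
#' adjustment set. The per-observation weight is
#' the ratio of the numerator to the denominator probability of the
#' exposure level actually observed. These weights aim to create
#' exchangeability between exposed and unexposed person-waves, as would
#' hold after randomisation.
#'
#' @param table Analysis table from [build_analysis_table()], complete
#'   on all model variables.
#' @param roles A [variable_roles()] object.
#' @return A `weight_set` with `sw_a` the stabilised exposure weights,
#'   `sw_m = 1` (total-effect mode), and `w = sw_a`.
#' @export
fit_exposure_weights <- function(table, roles = variable_roles()) {
  design <- build_design(table, roles)
  fit_exposure_weights_design(design)
}

fit_exposure_weights_design <- function(design) {
  f_den <- fit_logit_set(design, "den_a", label = "exposure denominator")
  f_num <- fit_logit_set(design, "num_a", label = "exposure numerator")
  a <- design$a
  p_den <- ifelse(a == 1, plogis(f_den$eta), 1 - plogis(f_den$eta))
  p_num <- ifelse(a == 1, plogis(f_num$eta), 1 - plogis(f_num$eta))
  new_weight_set(sw_a = p_num / p_den, sw_m = rep(1, length(a)),
                 mode = "TE", models = list(den = f_den, num = f_num))
}

#' Mediator (income-density) weights for the controlled direct effect
#'
#' Blocks the pathway from non-employment to mental health operating via
#' concurrent income by adding a second stabilised weight: the ratio of
#' two conditional normal densities of concurrent log income, the
#' numerator conditioning on the exposure and baseline confounders only,
#' the denominator additionally on age and every lag-1 covariate. Both
#' conditional means are linear regressions with fitted residual
#' standard deviations. Relative poverty receives no separate weight:
#' given the sample median it is a deterministic function of income and
#' enters the CDE outcome model as a covariate instead.
#'
#' @inheritParams fit_exposure_weights
#' @param exposure_weights Optional `weight_set` from
#'   [fit_exposure_weights()]; fitted afresh when omitted.
#' @return A `weight_set` in CDE mode with `w = sw_a * sw_m`.
#' @export
fit_mediator_weights <- function(table, roles = variable_roles(),
                                 exposure_weights = NULL) {
  design <- build_design(table, roles)
  if (is.null(exposure_weights)) {
    exposure_weights <- fit_exposure_weights_design(design)
  }
  fit_mediator_weights_design(design, exposure_weights)
}

fit_mediator_weights_design <- function(design, exposure_weights) {
  w1 <- rep(1, nrow(design$X))
  f_den <- cpp_wls(design$X, design$sets$mden - 1L, design$m, w1)
  f_num <- cpp_wls(design$X, design$sets$mnum - 1L, design$m, w1)
  if (!isTRUE(f_den$ok) || !isTRUE(f_num$ok)) {
    stop("mediator weight regression is rank deficient", call. = FALSE)
  }
  if (f_den$sigma < 1e-8 || f_num$sigma < 1e-8) {
    stop("mediator density is degenerate (residual s.d. ~ 0)", call. = FALSE)
  }
  dnum <- stats::dnorm(design$m, f_num$eta, f_num$sigma)
  dden <- stats::dnorm(design$m, f_den$eta, f_den$sigma)
  sw_m <- dnum / dden
  new_weight_set(sw_a = exposure_weights$sw_a, sw_m = sw_m, mode = "CDE",
                 models = c(exposure_weights$models,
                            list(mden = f_den, mnum = f_num)))
}

#' Truncate extreme weights at empirical percentiles
#'
#' Clips the combined weight to its `lower_pct` and `upper_pct`
#' empirical percentiles and records the fraction of observations
#' affected. Truncation is off by default in the pipeline (the primary
#' analysis uses untruncated weights); 1/99 is a reasonable choice for
#' small samples.
#'
#' @param ws A `weight_set`.
#' @param lower_pct,upper_pct Percentiles in (0, 50) and (50, 100).
#' @return The `weight_set` with clipped `w` and truncation metadata.
#' @export
truncate_weights <- function(ws, lower_pct = 1, upper_pct = 99) {
  if (!(lower_pct > 0 && lower_pct < 50 && upper_pct > 50 && upper_pct < 100)) {
    stop("truncation percentiles must satisfy 0 < lower < 50 < upper < 100",
         call. = FALSE)
  }
  bounds <- quantile(ws$w, c(lower_pct, upper_pct) / 100, names = FALSE)
  clipped <- pmin(pmax(ws$w, bounds[1]), bounds[2])
  frac <- mean(clipped != ws$w)
  ws$w <- clipped
  ws$truncation <- list(lower_pct = lower_pct, upper_pct = upper_pct,
                        bounds = bounds, fraction = frac)
  ws$summary <- c(mean = mean(clipped), max = max(clipped),
                  min = min(clipped), fraction_truncated = frac)
  ws
}

weighted_mean_var <- function(x, w) {
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)
  c(mean = m, var = v)
}

#' Standardised mean difference between exposure groups
#'
#' For continuous covariates: `|m1 - m0| / sqrt((v1 + v0) / 2)` with
#' (weighted) group means and variances. Binary covariates use
#' proportions with variance `p (1 - p)`; categorical covariates expand
#' to one indicator (and one SMD) per level. Returns `Inf` when the
#' pooled variance is zero but the means differ.
#'
#' @param values Numeric, logical, factor, or character vector.
#' @param group Binary group indicator (two levels, both non-empty).
#' @param weights Optional non-negative weights (default: unweighted).
#' @return A single SMD, or a named vector of per-level SMDs for a
#'   categorical input.
#' @export
#' @examples
#' smd(c(1, 2, 3, 4), c(0, 0, 1, 1))
smd <- function(values, group, weights = NULL) {
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g[!is.na(g)])) != 2) {
    stop("group must have exactly two non-empty levels", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(values))
  if (is.factor(values) || is.character(values)) {
    f <- factor(values)
    if (nlevels(f) > 2) {
      out <- vapply(levels(f), function(lv) {
        smd_binary(as.numeric(f == lv), g, weights)
      }, numeric(1))
      return(out)
    }
    values <- as.numeric(f) - 1
    return(smd_binary(values, g, weights))
  }
  values <- as.numeric(values)
  if (all(values %in% c(0, 1))) return(smd_binary(values, g, weights))
  s1 <- weighted_mean_var(values[g == 1], weights[g == 1])
  s0 <- weighted_mean_var(values[g == 0], weights[g == 0])
  pooled <- sqrt((s1["var"] + s0["var"]) / 2)
  d <- abs(s1["mean"] - s0["mean"])
  unname(if (pooled == 0) ifelse(d == 0, 0, Inf) else d / pooled)
}

smd_binary <- function(values, g, weights) {
  p1 <- sum(weights[g == 1] * values[g == 1]) / sum(weights[g == 1])
  p0 <- sum(weights[g == 0] * values[g == 0]) / sum(weights[g == 0])
  pooled <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
  d <- abs(p1 - p0)
  unname(if (pooled == 0) ifelse(d == 0, 0, Inf) else d / pooled)
}

#' Covariate balance before and after weighting
#'
#' Computes the standardised mean difference of every confounder in the
#' adjustment set (baseline confounders, age, squared age, and all
#' lag-1 covariates) between exposure groups, unweighted and weighted,
#' with the conventional thresholds: SMD < 0.1 negligible difference,
#' SMD < 0.2 reasonable balance. The output is a plain table suitable
#' for a love plot.
#'
#' @param table Analysis table.
#' @param roles A [variable_roles()] object.
#' @param ws A `weight_set` whose combined weight `w` is applied.
#' @param thresholds Length-2 numeric, negligible / reasonable.
#' @return A data frame of class `balance_report` with columns
#'   `covariate`, `smd_pre`, `smd_post`, `balance_pre`, `balance_post`.
#' @export
balance_report <- function(table, roles = variable_roles(), ws,
                           thresholds = c(0.1, 0.2)) {
  covs <- c(roles$baseline, roles$age, "age_sq",
            intersect(lag_names(roles), names(table)))
  g <- table[[roles$exposure]]
  rows <- lapply(covs, function(cv) {
    pre <- smd(table[[cv]], g, NULL)
    post <- smd(table[[cv]], g, ws$w)
    nm <- if (length(pre) > 1) paste0(cv, ":", names(pre)) else cv
    data.frame(covariate = nm, smd_pre = unname(pre),
               smd_post = unname(post))
  })
  out <- do.call(rbind, rows)
  label <- function(x) {
    ifelse(x < thresholds[1], "negligible",
           ifelse(x < thresholds[2], "reasonable", "imbalanced"))
  }
  out$balance_pre <- label(out$smd_pre)
  out$balance_post <- label(out$smd_post)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("balance_report", "data.frame")
  out
}
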