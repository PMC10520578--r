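#' Percentage of the total effect mediated by income
#'
#' `100 * (TE - CDE) / TE`, the percentage attenuation of the total
#' effect once the pathway via income is blocked. Both inputs are
#' absolute risk differences in percentage points. The result may be
#' negative (inconsistent mediation) or exceed 100.
#'
#' @param te_rd Total-effect risk difference (percentage points), non-zero.
#' @param cde_rd Controlled-direct-effect risk difference (pp).
#' @return Percent mediation.
#' @export
#' @examples
#' percent_mediation(7.09, 6.08)
percent_mediation <- function(te_rd, cde_rd) {
  out <- ifelse(te_rd == 0, NA_real_, 100 * (te_rd - cde_rd) / te_rd)
  if (any(te_rd == 0)) {
    warning("percent mediation is undefined when the total effect is 0",
            call. = FALSE)
  }
  out
}

# Point estimation of TE and CDE on one design (complete data).
point_fits <- function(design, truncate = NULL) {
  ws_te <- fit_exposure_weights_design(design)
  if (!is.null(truncate)) {
    ws_te <- truncate_weights(ws_te, truncate[1], truncate[2])
  }
  f_te <- fit_logit_set(design, "out_te", y = design$y, w = ws_te$w,
                        label = "TE outcome model")
  X_te <- design$X[, design$sets$out_te, drop = FALSE]
  f_te$coefficients <- setNames(drop(f_te$coef), colnames(X_te))
  marg_te <- marginal_standardise(f_te, X_te, design$exp_pos_te,
                                  w = ws_te$w, y = design$y)
  ws_cde <- fit_mediator_weights_design(design, ws_te)
  if (!is.null(truncate)) {
    ws_cde <- truncate_weights(ws_cde, truncate[1], truncate[2])
  }
  f_cde <- fit_logit_set(design, "out_cde", y = design$y, w = ws_cde$w,
                         label = "CDE outcome model")
  X_cde <- design$X[, design$sets$out_cde, drop = FALSE]
  f_cde$coefficients <- setNames(drop(f_cde$coef), colnames(X_cde))
  marg_cde <- marginal_standardise(f_cde, X_cde, design$exp_pos_cde,
                                   w = ws_cde$w, y = design$y)
  list(ws_te = ws_te, ws_cde = ws_cde, f_te = f_te, f_cde = f_cde,
       marg_te = marg_te, marg_cde = marg_cde)
}

stat_names <- c("te_rd", "cde_rd", "pct_mediation", "or_te", "or_cde",
                "prev_unexp_te", "prev_unexp_cde", "paf_te", "paf_cde")

point_stats <- function(pf) {
  c(te_rd = pf$marg_te$risk_difference_pp,
    cde_rd = pf$marg_cde$risk_difference_pp,
    pct_mediation = percent_mediation(pf$marg_te$risk_difference_pp,
                                      pf$marg_cde$risk_difference_pp),
    or_te = pf$marg_te$odds_ratio,
    or_cde = pf$marg_cde$odds_ratio,
    prev_unexp_te = pf$marg_te$prevalence_unexposed_pp,
    prev_unexp_cde = pf$marg_cde$prevalence_unexposed_pp,
    paf_te = pf$marg_te$paf_pct,
    paf_cde = pf$marg_cde$paf_pct)
}

coerce_imputed <- function(imputed) {
  if (inherits(imputed, "imputation_set")) imputed$completed
  else if (is.data.frame(imputed)) list(imputed)
  else if (is.list(imputed)) imputed
  else stop("imputed must be an imputation_set, data frame, or list",
            call. = FALSE)
}

#' Estimate the total or controlled direct effect across imputed datasets
#'
#' For each completed dataset: build the stabilised exposure weights
#' (and, in CDE mode, the additional mediator weights), fit the weighted
#' pooled logistic outcome model (TE covariates: baseline plus the full
#' lagged set including lagged income; CDE adds concurrent log income
#' and poverty), and marginally standardise. Point estimates are pooled
#' by their mean across the datasets (odds ratios on the log scale).
#' Interval estimation belongs to the cluster bootstrap
#' ([run_mediation()]).
#'
#' @param imputed An `imputation_set`, a single data frame, or a list of
#'   completed analysis tables sharing one schema.
#' @param roles A [variable_roles()] object.
#' @param mode `"TE"` or `"CDE"`.
#' @param truncate Optional `c(lower_pct, upper_pct)` weight truncation.
#' @return Object of class `effect_estimate`.
#' @export
estimate_effect <- function(imputed, roles = variable_roles(),
                            mode = c("TE", "CDE"), truncate = NULL) {
  mode <- match.arg(mode)
  datasets <- coerce_imputed(imputed)
  per <- matrix(NA_real_, length(datasets), length(stat_names),
                dimnames = list(NULL, stat_names))
  n_ind <- n_obs <- NA_integer_
  for (i in seq_along(datasets)) {
    tab <- rederive_after_imputation(datasets[[i]])
    design <- build_design(tab, roles)
    pf <- tryCatch(point_fits(design, truncate), error = function(e) {
      stop("estimation failed on imputed dataset ", i, ": ",
           conditionMessage(e), call. = FALSE)
    })
    per[i, ] <- point_stats(pf)
    n_ind <- design$n_persons
    n_obs <- nrow(design$X)
  }
  pooled <- pool_effect_rows(per, mode)
  structure(c(pooled, list(mode = mode, n_individuals = n_ind,
                           n_observations = n_obs, per_dataset = per,
                           m = length(datasets))),
            class = "effect_estimate")
}

pool_effect_rows <- function(per, mode) {
  sel <- if (mode == "TE") {
    c(rd = "te_rd", or = "or_te", prev = "prev_unexp_te", paf = "paf_te")
  } else {
    c(rd = "cde_rd", or = "or_cde", prev = "prev_unexp_cde", paf = "paf_cde")
  }
  list(
    risk_difference_pp = pool_point_estimates(per[, sel["rd"]]),
    odds_ratio = exp(pool_point_estimates(log(per[, sel["or"]]))),
    prevalence_unexposed_pp = pool_point_estimates(per[, sel["prev"]]),
    paf_pct = pool_point_estimates(per[, sel["paf"]])
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  fmt_ci <- function(point, ci, digits = 2) {
    if (is.null(ci) || anyNA(ci)) sprintf("%.*f", digits, point)
    else sprintf("%.*f (%.*f-%.*f)", digits, point, digits, ci[1],
                 digits, ci[2])
  }
  cat("<effect_estimate>", x$mode, "\n")
  cat("  odds ratio:            ", fmt_ci(x$odds_ratio, x$or_ci), "\n")
  cat("  risk difference (pp):  ",
      fmt_ci(x$risk_difference_pp, x$rd_ci), "\n")
  cat("  unexposed prevalence:  ",
      fmt_ci(x$prevalence_unexposed_pp, x$prev_ci), "\n")
  cat("  PAF:                   ", sprintf("%.2f%%", x$paf_pct), "\n")
  invisible(x)
}

#' Cluster bootstrap interval for an arbitrary estimator
#'
#' Resamples persons (all of a person's waves move together) with
#' replacement, re-applies `estimator` to each resampled table, and
#' summarises the replicates: the bootstrap standard error is their
#' standard deviation and the confidence interval is
#' `point +/- z * se` (normal approximation), with percentile intervals
#' also returned. Replicates on which the estimator fails or returns
#' non-finite values are dropped and counted; more than 20% failures
#' attaches a warning.
#'
#' @param panel Table with a person identifier column.
#' @param estimator Function taking a table, returning a named numeric
#'   vector.
#' @param B Number of resamplings (default 1000).
#' @param seed Integer seed for the resampling.
#' @param id_col Person identifier column (default `"pid"`).
#' @param conf Confidence level (default 0.95).
#' @return List with `point`, `se`, `ci` (normal), `ci_percentile`,
#'   `replicates`, `n_failed`.
#' @export
bootstrap_interval <- function(panel, estimator, B = 1000L, seed = 1L,
                               id_col = "pid", conf = 0.95) {
  stopifnot(B >= 1)
  point <- estimator(panel)
  ids <- unique(panel[[id_col]])
  set.seed(seed)
  z <- qnorm(1 - (1 - conf) / 2)
  reps <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, names(point)))
  row_of <- split(seq_len(nrow(panel)), match(panel[[id_col]], ids))
  for (b in seq_len(B)) {
    take <- sample.int(length(ids), length(ids), replace = TRUE)
    rows <- unlist(row_of[take], use.names = FALSE)
    boot <- panel[rows, , drop = FALSE]
    # relabel so duplicated persons stay distinct clusters
    boot[[id_col]] <- rep(seq_along(take),
                          lengths(row_of[take]))
    est <- tryCatch(estimator(boot), error = function(e) NULL)
    if (!is.null(est)) reps[b, ] <- est
  }
  finite <- apply(reps, 1, function(r) all(is.finite(r)))
  n_failed <- sum(!finite)
  if (n_failed > 0.2 * B) {
    warning(sprintf("bootstrap: %d of %d replicates failed or were undefined",
                    n_failed, B), call. = FALSE)
  }
  good <- reps[finite, , drop = FALSE]
  se <- apply(good, 2, sd)
  ci <- rbind(point - z * se, point + z * se)
  rownames(ci) <- c("lower", "upper")
  ci_pct <- apply(good, 2, quantile,
                  probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
  list(point = point, se = se, ci = ci, ci_percentile = ci_pct,
       replicates = good, n_failed = n_failed)
}

# Fast engine-backed bootstrap on a complete-data design.
boot_engine <- function(design, starts, B, seed) {
  set.seed(seed)
  draws <- matrix(
    sample.int(design$n_persons, design$n_persons * B, replace = TRUE) - 1L,
    nrow = design$n_persons, ncol = B)
  reps <- cpp_boot_mediation(
    design$X,
    design$sets$den_a - 1L, design$sets$num_a - 1L,
    design$sets$out_te - 1L, design$sets$out_cde - 1L,
    design$sets$mden - 1L, design$sets$mnum - 1L,
    design$a, design$y, design$m,
    design$exp_pos_te - 1L, design$exp_pos_cde - 1L,
    design$person - 1L, design$n_persons, draws, starts,
    maxit = 8L)
  reps
}

#' Full TE/CDE mediation analysis with cluster-bootstrap inference
#'
#' The orchestrator: on a lagged analysis table it estimates the total
#' effect and the controlled direct effect (pooled over `m` imputed
#' datasets when the table has missing values), the percentage mediation
#' `100 * (TE - CDE) / TE`, and person-clustered bootstrap confidence
#' intervals for every quantity (normal approximation, `point +/- 1.96
#' se`; odds ratios on the log scale; percentile intervals also kept).
#' Bootstrap replicates resample persons from the pre-imputation table
#' and are imputed once each (`m = 1`), while the point estimate pools
#' the full `m`.
#'
#' @param table Analysis table from [build_analysis_table()] (after
#'   [drop_high_missingness()] when it has missing data).
#' @param roles A [variable_roles()] object.
#' @param B Bootstrap resamplings (default 1000).
#' @param m Imputations for the point estimate (default 20; ignored on
#'   complete data, where all completions are identical).
#' @param seed Master seed; simulation of resamples and per-replicate
#'   imputations derive their streams from it.
#' @param complete_case Restrict to complete cases instead of imputing.
#' @param truncate Optional `c(lower_pct, upper_pct)` weight truncation.
#' @param imp_spec Optional [imputation_spec()] (its `m` is overridden).
#' @param conf Confidence level.
#' @return Object of class `mediation_result` with elements `te` and
#'   `cde` (class `effect_estimate`, with CIs), `pct_mediation`,
#'   `pct_ci`, `pct_ci_percentile`, `boot_se`, `replicates`, `B`,
#'   `n_boot_failed`, `m`, `seed`.
#' @export
run_mediation <- function(table, roles = variable_roles(), B = 1000L,
                          m = 20L, seed = 1L, complete_case = FALSE,
                          truncate = NULL, imp_spec = NULL, conf = 0.95) {
  if (!is.null(attr(table, "roles"))) roles <- attr(table, "roles")
  model_vars <- c(roles$exposure, roles$mediator, roles$outcome,
                  roles$baseline, roles$age,
                  intersect(lag_names(roles), names(table)),
                  if (!is.null(roles$mediator_binary)) roles$mediator_binary)
  has_na <- anyNA(table[, intersect(model_vars, names(table)),
                        drop = FALSE])
  if (is.null(imp_spec)) imp_spec <- imputation_spec(m = m)
  imp_spec$m <- as.integer(m)

  if (has_na && complete_case) {
    keep <- complete.cases(table[, intersect(model_vars, names(table)),
                                 drop = FALSE])
    table <- table[keep, , drop = FALSE]
    has_na <- FALSE
  }

  if (!has_na) {
    tab <- rederive_after_imputation(table)
    design <- build_design(tab, roles)
    pf <- point_fits(design, truncate)
    point <- point_stats(pf)
    per <- matrix(point, 1, dimnames = list(NULL, stat_names))
    if (is.null(truncate)) {
      starts <- list(den = unname(pf$ws_te$models$den$coef),
                     num = unname(pf$ws_te$models$num$coef),
                     out_te = unname(pf$f_te$coef),
                     out_cde = unname(pf$f_cde$coef))
      reps <- boot_engine(design, starts, B, seed)
      ok <- reps[, "ok"] == 1 & is.finite(reps[, "pct_mediation"])
      reps <- reps[ok, stat_names, drop = FALSE]
      n_failed <- B - nrow(reps)
    } else {
      bi <- bootstrap_interval(
        table, function(tb) {
          d <- build_design(rederive_after_imputation(tb), roles)
          point_stats(point_fits(d, truncate))
        }, B = B, seed = seed, id_col = roles$id, conf = conf)
      reps <- bi$replicates
      n_failed <- bi$n_failed
    }
    n_ind <- design$n_persons
    n_obs <- nrow(design$X)
  } else {
    imp_spec$seed <- seed + 1L
    imputed <- impute_mice(table, imp_spec)
    per <- matrix(NA_real_, imp_spec$m, length(stat_names),
                  dimnames = list(NULL, stat_names))
    for (i in seq_along(imputed$completed)) {
      tab <- rederive_after_imputation(imputed$completed[[i]])
      d <- build_design(tab, roles)
      per[i, ] <- point_stats(point_fits(d, truncate))
    }
    point <- colMeans(per)
    point["or_te"] <- exp(mean(log(per[, "or_te"])))
    point["or_cde"] <- exp(mean(log(per[, "or_cde"])))
    point["pct_mediation"] <- percent_mediation(point["te_rd"],
                                                point["cde_rd"])
    n_ind <- length(unique(table[[roles$id]]))
    n_obs <- nrow(imputed$completed[[1]])
    one_rep <- function(tb, b) {
      sp <- imp_spec; sp$m <- 1L; sp$seed <- seed + 1000L + b
      comp <- impute_mice(tb, sp)$completed[[1]]
      d <- build_design(rederive_after_imputation(comp), roles)
      point_stats(point_fits(d, truncate))
    }
    ids <- unique(table[[roles$id]])
    row_of <- split(seq_len(nrow(table)), match(table[[roles$id]], ids))
    set.seed(seed)
    reps <- matrix(NA_real_, B, length(stat_names),
                   dimnames = list(NULL, stat_names))
    for (b in seq_len(B)) {
      take <- sample.int(length(ids), length(ids), replace = TRUE)
      rows <- unlist(row_of[take], use.names = FALSE)
      boot <- table[rows, , drop = FALSE]
      boot[[roles$id]] <- rep(seq_along(take), lengths(row_of[take]))
      est <- tryCatch(suppressMessages(one_rep(boot, b)),
                      error = function(e) NULL)
      if (!is.null(est)) reps[b, ] <- est
    }
    finite <- apply(reps, 1, function(r) all(is.finite(r)))
    reps <- reps[finite, , drop = FALSE]
    n_failed <- B - nrow(reps)
  }

  if (n_failed > 0.2 * B) {
    warning(sprintf("bootstrap: %d of %d replicates failed or were undefined",
                    n_failed, B), call. = FALSE)
  }
  z <- qnorm(1 - (1 - conf) / 2)
  se <- apply(reps, 2, sd)
  norm_ci <- function(stat, log_scale = FALSE) {
    p <- point[[stat]]
    if (log_scale) {
      s <- sd(log(reps[, stat]))
      exp(log(p) + c(-1, 1) * z * s)
    } else {
      p + c(-1, 1) * z * se[[stat]]
    }
  }
  pct_ci <- norm_ci("pct_mediation")
  pct_pctl <- unname(quantile(reps[, "pct_mediation"],
                              c((1 - conf) / 2, 1 - (1 - conf) / 2)))

  mk_effect <- function(mode) {
    pre <- if (mode == "TE") "te" else "cde"
    sel <- if (mode == "TE") {
      c(rd = "te_rd", or = "or_te", prev = "prev_unexp_te", paf = "paf_te")
    } else {
      c(rd = "cde_rd", or = "or_cde", prev = "prev_unexp_cde",
        paf = "paf_cde")
    }
    structure(list(
      mode = mode,
      risk_difference_pp = unname(point[[sel["rd"]]]),
      rd_ci = norm_ci(sel[["rd"]]),
      odds_ratio = unname(point[[sel["or"]]]),
      or_ci = norm_ci(sel[["or"]], log_scale = TRUE),
      prevalence_unexposed_pp = unname(point[[sel["prev"]]]),
      prev_ci = norm_ci(sel[["prev"]]),
      paf_pct = unname(point[[sel["paf"]]]),
      n_individuals = n_ind, n_observations = n_obs,
      per_dataset = per, m = nrow(per)
    ), class = "effect_estimate")
  }

  structure(list(
    te = mk_effect("TE"), cde = mk_effect("CDE"),
    pct_mediation = unname(percent_mediation(point[["te_rd"]],
                                             point[["cde_rd"]])),
    pct_ci = pct_ci, pct_ci_percentile = pct_pctl,
    boot_se = se, replicates = reps, B = as.integer(B),
    n_boot_failed = n_failed, m = nrow(per), seed = as.integer(seed),
    n_individuals = n_ind, n_observations = n_obs
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result>  n =", x$n_individuals, "; obs =",
      x$n_observations, "; B =", x$B, "; m =", x$m, "\n")
  print(x$te)
  print(x$cde)
  cat(sprintf("  %% mediation: %.2f%% (%.2f-%.2f)\n", x$pct_mediation,
              x$pct_ci[1], x$pct_ci[2]))
  invisible(x)
}

#' Restrict to person-waves at risk of an employment transition
#'
#' For the transition analyses the exposure is a move into or out of
#' employment since the previous wave, and the sample is restricted to
#' those at risk of that move. `"gain"` keeps person-waves not in paid
#' work at `t - 1` and sets the exposure to being employed at `t`;
#' `"loss"` keeps person-waves employed at `t - 1` and sets the exposure
#' to being out of work at `t`. The lagged exposure is constant within
#' each at-risk set and is therefore removed from the adjustment set of
#' the returned roles (attached as attribute `roles`).
#'
#' @param table Analysis table with the lagged exposure column.
#' @param direction `"gain"` or `"loss"`.
#' @param roles A [variable_roles()] object for the source table.
#' @return The at-risk subset with a `transition` exposure column and a
#'   modified `roles` attribute.
#' @export
transition_table <- function(table, direction = c("gain", "loss"),
                             roles = variable_roles()) {
  direction <- match.arg(direction)
  lag_col <- paste0(roles$exposure, "_lag")
  if (!lag_col %in% names(table)) {
    stop("lagged exposure column '", lag_col, "' not found", call. = FALSE)
  }
  if (direction == "gain") {
    out <- table[!is.na(table[[lag_col]]) & table[[lag_col]] == 1, ,
                 drop = FALSE]
    out$transition <- 1L - out[[roles$exposure]]
  } else {
    out <- table[!is.na(table[[lag_col]]) & table[[lag_col]] == 0, ,
                 drop = FALSE]
    out$transition <- out[[roles$exposure]]
  }
  new_roles <- roles
  new_roles$exposure <- "transition"
  new_roles$lag_extra <- setdiff(roles$lag_extra, roles$exposure)
  attr(out, "roles") <- new_roles
  attr(out, "direction") <- direction
  out
}

#' Stratified mediation analyses
#'
#' Re-runs the full TE/CDE/mediation machinery within population strata,
#' each stratum with its own weights and bootstrap: gender, educational
#' attainment, working age dichotomised at the observation level into
#' younger (25--40) and older (41--64), and concurrent relative poverty
#' (poverty status in the same wave as the exposure). Variables that are
#' constant within a stratum (the stratifying confounder; poverty as a
#' CDE covariate when stratifying on it) are removed from that stratum's
#' models. Strata with fewer persons than `min_persons` are skipped with
#' a warning.
#'
#' @param table Analysis table (complete or with missingness).
#' @param roles A [variable_roles()] object.
#' @param strata Which stratified analyses to run.
#' @param B,m,seed,complete_case Passed to [run_mediation()]; stratum
#'   seeds are derived deterministically from `seed`.
#' @param min_persons Minimum persons per stratum.
#' @param age_split Last age (inclusive) of the younger band.
#' @return Named list (one element per stratifier) of named lists of
#'   `mediation_result`.
#' @export
stratified_run <- function(table, roles = variable_roles(),
                           strata = c("gender", "education", "age_band",
                                      "poverty"),
                           B = 1000L, m = 20L, seed = 1L,
                           complete_case = FALSE, min_persons = 100L,
                           age_split = 40) {
  strata <- match.arg(strata, several.ok = TRUE)
  out <- list()
  k <- 0L
  for (sv in strata) {
    groups <- switch(sv,
      gender = split(seq_len(nrow(table)), table$gender),
      education = split(seq_len(nrow(table)), table$education),
      age_band = split(seq_len(nrow(table)),
                       ifelse(table[[roles$age]] <= age_split,
                              sprintf("younger_25_%d", age_split),
                              sprintf("older_%d_64", age_split + 1))),
      poverty = split(seq_len(nrow(table)),
                      ifelse(table$poverty == 1, "in_poverty",
                             "not_in_poverty")))
    res <- list()
    for (g in names(groups)) {
      k <- k + 1L
      sub <- table[groups[[g]], , drop = FALSE]
      n_persons <- length(unique(sub[[roles$id]]))
      if (n_persons < min_persons) {
        warning("stratum ", sv, "=", g, " skipped (", n_persons,
                " persons < ", min_persons, ")", call. = FALSE)
        next
      }
      sub_roles <- roles
      if (sv %in% c("gender", "education")) {
        sub_roles$baseline <- setdiff(roles$baseline, sv)
      }
      if (sv == "poverty") sub_roles$mediator_binary <- NULL
      res[[g]] <- run_mediation(sub, sub_roles, B = B, m = m,
                                seed = seed + 37L * k,
                                complete_case = complete_case)
    }
    out[[sv]] <- res
  }
  out
}
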