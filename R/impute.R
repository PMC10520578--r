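#' Specification for multiple imputation by chained equations
#'
#' @param m Number of completed datasets (default 20).
#' @param n_iterations Chain length per dataset (default 10).
#' @param pmm_k Donor-pool size for predictive mean matching (default 5).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @param always_predictors Variables always included as predictors when
#'   present (gender, age, wave, number of children).
#' @return Object of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 20L, n_iterations = 10L, pmm_k = 5L,
                            seed = NULL,
                            always_predictors = c("gender", "age", "wave",
                                                  "n_children")) {
  stopifnot(m >= 1, n_iterations >= 1, pmm_k >= 1)
  structure(list(m = as.integer(m), n_iterations = as.integer(n_iterations),
                 pmm_k = as.integer(pmm_k), seed = seed,
                 always_predictors = always_predictors),
            class = "imputation_spec")
}

# The 22 variables required for analysis: 14 concurrent (exposure,
# income, GHQ, baseline confounders, age, time-varying confounders,
# MCS, region) plus 8 lag-1 covariates.
required_analysis_variables <- function(roles = variable_roles()) {
  c(roles$exposure, "income", "ghq", roles$baseline, roles$age,
    roles$time_varying, "mcs",
    paste0(c(roles$exposure, roles$mediator, roles$outcome, "mcs",
             "tenure", "benefits", "relationship", "pcs"), "_lag"))
}

#' Drop observations with high missingness
#'
#' Removes rows (person-wave observations) missing strictly more than
#' `max_missing` of the variables required for analysis. The canonical
#' required set has 22 variables; if the supplied set has a different
#' length a warning is issued and the rule is applied to the listed set.
#'
#' @param panel Analysis table (or panel) containing the variables.
#' @param variables Character vector of required variables; defaults to
#'   [required_analysis_variables()] intersected with the table.
#' @param max_missing Strict threshold (default 9: rows missing 10 or
#'   more of 22 are dropped, rows missing exactly 9 are kept).
#' @return The filtered table; the number of rows removed is reported in
#'   a message and attached as attribute `n_dropped`.
#' @export
drop_high_missingness <- function(panel, variables = NULL, max_missing = 9L) {
  if (is.null(variables)) {
    variables <- intersect(required_analysis_variables(), names(panel))
  }
  if (length(variables) != 22L) {
    warning("required-variable set has ", length(variables),
            " entries, not 22; applying the rule to the listed set",
            call. = FALSE)
  }
  n_miss <- rowSums(is.na(panel[, variables, drop = FALSE]))
  keep <- n_miss <= max_missing
  out <- panel[keep, , drop = FALSE]
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf(
      "drop_high_missingness: removed %d of %d observations (%.1f%%)",
      n_dropped, length(keep), 100 * n_dropped / length(keep)))
  }
  if (n_dropped == length(keep)) {
    warning("all observations dropped by the missingness rule",
            call. = FALSE)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

impute_family <- function(x) {
  ux <- unique(x[!is.na(x)])
  if (is.factor(x) || is.character(x)) {
    if (length(ux) > 2) "multinomial" else "logistic"
  } else if (length(ux) <= 2) "logistic" else "pmm"
}

# One conditional-model update of a single variable (current completions
# in `data`, missing rows `mis`), returning imputed values for `mis`.
impute_one <- function(data, var, mis, predictors, pmm_k) {
  obs <- !mis
  form <- reformulate(predictors)
  mf <- data[, predictors, drop = FALSE]
  X <- model.matrix(form, data = mf)
  y <- data[[var]]
  fam <- impute_family(y)
  if (fam == "pmm") {
    fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
    keep <- !is.na(fit$coefficients)
    pred <- drop(X[, keep, drop = FALSE] %*% fit$coefficients[keep])
    donors_pred <- pred[obs]
    donors_val <- y[obs]
    target <- pred[mis]
    imp <- vapply(target, function(tp) {
      k <- min(pmm_k, length(donors_val))
      idx <- order(abs(donors_pred - tp))[seq_len(k)]
      donors_val[sample(idx, 1)]
    }, numeric(1))
    if (is.integer(y)) as.integer(imp) else imp
  } else if (fam == "logistic") {
    f <- factor(y)
    yy <- as.numeric(f[obs]) - 1
    fit <- suppressWarnings(
      glm.fit(X[obs, , drop = FALSE], yy, family = binomial()))
    keep <- !is.na(fit$coefficients)
    eta <- drop(X[mis, keep, drop = FALSE] %*% fit$coefficients[keep])
    draw <- rbinom(length(eta), 1, plogis(eta))
    out <- levels(f)[draw + 1]
    if (is.factor(y)) factor(out, levels = levels(y))
    else if (is.character(y)) out
    else as.numeric(out)
  } else {
    dat <- data.frame(.y = y, mf)
    fit <- nnet::multinom(reformulate(predictors, ".y"),
                          data = dat[obs, , drop = FALSE], trace = FALSE)
    pr <- predict(fit, newdata = dat[mis, , drop = FALSE], type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = sum(mis))
    lv <- fit$lev
    idx <- apply(pr, 1, function(p) sample(length(lv), 1, prob = p))
    out <- lv[idx]
    if (is.factor(y)) factor(out, levels = levels(y)) else out
  }
}

#' Multiple imputation by chained equations
#'
#' Creates `m` completed copies of the table under a missing-at-random
#' assumption. Within each chain, variables are visited in order of
#' increasing missingness and imputed from a conditional model given the
#' current completions of all other modelled variables: predictive mean
#' matching (`pmm_k` donors) for continuous variables, a logistic draw
#' for binaries, and a multinomial draw for categoricals. Imputation is
#' performed on the continuous income and GHQ scores; dichotomised
#' variables (caseness, poverty) are meant to be re-derived afterwards
#' (see [rederive_after_imputation()]). Observed cells are never
#' altered. Rows with missing region are dropped beforehand.
#'
#' @param panel Table to impute (typically the lagged analysis table
#'   after [drop_high_missingness()]).
#' @param spec An [imputation_spec()].
#' @param variables Columns to model; defaults to every column except
#'   identifiers, derived dichotomies, and fully observed columns are
#'   used as predictors only.
#' @return Object of class `imputation_set`: `completed` (list of `m`
#'   data frames), `diagnostics` (per-variable chain means), `spec`.
#' @export
impute_mice <- function(panel, spec = imputation_spec(), variables = NULL) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if ("region" %in% names(panel) && anyNA(panel$region)) {
    n_bad <- sum(is.na(panel$region))
    message("impute_mice: dropping ", n_bad, " rows with missing region")
    panel <- panel[!is.na(panel$region), , drop = FALSE]
  }
  derived <- c("caseness", "poverty", "log_income", "unemployed")
  if (is.null(variables)) {
    variables <- setdiff(names(panel),
                         c("pid", "wave", "baseline_only", derived))
  }
  n_na <- vapply(panel[variables], function(x) sum(is.na(x)), integer(1))
  if (any(n_na == nrow(panel))) {
    stop("variable(s) with 100% missingness cannot be imputed: ",
         paste(variables[n_na == nrow(panel)], collapse = ", "),
         call. = FALSE)
  }
  targets <- variables[n_na > 0]
  if (!length(targets)) {
    completed <- replicate(spec$m, panel, simplify = FALSE)
    return(structure(list(completed = completed, diagnostics = NULL,
                          spec = spec), class = "imputation_set"))
  }
  targets <- targets[order(n_na[targets])]
  mis_idx <- lapply(targets, function(v) is.na(panel[[v]]))
  names(mis_idx) <- targets
  completed <- vector("list", spec$m)
  diag_list <- list()
  for (chain in seq_len(spec$m)) {
    data <- panel
    # initial fill: random draws from the observed margin
    for (v in targets) {
      mis <- mis_idx[[v]]
      data[[v]][mis] <- sample(panel[[v]][!mis], sum(mis), replace = TRUE)
    }
    trace <- matrix(NA_real_, spec$n_iterations, length(targets),
                    dimnames = list(NULL, targets))
    for (it in seq_len(spec$n_iterations)) {
      for (v in targets) {
        mis <- mis_idx[[v]]
        preds <- union(setdiff(variables, v),
                       intersect(spec$always_predictors, names(panel)))
        preds <- setdiff(preds, v)
        # drop degenerate predictors (single observed level)
        preds <- preds[vapply(preds, function(p) {
          length(unique(data[[p]])) > 1
        }, logical(1))]
        data[[v]][mis] <- impute_one(data, v, mis, preds, spec$pmm_k)
        xv <- data[[v]][mis]
        trace[it, v] <- if (is.numeric(xv)) mean(xv)
        else mean(as.numeric(factor(xv, levels = levels(factor(data[[v]]))))
                  , na.rm = TRUE)
      }
    }
    completed[[chain]] <- data
    diag_list[[chain]] <- trace
  }
  structure(list(completed = completed, diagnostics = diag_list,
                 spec = spec, targets = targets),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> m =", length(x$completed), "\n")
  if (!is.null(x$targets)) {
    cat("  imputed variables:", paste(x$targets, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Re-derive dichotomised and transformed variables after imputation
#'
#' Caseness and poverty are dichotomised after imputation of the
#' continuous GHQ and income scores, and log income is recomputed.
#' Lagged derived columns are refreshed from their imputed continuous
#' counterparts where present.
#'
#' @param table A completed analysis table.
#' @return The table with `caseness`, `poverty`, `log_income`, and
#'   `unemployed` consistent with the imputed scores.
#' @export
rederive_after_imputation <- function(table) {
  if ("ghq" %in% names(table)) table$caseness <- derive_caseness(table$ghq)
  if ("income" %in% names(table)) {
    table$log_income <- log_income(table$income)
    table <- derive_poverty(table)
  }
  if ("employed" %in% names(table)) {
    table$unemployed <- 1L - table$employed
  }
  table
}

#' Pool point estimates across imputed datasets
#'
#' Rubin's rule for the point estimate: the arithmetic mean of the
#' per-dataset estimates (interval estimation is delegated to the
#' cluster bootstrap).
#'
#' @param estimates Numeric vector of per-dataset estimates of one
#'   estimand.
#' @return Their mean.
#' @export
pool_point_estimates <- function(estimates) {
  if (!length(estimates)) stop("no estimates to pool", call. = FALSE)
  mean(as.numeric(estimates))
}
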