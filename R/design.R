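# Internal: one shared model matrix per analysis table, plus the column
# index sets for every model the estimator fits. Building this once and
# letting bootstrap replicates enter as frequency weights is what keeps
# the cluster bootstrap affordable.
#
# Column sets (intercept always included):
#   den_a  : P(A_t | V, age, age^2, all lag-1 covariates)   [weight denominator]
#   num_a  : P(A_t | V, A_{t-1})                            [stabilising numerator]
#   out_te : Y_t ~ A_t + V + age + age^2 + all lag-1 covariates
#   out_cde: out_te + log income_t + poverty_t
#   mden   : E[M_t | A_t, V, age, age^2, all lag-1 covariates]
#   mnum   : E[M_t | A_t, V]
build_design <- function(table, roles = variable_roles()) {
  lags <- intersect(lag_names(roles), names(table))
  vars <- c(roles$exposure, roles$mediator, roles$mediator_binary,
            roles$baseline, roles$age, "age_sq", lags)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("analysis table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sub <- table[, vars, drop = FALSE]
  fac <- vapply(sub, is.factor, logical(1))
  sub[fac] <- lapply(sub[fac], droplevels)
  if (anyNA(sub) || anyNA(table[[roles$outcome]])) {
    stop("analysis table contains missing values among model variables; ",
         "impute (impute_mice) or restrict to complete cases first",
         call. = FALSE)
  }
  form <- reformulate(vars)
  mm <- model.matrix(form, data = sub)
  asgn <- attr(mm, "assign")
  labels <- attr(terms(form), "term.labels")
  cols_of <- function(v) {
    idx <- unlist(lapply(v, function(x) which(asgn == match(x, labels))))
    as.integer(idx)
  }
  intercept <- 1L
  lag_cols <- cols_of(lags)
  base_cols <- cols_of(roles$baseline)
  age_cols <- cols_of(c(roles$age, "age_sq"))
  exp_col <- cols_of(roles$exposure)
  med_cols <- cols_of(c(roles$mediator, roles$mediator_binary))
  sets <- list(
    den_a = c(intercept, base_cols, age_cols, lag_cols),
    # marginal (intercept-only) stabilising numerator: the weighted
    # pseudo-population then balances every covariate in the
    # denominator, which is what the balance diagnostics check
    num_a = intercept,
    out_te = c(intercept, exp_col, base_cols, age_cols, lag_cols),
    out_cde = c(intercept, exp_col, base_cols, age_cols, lag_cols, med_cols),
    mden = c(intercept, exp_col, base_cols, age_cols, lag_cols),
    mnum = c(intercept, exp_col, base_cols)
  )
  list(
    X = mm,
    sets = sets,
    colnames = colnames(mm),
    a = as.numeric(table[[roles$exposure]]),
    y = as.numeric(table[[roles$outcome]]),
    m = as.numeric(table[[roles$mediator]]),
    person = match(table[[roles$id]], unique(table[[roles$id]])),
    n_persons = length(unique(table[[roles$id]])),
    exp_pos_te = match(exp_col, sets$out_te),
    exp_pos_cde = match(exp_col, sets$out_cde),
    roles = roles
  )
}

# Fit one logistic model on a column set of the shared matrix; errors on
# separation / rank problems with the offending columns named.
fit_logit_set <- function(design, set, y = design$a, w = NULL, start = NULL,
                          label = "model") {
  cols <- design$sets[[set]]
  X <- design$X[, cols, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(label, ": design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (is.null(w)) w <- rep(1, nrow(design$X))
  f <- cpp_irls(design$X, cols - 1L, y, w,
                start = start, tol = 1e-10, maxit = 100L)
  if (isTRUE(f$separated) || !isTRUE(f$converged)) {
    culprit <- colnames(X)[which.max(abs(f$coef))]
    stop(label, ": logistic fit failed to converge after ", f$iterations,
         " iterations (largest coefficient on '", culprit,
         "'), suggesting separation", call. = FALSE)
  }
  names(f$coef) <- colnames(X)
  f
}
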