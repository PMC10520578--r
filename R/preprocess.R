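#' CMD caseness from the GHQ-12 score
#'
#' A GHQ-12 score of 4 or more indicates a strong likelihood of common
#' mental disorder ("caseness").
#'
#' @param ghq Integer vector of GHQ-12 scores in 0--12; `NA` propagates.
#' @param cut Caseness cut-off (default 4).
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' derive_caseness(c(0, 3, 4, 12, NA))
derive_caseness <- function(ghq, cut = 4L) {
  obs <- ghq[!is.na(ghq)]
  if (length(obs) && (any(obs < 0) || any(obs > 12))) {
    stop("ghq scores must lie in [0, 12]", call. = FALSE)
  }
  as.integer(ghq >= cut)
}

#' Flag relative poverty against 60% of the sample median income
#'
#' Adds/overwrites a `poverty` column: equivalised after-housing-cost
#' income below `fraction` (default 0.6) of the median income over all
#' observed person-waves in the input table. The median is computed once
#' per call on the sample itself (unweighted); the line used is attached
#' as attribute `poverty_line`. Missing income yields missing poverty.
#'
#' @param panel Data frame with an income column.
#' @param income_col Name of the income column (default `"income"`).
#' @param fraction Fraction of the median defining the line.
#' @return The panel with a `poverty` column (0/1 integer).
#' @export
derive_poverty <- function(panel, income_col = "income", fraction = 0.6) {
  inc <- panel[[income_col]]
  if (is.null(inc)) stop("column '", income_col, "' not found", call. = FALSE)
  if (all(is.na(inc))) stop("all incomes are missing", call. = FALSE)
  line <- fraction * median(inc, na.rm = TRUE)
  panel$poverty <- as.integer(inc < line)
  attr(panel, "poverty_line") <- line
  panel
}

oecd_scale <- function(n_adults, n_children) {
  1.0 + 0.5 * (n_adults - 1) + 0.3 * n_children
}

#' Modified-OECD equivalisation of household income
#'
#' Divides household income by the modified OECD scale
#' `1 + 0.5 * (n_adults - 1) + 0.3 * n_children`, making households of
#' different composition comparable.
#'
#' @param household_income Household income (any currency/period).
#' @param n_adults Number of adults (>= 1).
#' @param n_children Number of children.
#' @return Equivalised income.
#' @export
#' @examples
#' equivalise_income(1800, 2, 1) # == 1000
equivalise_income <- function(household_income, n_adults, n_children) {
  if (any(n_adults < 1, na.rm = TRUE)) {
    stop("n_adults must be >= 1", call. = FALSE)
  }
  household_income / oecd_scale(n_adults, n_children)
}

#' Log income with a positive floor
#'
#' The income--mental-health relationship is curvilinear, so income
#' enters all models as a natural log. Incomes at or below `floor`
#' (default 1 currency unit/month) are floored before logging, keeping
#' the mediator finite without discarding rows. `NA` propagates.
#'
#' @param income Numeric vector.
#' @param floor Positive floor applied before logging.
#' @return `log(pmax(income, floor))`.
#' @export
log_income <- function(income, floor = 1) {
  stopifnot(floor > 0)
  log(pmax(income, floor))
}

#' Restrict a panel to working age
#'
#' Keeps rows with age inside the closed interval `age_range`
#' (default 25--64).
#'
#' @param panel Data frame with an `age` column.
#' @param age_range Length-2 numeric, inclusive bounds.
#' @return The filtered panel.
#' @export
restrict_sample <- function(panel, age_range = c(25, 64)) {
  if (is.null(panel$age)) stop("column 'age' not found", call. = FALSE)
  panel[!is.na(panel$age) &
          panel$age >= age_range[1] & panel$age <= age_range[2], ,
        drop = FALSE]
}

#' Variable roles for the mediation analysis
#'
#' Names the columns playing each role in the analysis: the exposure
#' (non-employment), the continuous and binary mediators (log income and
#' relative poverty), the outcome (caseness), baseline (time-invariant)
#' confounders, time-varying confounders entering the models as
#' one-wave-lagged terms, and the extra lag-1 covariates (lagged
#' exposure, lagged log income, lagged caseness, lagged MCS) required to
#' adjust for past exposure and past outcome.
#'
#' @param exposure,mediator,mediator_binary,outcome Column names.
#' @param baseline Time-invariant confounder columns.
#' @param time_varying Time-varying confounder columns (lagged in models).
#' @param lag_extra Additional columns lagged into the adjustment set.
#' @param age,id,wave Column names for age, person id, wave index.
#' @return Object of class `variable_roles`.
#' @export
variable_roles <- function(exposure = "unemployed",
                           mediator = "log_income",
                           mediator_binary = "poverty",
                           outcome = "caseness",
                           baseline = c("gender", "ethnicity", "education"),
                           time_varying = c("tenure", "benefits",
                                            "relationship", "n_children",
                                            "pcs", "region"),
                           lag_extra = c("unemployed", "log_income",
                                         "caseness", "mcs"),
                           age = "age", id = "pid", wave = "wave") {
  roles <- list(exposure = exposure, mediator = mediator,
                mediator_binary = mediator_binary, outcome = outcome,
                baseline = baseline, time_varying = time_varying,
                lag_extra = lag_extra, age = age, id = id, wave = wave)
  primary <- c(exposure, mediator, mediator_binary, outcome)
  lagged <- paste0(c(time_varying, lag_extra), "_lag")
  all_roles <- c(primary, baseline, lagged, age, id, wave)
  dup <- unique(all_roles[duplicated(all_roles)])
  if (length(dup)) {
    stop("column(s) assigned to more than one role: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(roles, class = "variable_roles")
}

lag_names <- function(roles) {
  paste0(c(roles$time_varying, roles$lag_extra), "_lag")
}

# columns that must exist in the raw panel before lagging
roles_source_columns <- function(roles) {
  unique(c(roles$id, roles$wave, roles$exposure, roles$mediator,
           roles$outcome, roles$baseline, roles$time_varying,
           roles$lag_extra, roles$age))
}

#' Build the lagged analysis table
#'
#' Pairs each person-wave's exposure, mediator, and outcome with the
#' previous wave's values of every lag-1 covariate (time-varying
#' confounders plus lagged exposure, lagged log income, lagged caseness
#' and lagged MCS), implementing the minimally sufficient adjustment set
#' in which time-varying confounders precede the exposure. Each person's
#' first observed wave contributes baseline information only and yields
#' no outcome row; a row whose `t - 1` wave is absent contributes no
#' outcome row either (the lag is undefined rather than imputed).
#' Squared age is added as `age_sq`.
#'
#' Derived columns (`unemployed`, `caseness`, `log_income`, `poverty`)
#' are computed first if absent.
#'
#' @param panel Long panel sorted by (id, wave); duplicates are an error.
#' @param roles A [variable_roles()] object.
#' @return The analysis table: all concurrent columns plus one `_lag`
#'   column per lag-1 covariate.
#' @export
build_analysis_table <- function(panel, roles = variable_roles()) {
  panel <- derive_analysis_variables(panel, roles)
  key <- paste(panel[[roles$id]], panel[[roles$wave]])
  if (anyDuplicated(key)) {
    stop("duplicate (person, wave) rows in panel", call. = FALSE)
  }
  missing_cols <- setdiff(roles_source_columns(roles), names(panel))
  if (length(missing_cols)) {
    stop("panel lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ord <- order(panel[[roles$id]], panel[[roles$wave]])
  panel <- panel[ord, , drop = FALSE]
  key <- paste(panel[[roles$id]], panel[[roles$wave]])
  prev <- match(paste(panel[[roles$id]], panel[[roles$wave]] - 1L), key)
  keep <- !is.na(prev)
  out <- panel[keep, , drop = FALSE]
  prev <- prev[keep]
  for (nm in c(roles$time_varying, roles$lag_extra)) {
    out[[paste0(nm, "_lag")]] <- panel[[nm]][prev]
  }
  out$age_sq <- out[[roles$age]]^2
  rownames(out) <- NULL
  out
}

# Ensure derived analysis variables exist on a raw panel.
derive_analysis_variables <- function(panel, roles = variable_roles()) {
  if (!"unemployed" %in% names(panel) && "employed" %in% names(panel)) {
    panel$unemployed <- 1L - panel$employed
  }
  if (!"caseness" %in% names(panel) && "ghq" %in% names(panel)) {
    panel$caseness <- derive_caseness(panel$ghq)
  }
  if (!"log_income" %in% names(panel) && "income" %in% names(panel)) {
    panel$log_income <- log_income(panel$income)
  }
  if (!"poverty" %in% names(panel) && "income" %in% names(panel)) {
    panel <- derive_poverty(panel)
  }
  panel
}
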