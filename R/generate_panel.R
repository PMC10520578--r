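# Forward simulation engine shared by generate_panel() and oracle_effects().
# State is kept in n x T matrices; wave 1 is initialised cross-sectionally
# and later waves evolve from the lagged state, so income and CMD risk
# depend on time-varying covariates only through their t-1 values.
sim_engine <- function(params, n = params$n_individuals,
                       collect_counterfactuals = FALSE) {
  p <- params
  T <- p$n_waves
  bl <- p$baseline; em <- p$employment; inc <- p$income
  out <- p$outcome; tr <- p$transitions

  female <- rbinom(n, 1, bl$p_female)
  nonwhite <- rbinom(n, 1, bl$p_nonwhite)
  edu <- sample(1:3, n, TRUE, prob = bl$p_education) # 1 high, 2 medium, 3 low
  edu_high <- as.numeric(edu == 1); edu_medium <- as.numeric(edu == 2)
  edu_low <- as.numeric(edu == 3)
  region <- sample(seq_along(bl$region_probs), n, TRUE,
                   prob = bl$region_probs / sum(bl$region_probs))
  age1 <- sample(bl$age_entry[1]:bl$age_entry[2], n, TRUE)

  A <- loginc <- case <- ghq <- mcs <- pcs <- matrix(NA_real_, n, T)
  owner <- benefits <- coupled <- nchild <- matrix(NA_real_, n, T)
  if (collect_counterfactuals) {
    te_i <- cde_i <- matrix(NA_real_, n, T)
  }

  oM_at <- function(age) {
    if (is.null(out$beta_log_income_older)) rep(out$beta_log_income, length(age))
    else ifelse(age > out$age_split, out$beta_log_income_older,
                out$beta_log_income)
  }
  pcs_target <- function(age) {
    tr$pcs_target_intercept + tr$pcs_target_age * (age - 45) +
      tr$pcs_target_edu_low * edu_low
  }
  draw_ghq <- function(is_case) {
    g <- integer(length(is_case))
    pc <- 0.75^(0:8); pc <- pc / sum(pc)
    pn <- c(0.45, 0.25, 0.18, 0.12)
    ncase <- sum(is_case)
    if (ncase > 0) g[is_case == 1] <- sample(4:12, ncase, TRUE, prob = pc)
    if (ncase < length(is_case)) {
      g[is_case == 0] <- sample(0:3, length(is_case) - ncase, TRUE, prob = pn)
    }
    g
  }

  # ---- wave 1: cross-sectional initialisation (baseline-only rows) ----
  pcs[, 1] <- rnorm(n, pcs_target(age1), tr$pcs_baseline_sd)
  owner[, 1] <- rbinom(n, 1, plogis(0.2 + 0.5 * edu_high - 0.6 * edu_low +
                                      0.04 * (age1 - 45)))
  coupled[, 1] <- rbinom(n, 1, plogis(0.95 + 0.02 * (age1 - 45) -
                                        0.25 * edu_low))
  nchild[, 1] <- pmin(rpois(n, pmax(0.1, 1.5 - 0.05 * abs(age1 - 35))), 4)
  benefits[, 1] <- rbinom(n, 1, plogis(-2.0 + 0.35 * (nchild[, 1] > 0) +
                                         0.5 * edu_low))
  eta_a1 <- em$wave1_intercept + em$female * female +
    em$edu_medium * edu_medium + em$edu_low * edu_low +
    em$pcs_lag * (pcs[, 1] - 50) + em$benefits_lag * benefits[, 1] +
    em$n_children_lag * nchild[, 1]
  A[, 1] <- rbinom(n, 1, plogis(eta_a1))
  base1 <- inc$intercept + inc$edu_high * edu_high + inc$edu_low * edu_low +
    inc$female * female + inc$coupled_lag * coupled[, 1] +
    inc$pcs_lag * (pcs[, 1] - 50) + inc$benefits_lag * benefits[, 1] +
    inc$n_children_lag * nchild[, 1]
  loginc[, 1] <- base1 + inc$beta_unemployed * A[, 1] + rnorm(n, 0, inc$sd)
  eta_y1 <- out$wave1_intercept + out$beta_unemployed * A[, 1] +
    oM_at(age1) * (loginc[, 1] - out$log_income_ref) +
    out$female * female + out$edu_low * edu_low +
    out$pcs_lag * (pcs[, 1] - 50) + out$benefits_lag * benefits[, 1] +
    out$coupled_lag * coupled[, 1]
  case[, 1] <- rbinom(n, 1, plogis(eta_y1))
  ghq[, 1] <- draw_ghq(case[, 1])
  mcs[, 1] <- tr$mcs_intercept + tr$mcs_caseness * case[, 1] +
    tr$mcs_unemployed * A[, 1] + rnorm(n, 0, tr$mcs_sd)

  # ---- waves 2..T ----
  for (t in 2:T) {
    age_t <- age1 + t - 1
    al <- A[, t - 1]
    stay <- rbinom(n, 1, tr$tenure_stay_owner)
    move_up <- rbinom(n, 1, plogis(tr$tenure_renter_to_owner_logit +
                                     tr$tenure_edu_high * edu_high +
                                     tr$tenure_unemployed_lag * al))
    owner[, t] <- ifelse(owner[, t - 1] == 1, stay, move_up)
    benefits[, t] <- rbinom(n, 1, plogis(
      tr$benefits_intercept + tr$benefits_lag * benefits[, t - 1] +
        tr$benefits_unemployed_lag * al +
        tr$benefits_children * (nchild[, t - 1] > 0) +
        tr$benefits_edu_low * edu_low))
    stay_c <- rbinom(n, 1, tr$relationship_stay_coupled)
    form_c <- rbinom(n, 1, tr$relationship_single_to_coupled)
    coupled[, t] <- ifelse(coupled[, t - 1] == 1, stay_c, form_c)
    gain <- rbinom(n, 1, tr$child_gain * (age_t < tr$child_gain_age_max))
    lose <- rbinom(n, 1, tr$child_loss * (nchild[, t - 1] > 0))
    nchild[, t] <- pmin(pmax(nchild[, t - 1] + gain - lose, 0), 4)
    pcs[, t] <- pcs[, t - 1] +
      tr$pcs_reversion * (pcs_target(age_t) - pcs[, t - 1]) +
      rnorm(n, 0, tr$pcs_sd)

    eta_a <- em$intercept + em$persistence * al + em$female * female +
      em$edu_medium * edu_medium + em$edu_low * edu_low +
      em$pcs_lag * (pcs[, t - 1] - 50) +
      em$benefits_lag * benefits[, t - 1] +
      em$caseness_lag * case[, t - 1] +
      em$n_children_lag * nchild[, t - 1]
    A[, t] <- rbinom(n, 1, plogis(eta_a))

    base <- inc$intercept + inc$edu_high * edu_high + inc$edu_low * edu_low +
      inc$female * female + inc$coupled_lag * coupled[, t - 1] +
      inc$pcs_lag * (pcs[, t - 1] - 50) +
      inc$benefits_lag * benefits[, t - 1] +
      inc$n_children_lag * nchild[, t - 1]
    eps <- rnorm(n, 0, inc$sd)
    loginc[, t] <- base + inc$beta_unemployed * A[, t] + eps

    eta_rest <- out$intercept + out$caseness_lag * case[, t - 1] +
      out$mcs_lag * (mcs[, t - 1] - 52) + out$female * female +
      out$edu_low * edu_low + out$pcs_lag * (pcs[, t - 1] - 50) +
      out$benefits_lag * benefits[, t - 1] +
      out$coupled_lag * coupled[, t - 1]
    oM_t <- oM_at(age_t)
    eta_y <- eta_rest + out$beta_unemployed * A[, t] +
      oM_t * (loginc[, t] - out$log_income_ref)
    case[, t] <- rbinom(n, 1, plogis(eta_y))
    ghq[, t] <- draw_ghq(case[, t])
    mcs[, t] <- tr$mcs_intercept + tr$mcs_caseness * case[, t] +
      tr$mcs_unemployed * A[, t] + rnorm(n, 0, tr$mcs_sd)

    if (collect_counterfactuals) {
      # Contemporaneous intervention on A_t with the same income noise draw;
      # the CDE contrast holds log income at its employed (A = 0) value.
      li0 <- base + eps
      li1 <- base + inc$beta_unemployed + eps
      risk <- function(a_val, li) {
        plogis(eta_rest + out$beta_unemployed * a_val +
                 oM_t * (li - out$log_income_ref))
      }
      te_i[, t] <- risk(1, li1) - risk(0, li0)
      cde_i[, t] <- risk(1, li0) - risk(0, li0)
    }
  }

  res <- list(female = female, nonwhite = nonwhite, edu = edu,
              region = region, age1 = age1, A = A, loginc = loginc,
              case = case, ghq = ghq, mcs = mcs, pcs = pcs, owner = owner,
              benefits = benefits, coupled = coupled, nchild = nchild)
  if (collect_counterfactuals) {
    res$te_i <- te_i
    res$cde_i <- cde_i
  }
  res
}

#' Generate a synthetic longitudinal employment/income/mental-health panel
#'
#' Simulates a long-format person-by-wave panel with the causal structure
#' described in [sim_params()]: non-employment lowers equivalised household
#' income within the same wave, and both non-employment (directly) and log
#' income (the mediated path) shift the risk of common mental disorder.
#' All derived analysis variables (caseness, relative poverty against 60%
#' of the sample median, log income) are populated on output.
#'
#' @param params A [sim_params()] object.
#' @return A `data.frame`, one row per person-wave, sorted by
#'   (`pid`, `wave`), with columns: `pid`, `wave`, `baseline_only`, `age`,
#'   `gender`, `ethnicity`, `education`, `region`, `tenure`, `benefits`,
#'   `relationship`, `n_children`, `pcs`, `mcs`, `employed`, `unemployed`,
#'   `income` (equivalised GBP/month after housing costs), `ghq`,
#'   `n_adults`, `hh_income_ahc`, `hh_income_gross`, and the derived
#'   `caseness`, `log_income`, `poverty`.
#' @export
#' @examples
#' panel <- generate_panel(sim_params(200, seed = 7))
#' mean(panel$unemployed)
generate_panel <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_individuals
  T <- params$n_waves
  s <- sim_engine(params)

  pid <- rep(seq_len(n), each = T)
  wave <- rep(seq_len(T), times = n)
  idx <- cbind(rep(seq_len(n), each = T), wave) # (person, wave) matrix index
  edu_lab <- c("high", "medium", "low")
  panel <- data.frame(
    pid = pid,
    wave = wave,
    baseline_only = wave == 1L,
    age = s$age1[idx[, 1]] + wave - 1L,
    gender = factor(ifelse(s$female[idx[, 1]] == 1, "female", "male"),
                    levels = c("male", "female")),
    ethnicity = factor(ifelse(s$nonwhite[idx[, 1]] == 1, "nonwhite", "white"),
                       levels = c("white", "nonwhite")),
    education = factor(edu_lab[s$edu[idx[, 1]]], levels = edu_lab),
    region = factor(sprintf("r%02d", s$region[idx[, 1]]),
                    levels = sprintf("r%02d", seq_len(12))),
    tenure = factor(ifelse(s$owner[idx] == 1, "owner", "renter"),
                    levels = c("owner", "renter")),
    benefits = as.integer(s$benefits[idx]),
    relationship = factor(ifelse(s$coupled[idx] == 1, "coupled", "single"),
                          levels = c("single", "coupled")),
    n_children = as.integer(s$nchild[idx]),
    pcs = s$pcs[idx],
    mcs = s$mcs[idx],
    employed = as.integer(1 - s$A[idx]),
    income = exp(s$loginc[idx]),
    ghq = as.integer(s$ghq[idx])
  )
  panel$unemployed <- 1L - panel$employed
  panel$n_adults <- 1L + as.integer(panel$relationship == "coupled")
  scale <- oecd_scale(panel$n_adults, panel$n_children)
  panel$hh_income_ahc <- panel$income * scale
  panel$hh_income_gross <-
    panel$hh_income_ahc / (1 - params$income$housing_cost_fraction)
  panel$caseness <- derive_caseness(panel$ghq)
  panel$log_income <- log_income(panel$income)
  panel <- derive_poverty(panel)
  panel
}

#' Brute-force oracle effects for a simulation configuration
#'
#' Computes the true total effect (TE) and controlled direct effect (CDE)
#' implied by a [sim_params()] configuration by Monte-Carlo simulation of
#' the structural equations. For every simulated person-wave (waves 2
#' onwards), the risk of caseness is evaluated under an intervention
#' setting non-employment on and off while income responds naturally
#' (TE), and with log income additionally held at its employed-state
#' draw (CDE). Effects are pooled over waves and persons, as the
#' weighted pooled-logistic estimator pools them.
#'
#' @param params A [sim_params()] object.
#' @param n_mc Number of Monte-Carlo persons (>= 1e5 recommended for a
#'   Monte-Carlo s.e. well below 0.1 percentage points).
#' @param seed Seed for the oracle simulation; the result is invariant to
#'   it up to the reported Monte-Carlo s.e.
#' @return An object of class `sim_truth` with elements `oracle_te_rd`,
#'   `oracle_cde_rd` (percentage points), `oracle_pct_mediation` (percent),
#'   `monte_carlo_se` (percentage points, person-clustered), `n_mc`, and
#'   a `params` echo.
#' @export
oracle_effects <- function(params, n_mc = 1e5, seed = params$seed + 1000003L) {
  validate_sim_params(params)
  set.seed(seed)
  s <- sim_engine(params, n = as.integer(n_mc),
                  collect_counterfactuals = TRUE)
  te_pw <- s$te_i[, -1, drop = FALSE]
  cde_pw <- s$cde_i[, -1, drop = FALSE]
  te_person <- rowMeans(te_pw)
  cde_person <- rowMeans(cde_pw)
  te <- 100 * mean(te_person)
  cde <- 100 * mean(cde_person)
  mc_se <- 100 * stats::sd(te_person) / sqrt(length(te_person))
  structure(list(
    params = params,
    oracle_te_rd = te,
    oracle_cde_rd = cde,
    oracle_pct_mediation = if (te != 0) 100 * (te - cde) / te else NA_real_,
    monte_carlo_se = mc_se,
    n_mc = as.integer(n_mc)
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>  (Monte-Carlo, n =", x$n_mc, ")\n")
  cat(sprintf("  TE  risk difference: %.3f pp (MC se %.3f)\n",
              x$oracle_te_rd, x$monte_carlo_se))
  cat(sprintf("  CDE risk difference: %.3f pp\n", x$oracle_cde_rd))
  cat(sprintf("  %% mediation:         %.2f%%\n", x$oracle_pct_mediation))
  invisible(x)
}

#' Inject missing-at-random missingness into a panel
#'
#' Blanks values of selected variables with probabilities that depend
#' only on fully observed covariates (gender), i.e. missing at random by
#' construction: the probability that a cell is blanked never depends on
#' the value being blanked. Derived columns (`unemployed`, `caseness`,
#' `log_income`, `poverty`) are recomputed afterwards so missingness
#' propagates to them.
#'
#' @param panel A panel from [generate_panel()] (or of the same layout).
#' @param params A [sim_params()] object whose `missingness$rates` gives
#'   per-variable target rates and `missingness$female_logit_shift` the
#'   log-odds shift of the blanking probability for women (centred so the
#'   marginal rate stays at the target).
#' @return The panel with `NA`s injected.
#' @export
inject_missingness <- function(panel, params) {
  rates <- params$missingness$rates
  shift <- params$missingness$female_logit_shift
  stopifnot(all(rates >= 0 & rates <= 1))
  if (all(rates == 0)) return(panel)
  female <- as.numeric(panel$gender == "female")
  centred <- female - mean(female)
  for (v in names(rates)) {
    r <- rates[[v]]
    if (r <= 0 || !v %in% names(panel)) next
    pr <- plogis(qlogis(r) + shift * centred)
    blank <- runif(nrow(panel)) < pr
    panel[[v]][blank] <- NA
  }
  # re-derive, with NA propagation
  if ("employed" %in% names(panel)) {
    panel$unemployed <- 1L - panel$employed
  }
  if ("ghq" %in% names(panel)) panel$caseness <- derive_caseness(panel$ghq)
  if ("income" %in% names(panel)) {
    panel$log_income <- log_income(panel$income)
    panel <- derive_poverty(panel)
  }
  panel
}
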