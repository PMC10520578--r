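test_that("standardised mean differences match hand computation", {
  # identical groups
  expect_equal(smd(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1)), 0)
  # means 1 vs 0 with unit variances
  set.seed(2)
  x <- c(rnorm(5e4, 0, 1), rnorm(5e4, 1, 1))
  g <- rep(0:1, each = 5e4)
  expect_lt(abs(smd(x, g) - 1), 0.02)
  # binary covariate uses proportions
  b <- c(rep(0, 6), rep(1, 4), rep(0, 2), rep(1, 8))
  gb <- rep(0:1, each = 10)
  p1 <- 0.8; p0 <- 0.4
  expect_equal(smd(b, gb),
               abs(p1 - p0) / sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2))
  # categorical expands to one SMD per level
  f <- factor(c("a", "a", "b", "c", "a", "b", "b", "c"))
  gf <- c(0, 0, 0, 0, 1, 1, 1, 1)
  s <- smd(f, gf)
  expect_named(s, c("a", "b", "c"))
  # zero pooled variance with unequal means flags infinity
  expect_equal(smd(c(0, 0, 1, 1), c(0, 0, 1, 1)), Inf)
})

test_that("smd is symmetric in group labels and affine invariant", {
  set.seed(5)
  x <- rnorm(400); g <- rbinom(400, 1, 0.4); w <- runif(400, 0.5, 2)
  expect_equal(smd(x, g, w), smd(x, 1 - g, w))
  expect_equal(smd(3 * x - 7, g, w), smd(x, g, w))
})

test_that("randomised exposure yields stabilised weights centred at one", {
  p <- sim_params(6000, seed = 61,
                  employment = list(persistence = 0, female = 0,
                                    edu_medium = 0, edu_low = 0,
                                    pcs_lag = 0, benefits_lag = 0,
                                    caseness_lag = 0, n_children_lag = 0,
                                    intercept = qlogis(0.26),
                                    wave1_intercept = qlogis(0.26)))
  tab <- build_analysis_table(generate_panel(p))
  ws <- fit_exposure_weights(tab)
  expect_lt(abs(mean(ws$sw_a) - 1), 0.02)
  expect_true(all(ws$sw_m == 1))
  expect_identical(ws$mode, "TE")
  # weighting exchangeable data does not harm balance
  bal <- balance_report(tab, variable_roles(), ws)
  expect_true(all(abs(bal$smd_post - bal$smd_pre) < 0.05))
})

test_that("exposure weights equal the per-stratum probability ratio", {
  tab <- toy_weight_table()
  roles <- toy_roles()
  ws <- fit_exposure_weights(tab, roles)
  # independent oracle: glm fits of the same two models (marginal
  # stabilising numerator)
  den <- glm(unemployed ~ z + age + age_sq + unemployed_lag,
             binomial(), tab)
  num <- glm(unemployed ~ 1, binomial(), tab)
  pd <- ifelse(tab$unemployed == 1, fitted(den), 1 - fitted(den))
  pn <- ifelse(tab$unemployed == 1, fitted(num), 1 - fitted(num))
  expect_equal(ws$sw_a, pn / pd, tolerance = 1e-6)
  # closed form per stratum at large n: P(A=1|z) in {0.3, 0.6} and the
  # numerator is the marginal P(A=1) = 0.45
  p_marg <- mean(tab$unemployed)
  hand <- ifelse(tab$unemployed == 1,
                 p_marg / c(0.3, 0.6)[tab$z + 1],
                 (1 - p_marg) / (1 - c(0.3, 0.6)[tab$z + 1]))
  # cell means of the fitted weights against the closed form (the
  # per-observation weights also carry finite-sample noise from the
  # age terms in the denominator model)
  cells <- interaction(tab$z, tab$unemployed)
  expect_lt(max(abs(tapply(ws$sw_a, cells, mean) -
                      tapply(hand, cells, mean))), 0.03)
  expect_lt(mean(abs(ws$sw_a - hand)), 0.03)
})

test_that("mediator weights equal the closed-form normal density ratio", {
  tab <- toy_weight_table(n = 5000, seed = 101)
  # make income depend on the confounder so the ratio is non-trivial
  set.seed(102)
  tab$log_income <- 7 + 0.4 * tab$unemployed - 0.5 * tab$z + rnorm(5000, 0, 0.3)
  roles <- toy_roles()
  ws <- fit_mediator_weights(tab, roles)
  expect_identical(ws$mode, "CDE")
  # oracle via lm + dnorm on the same conditioning sets
  fden <- lm(log_income ~ unemployed + z + age + age_sq + unemployed_lag,
             data = tab)
  fnum <- lm(log_income ~ unemployed + z, data = tab)
  sden <- sqrt(sum(residuals(fden)^2) / (nrow(tab) - length(coef(fden))))
  snum <- sqrt(sum(residuals(fnum)^2) / (nrow(tab) - length(coef(fnum))))
  ratio <- dnorm(tab$log_income, fitted(fnum), snum) /
    dnorm(tab$log_income, fitted(fden), sden)
  expect_equal(ws$sw_m, ratio, tolerance = 1e-6)
  expect_equal(ws$w, ws$sw_a * ws$sw_m)
})

test_that("mediator independent of covariates given exposure gives unit weights", {
  tab <- toy_weight_table(n = 8000, seed = 103)
  set.seed(104)
  tab$log_income <- 7 + 0.3 * tab$unemployed + rnorm(8000, 0, 0.4)
  ws <- fit_mediator_weights(tab, toy_roles())
  expect_lt(abs(mean(ws$sw_m) - 1), 0.02)
  expect_lt(sd(ws$sw_m), 0.05)
})

test_that("weight truncation clips at empirical percentiles only when asked", {
  base <- fit_exposure_weights(default_sim_table())
  expect_equal(base$summary[["fraction_truncated"]], 0)
  tr <- truncate_weights(base, 1, 99)
  expect_lte(max(tr$w), quantile(base$w, 0.99))
  expect_gte(min(tr$w), quantile(base$w, 0.01))
  expect_lt(tr$truncation$fraction, 0.025)
  # all weights equal -> no change
  eq <- base; eq$w <- rep(2, length(eq$w))
  expect_equal(truncate_weights(eq)$w, eq$w)
  # one extreme weight among ones clips to the 99th percentile
  ex <- base; ex$w <- c(rep(1, 999), 1e6)
  tr2 <- truncate_weights(ex)
  expect_equal(max(tr2$w), unname(quantile(ex$w, 0.99)))
  expect_error(truncate_weights(base, 60, 40), "percentiles")
})

test_that("planted confounding is removed by weighting at moderate n", {
  tab <- default_sim_table()
  roles <- variable_roles()
  ws <- fit_exposure_weights(tab, roles)
  bal <- balance_report(tab, roles, ws)
  # lagged exposure is the most imbalanced covariate before weighting
  expect_equal(bal$covariate[which.max(bal$smd_pre)], "unemployed_lag")
  expect_gt(max(bal$smd_pre), 0.2)
  # weighting pulls every confounder towards balance
  expect_lt(max(bal$smd_post), 0.15)
  expect_named(bal, c("covariate", "smd_pre", "smd_post", "balance_pre",
                      "balance_post"))
})

test_that("weighted prevalences match direct standardisation in a discrete world", {
  # two strata z with additive-logit risks; frequency-weighted rows make
  # the MLE exact, so standardisation must match stratification exactly
  b0 <- -1.2; bA <- 0.8; bz <- 0.6
  grid <- expand.grid(a = 0:1, z = 0:1, y = 0:1)
  pz <- c(`0` = 0.7, `1` = 0.3)
  pa_z <- c(`0` = 0.2, `1` = 0.5)
  py <- plogis(b0 + bA * grid$a + bz * grid$z)
  w <- pz[as.character(grid$z)] *
    ifelse(grid$a == 1, pa_z[as.character(grid$z)],
           1 - pa_z[as.character(grid$z)]) *
    ifelse(grid$y == 1, py, 1 - py)
  X <- cbind(`(Intercept)` = 1, a = grid$a, z = grid$z)
  fit <- weighted_logistic(X, grid$y, w)
  expect_equal(unname(coef(fit)[["a"]]), bA, tolerance = 1e-7)
  ms <- marginal_standardise(fit, X, "a", w, y = grid$y)
  r1_hand <- sum(pz * plogis(b0 + bA + bz * c(0, 1)))
  r0_hand <- sum(pz * plogis(b0 + bz * c(0, 1)))
  expect_equal(ms$risk_exposed, r1_hand, tolerance = 1e-8)
  expect_equal(ms$risk_unexposed, r0_hand, tolerance = 1e-8)
})
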