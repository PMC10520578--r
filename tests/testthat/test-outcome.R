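test_that("saturated 2x2 fit recovers the cross-product odds ratio", {
  # counts: exposed cases 30, exposed non-cases 70, unexposed 20/180
  a <- c(1, 1, 0, 0); y <- c(1, 0, 1, 0); n <- c(30, 70, 20, 180)
  X <- cbind(intercept = 1, exposure = a)
  fit <- weighted_logistic(X, y, w = n)
  expect_equal(unname(coef(fit)[["exposure"]]),
               log((30 * 180) / (70 * 20)), tolerance = 1e-9)
  expect_equal(unname(coef(fit)[["intercept"]]), log(20 / 180),
               tolerance = 1e-9)
  # doubling all weights leaves coefficients unchanged
  fit2 <- weighted_logistic(X, y, w = 2 * n)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-10)
})

test_that("IRLS agrees with glm and with an exhaustive likelihood grid", {
  set.seed(17)
  x <- rnorm(300); X <- cbind(1, x)
  y <- rbinom(300, 1, plogis(-0.5 + 0.9 * x))
  w <- runif(300, 0.5, 2)
  fit <- weighted_logistic(X, y, w)
  ref <- suppressWarnings(glm.fit(X, y, weights = w, family = binomial()))
  expect_equal(unname(coef(fit)), unname(ref$coefficients),
               tolerance = 1e-8)
  # brute-force grid over (intercept, slope): coarse pass then a fine
  # pass around the coarse optimum
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(w * (y * log(p) + (1 - y) * log(1 - p)))
  }
  search <- function(b0s, b1s) {
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    grid[which.max(mapply(ll, grid$b0, grid$b1)), ]
  }
  coarse <- search(seq(-2, 1, by = 0.02), seq(-0.5, 2.5, by = 0.02))
  best <- search(seq(coarse$b0 - 0.03, coarse$b0 + 0.03, by = 0.0005),
                 seq(coarse$b1 - 0.03, coarse$b1 + 0.03, by = 0.0005))
  expect_lt(abs(unname(coef(fit)[1]) - best$b0), 1e-3)
  expect_lt(abs(unname(coef(fit)[2]) - best$b1), 1e-3)
})

test_that("degenerate and ill-posed designs are rejected with diagnostics", {
  X <- cbind(1, c(0, 0, 1, 1))
  expect_error(weighted_logistic(X, c(0, 0, 0, 0)), "converge|separat")
  expect_error(weighted_logistic(X, c(0, 0, 1, 1)), "converge|separat")
  X2 <- cbind(a = 1, b = c(1, 2, 1, 2), c = c(2, 4, 2, 4))
  expect_error(weighted_logistic(X2, c(0, 1, 0, 1)), "aliased.*c")
  expect_error(weighted_logistic(X, c(0, 1, 0, 1), w = c(1, 1, 0, 1)),
               "weights")
})

test_that("marginal standardisation reproduces hand-evaluated logistic risks", {
  # known coefficients, no fitting: predict each row with exposure on/off
  X <- cbind(intercept = 1, a = c(0, 1, 0, 1), u = c(0.2, -1, 2, 0.5))
  beta <- c(-0.7, 0.6, 0.3)
  fit <- structure(list(coefficients = setNames(beta, colnames(X))),
                   class = "msm_fit")
  w <- c(1, 2, 1, 1)
  ms <- marginal_standardise(fit, X, "a", w)
  r1 <- weighted.mean(plogis(-0.7 + 0.6 + 0.3 * X[, "u"]), w)
  r0 <- weighted.mean(plogis(-0.7 + 0.3 * X[, "u"]), w)
  expect_equal(ms$risk_exposed, r1, tolerance = 1e-10)
  expect_equal(ms$risk_unexposed, r0, tolerance = 1e-10)
  expect_equal(ms$odds_ratio, (r1 / (1 - r1)) / (r0 / (1 - r0)),
               tolerance = 1e-10)
  expect_equal(ms$risk_difference_pp, 100 * (r1 - r0), tolerance = 1e-10)
  # standardised risks lie between the extreme fitted probabilities
  lo <- min(plogis(c(-0.7 + 0.6 + 0.3 * X[, "u"], -0.7 + 0.3 * X[, "u"])))
  hi <- max(plogis(c(-0.7 + 0.6 + 0.3 * X[, "u"], -0.7 + 0.3 * X[, "u"])))
  expect_true(all(c(ms$risk_exposed, ms$risk_unexposed) >= lo - 1e-12))
  expect_true(all(c(ms$risk_exposed, ms$risk_unexposed) <= hi + 1e-12))
})

test_that("zero exposure coefficient gives OR 1 and no risk difference", {
  X <- cbind(1, a = rep(0:1, 10), z = rnorm(20))
  fit <- structure(list(coefficients = setNames(c(-1, 0, 0.5),
                                                c("i", "a", "z"))),
                   class = "msm_fit")
  ms <- marginal_standardise(fit, X, 2)
  expect_equal(ms$odds_ratio, 1)
  expect_equal(ms$risk_difference_pp, 0)
})

test_that("population attributable fraction follows the prevalence formula", {
  expect_equal(paf(0.20, 0.20), 0)
  expect_equal(paf(0.20, 0.18), 10)
  expect_equal(paf(0.18, 0.20), -100 * 0.02 / 0.18)
  expect_error(paf(0, 0.1), "prev_total")
  # monotone increasing in total prevalence for fixed unexposed prevalence
  tots <- seq(0.15, 0.4, by = 0.01)
  expect_true(all(diff(paf(tots, 0.15)) > 0))
})

test_that("double robustness protects against one misspecified model", {
  # weight model deliberately missing the strongest confounder (lagged
  # caseness): with the outcome model still correct, the TE estimate
  # stays near the oracle while the naive contrast is badly biased
  p <- sim_params(6000, seed = 314)
  tab <- build_analysis_table(generate_panel(p))
  d <- msmmed:::build_design(tab, variable_roles())
  truth <- oracle_effects(p, n_mc = 1e5)

  broken <- d
  drop_cols <- d$sets$den_a[grepl("caseness_lag|pcs_lag|benefits_lag",
                                  d$colnames[d$sets$den_a])]
  broken$sets$den_a <- setdiff(d$sets$den_a, drop_cols)
  ws <- msmmed:::fit_exposure_weights_design(broken)
  f <- msmmed:::fit_logit_set(d, "out_te", y = d$y, w = ws$w)
  X_te <- d$X[, d$sets$out_te, drop = FALSE]
  f$coefficients <- setNames(drop(f$coef), colnames(X_te))
  dr <- marginal_standardise(f, X_te, d$exp_pos_te, w = ws$w, y = d$y)

  naive_rd <- 100 * (mean(d$y[d$a == 1]) - mean(d$y[d$a == 0]))
  bias_dr <- abs(dr$risk_difference_pp - truth$oracle_te_rd)
  bias_naive <- abs(naive_rd - truth$oracle_te_rd)
  expect_lt(bias_dr, 0.25 * bias_naive)
})
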