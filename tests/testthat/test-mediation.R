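test_that("percentage mediation reproduces the published worked examples", {
  # primary analysis risk differences, printed to two decimals
  expect_lt(abs(percent_mediation(7.09, 6.08) - 14.22) / 14.22, 0.005)
  # job-loss transition
  expect_lt(abs(percent_mediation(7.42, 6.30) - 15.10) / 15.10, 0.005)
  # equal effects mediate nothing; zero total effect is undefined
  expect_equal(percent_mediation(5.5, 5.5), 0)
  expect_equal(percent_mediation(-3, -3), 0)
  expect_warning(out <- percent_mediation(0, 1), "undefined")
  expect_true(is.na(out))
})

test_that("cluster bootstrap of a sample mean matches sampling theory", {
  set.seed(8)
  n <- 200; sigma <- 2
  panel <- data.frame(pid = 1:n, x = rnorm(n, 5, sigma))
  bi <- bootstrap_interval(panel, function(d) c(mu = mean(d$x)),
                           B = 1000, seed = 9)
  expect_lt(abs(bi$se[["mu"]] - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.15)
  # CI symmetric about the point by construction
  expect_equal(bi$ci["upper", "mu"] - bi$point[["mu"]],
               bi$point[["mu"]] - bi$ci["lower", "mu"], tolerance = 1e-10)
  expect_equal(bi$n_failed, 0)
  # degenerate constant estimator -> zero-width interval
  bc <- bootstrap_interval(panel, function(d) c(k = 42), B = 60, seed = 1)
  expect_equal(bc$se[["k"]], 0)
  expect_equal(unname(diff(bc$ci[, "k"])), 0)
})

test_that("transition tables keep only those at risk, disjointly", {
  # 4 persons: always employed, always unemployed, loses job, gains job
  pan <- data.frame(
    pid = rep(1:4, each = 3), wave = rep(1:3, 4),
    employed = c(1, 1, 1, 0, 0, 0, 1, 0, 0, 0, 1, 1),
    income = rep(1000, 12), ghq = rep(2L, 12),
    age = rep(40, 12), gender = rep("f", 12), ethnicity = rep("w", 12),
    education = rep("m", 12), tenure = rep("o", 12),
    benefits = rep(0L, 12), relationship = rep("s", 12),
    n_children = rep(0L, 12), pcs = rep(50, 12), mcs = rep(50, 12),
    region = rep("r1", 12)
  )
  tab <- build_analysis_table(pan)
  gain <- transition_table(tab, "gain")
  loss <- transition_table(tab, "loss")
  # manual enumeration of at-risk person-waves (t = 2, 3):
  # unemployed at t-1: person 2 (both), person 3 (wave 3), person 4 (wave 2)
  expect_equal(nrow(gain), 4)
  expect_setequal(paste(gain$pid, gain$wave),
                  c("2 2", "2 3", "3 3", "4 2"))
  # employed at t-1: person 1 (both), person 3 (wave 2), person 4 (wave 3)
  expect_equal(nrow(loss), 4)
  expect_setequal(paste(loss$pid, loss$wave),
                  c("1 2", "1 3", "3 2", "4 3"))
  # the two at-risk sets partition the outcome rows
  expect_equal(nrow(gain) + nrow(loss), nrow(tab))
  expect_length(intersect(paste(gain$pid, gain$wave),
                          paste(loss$pid, loss$wave)), 0)
  # exposure coding: gain = became employed, loss = became unemployed
  expect_equal(gain$transition, 1 - gain$unemployed)
  expect_equal(loss$transition, loss$unemployed)
  # always-employed persons are at risk only of loss
  expect_false(1 %in% gain$pid)
  expect_true(1 %in% loss$pid)
  # the lagged exposure leaves the adjustment set of the returned roles
  expect_false("unemployed" %in% attr(gain, "roles")$lag_extra)
  expect_identical(attr(gain, "roles")$exposure, "transition")
})

test_that("bootstrap engine replicates agree with the reference R path", {
  tab <- default_sim_table()
  d <- msmmed:::build_design(tab, variable_roles())
  pf <- msmmed:::point_fits(d)
  starts <- list(den = unname(pf$ws_te$models$den$coef),
                 num = unname(pf$ws_te$models$num$coef),
                 out_te = unname(pf$f_te$coef),
                 out_cde = unname(pf$f_cde$coef))
  # identity resample: the engine must reproduce the double-precision
  # point estimates (the float path is only used for replicates)
  idd <- matrix(0:(d$n_persons - 1), ncol = 1)
  one <- msmmed:::cpp_boot_mediation(
    d$X, d$sets$den_a - 1L, d$sets$num_a - 1L, d$sets$out_te - 1L,
    d$sets$out_cde - 1L, d$sets$mden - 1L, d$sets$mnum - 1L,
    d$a, d$y, d$m, d$exp_pos_te - 1L, d$exp_pos_cde - 1L,
    d$person - 1L, d$n_persons, idd, starts, 8L)
  pt <- msmmed:::point_stats(pf)
  expect_equal(one[1, "ok"][[1]], 1)
  expect_lt(max(abs(one[1, 1:9] - pt) / pmax(abs(pt), 1)), 2e-3)

  # a non-trivial resample, cross-checked against plain R refitting with
  # the person multiplicities as frequency weights
  set.seed(55)
  take <- sample.int(d$n_persons, d$n_persons, replace = TRUE)
  draw <- matrix(take - 1L, ncol = 1)
  eng <- msmmed:::cpp_boot_mediation(
    d$X, d$sets$den_a - 1L, d$sets$num_a - 1L, d$sets$out_te - 1L,
    d$sets$out_cde - 1L, d$sets$mden - 1L, d$sets$mnum - 1L,
    d$a, d$y, d$m, d$exp_pos_te - 1L, d$exp_pos_cde - 1L,
    d$person - 1L, d$n_persons, draw, starts, 8L)
  mult <- tabulate(take, d$n_persons)[d$person]
  rows <- rep(seq_len(nrow(tab)), times = mult)
  boot <- tab[rows, , drop = FALSE]
  ref <- msmmed:::point_stats(
    msmmed:::point_fits(msmmed:::build_design(boot, variable_roles())))
  expect_lt(max(abs(eng[1, 1:9] - ref) / pmax(abs(ref), 1)), 5e-3)
})

test_that("identical seeds reproduce the mediation result exactly", {
  tab <- default_sim_table()
  r1 <- run_mediation(tab, B = 25, seed = 99)
  r2 <- run_mediation(tab, B = 25, seed = 99)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$pct_ci, r2$pct_ci)
  expect_identical(r1$te$odds_ratio, r2$te$odds_ratio)
})

test_that("sign coherence holds on bootstrap replicates", {
  tab <- default_sim_table()
  r <- run_mediation(tab, B = 60, seed = 7)
  reps <- r$replicates
  same_sign <- sign(reps[, "te_rd"]) == sign(reps[, "cde_rd"]) &
    abs(reps[, "cde_rd"]) < abs(reps[, "te_rd"])
  pm <- reps[same_sign, "pct_mediation"]
  expect_true(all(pm > 0 & pm < 100))
})

test_that("m = 1 imputation with no missingness equals the direct run", {
  tab <- default_sim_table()
  direct <- run_mediation(tab, B = 10, m = 1, seed = 5)
  imp <- impute_mice(tab, imputation_spec(m = 1, seed = 6))
  eff_d <- estimate_effect(tab, mode = "TE")
  eff_i <- estimate_effect(imp, mode = "TE")
  expect_equal(eff_i$risk_difference_pp, eff_d$risk_difference_pp,
               tolerance = 1e-12)
  expect_equal(direct$te$risk_difference_pp, eff_d$risk_difference_pp,
               tolerance = 1e-12)
})

test_that("stratified runs partition the sample and agree when homogeneous", {
  tab <- default_sim_table()
  out <- stratified_run(tab, B = 15, m = 1, seed = 11,
                        strata = c("gender", "age_band"))
  byg <- out$gender
  expect_setequal(names(byg), c("male", "female"))
  expect_equal(sum(vapply(byg, function(r) r$n_observations, numeric(1))),
               nrow(tab))
  # gender has only a prevalence (not effect-size) role in the default
  # generator, so stratum TE estimates agree within joint bootstrap error
  se2 <- sqrt(byg$male$boot_se[["te_rd"]]^2 +
                byg$female$boot_se[["te_rd"]]^2)
  expect_lt(abs(byg$male$te$risk_difference_pp -
                  byg$female$te$risk_difference_pp), 3 * se2)
  bands <- out$age_band
  expect_length(bands, 2)
  expect_equal(sum(vapply(bands, function(r) r$n_observations,
                          numeric(1))), nrow(tab))
})

test_that("planted age-band effect modification is recovered", {
  # stronger mediator pathway for the older band: its percent mediation
  # should exceed the younger band's in nearly all replicates
  wins <- 0
  for (r in 1:5) {
    p <- sim_params(3000, seed = 700 + r,
                    outcome = list(beta_log_income = -0.1,
                                   beta_log_income_older = -0.75))
    tab <- build_analysis_table(generate_panel(p))
    out <- stratified_run(tab, strata = "age_band", B = 5, m = 1,
                          seed = 800 + r)
    pm <- vapply(out$age_band, function(x) x$pct_mediation, numeric(1))
    wins <- wins + (pm[["older_41_64"]] > pm[["younger_25_40"]])
  }
  expect_gte(wins, 4)
})

test_that("bootstrap CI width shrinks roughly as one over root n", {
  widths <- vapply(c(1000, 4000), function(n) {
    p <- sim_params(n, seed = 1234)
    tab <- build_analysis_table(generate_panel(p))
    r <- run_mediation(tab, B = 100, seed = 4321)
    unname(diff(r$pct_ci))
  }, numeric(1))
  ratio <- widths[1] / widths[2]
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})
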