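test_that("caseness cut-off sits at a GHQ score of four", {
  expect_identical(derive_caseness(c(0L, 3L, 4L, 12L, NA)),
                   c(0L, 0L, 1L, 1L, NA))
  expect_error(derive_caseness(13L), "0, 12")
  expect_error(derive_caseness(-1L), "0, 12")
})

test_that("poverty line is 60% of the sample median, scale invariant", {
  p1 <- derive_poverty(data.frame(income = c(1000, 1000, 1000)))
  expect_identical(p1$poverty, c(0L, 0L, 0L))
  p2 <- derive_poverty(data.frame(income = c(100, 1000, 1000, 1000)))
  expect_identical(p2$poverty, c(1L, 0L, 0L, 0L))
  expect_equal(attr(p2, "poverty_line"), 600)
  # doubling all incomes leaves flags unchanged
  x <- data.frame(income = c(250, 400, 900, 1500, 2200, NA))
  expect_identical(derive_poverty(x)$poverty,
                   derive_poverty(transform(x, income = 2 * income))$poverty)
  expect_true(is.na(derive_poverty(x)$poverty[6]))
  expect_error(derive_poverty(data.frame(income = c(NA_real_, NA_real_))),
               "missing")
})

test_that("poverty flags match a brute-force scan on random inputs", {
  set.seed(14)
  for (i in 1:20) {
    inc <- rlnorm(200, 7, 0.6)
    flagged <- derive_poverty(data.frame(income = inc))$poverty
    brute <- vapply(inc, function(v) {
      as.integer(v < 0.6 * median(inc))
    }, integer(1))
    expect_identical(flagged, brute)
  }
})

test_that("modified-OECD equivalisation follows the composition scale", {
  expect_equal(equivalise_income(1000, 1, 0), 1000)
  expect_equal(equivalise_income(1800, 2, 1), 1000)
  expect_equal(equivalise_income(1500, 2, 0), 1000)
  expect_error(equivalise_income(1000, 0, 0), "n_adults")
  # inverse scale recovers household income
  set.seed(3)
  hh <- runif(50, 500, 4000)
  ad <- sample(1:3, 50, TRUE)
  ch <- sample(0:4, 50, TRUE)
  eq <- equivalise_income(hh, ad, ch)
  expect_equal(eq * (1 + 0.5 * (ad - 1) + 0.3 * ch), hh, tolerance = 1e-12)
})

test_that("log income floors non-positive values and is monotone", {
  expect_equal(log_income(exp(1)), 1)
  expect_equal(log_income(0), log(1))
  expect_true(is.finite(log_income(-50)))
  expect_true(is.na(log_income(NA)))
  x <- sort(runif(100, -10, 5000))
  expect_true(all(diff(log_income(x)) >= 0))
})

test_that("working-age restriction keeps the closed 25-64 interval", {
  pan <- data.frame(age = c(24, 25, 64, 65))
  expect_equal(restrict_sample(pan)$age, c(25, 64))
  expect_equal(nrow(restrict_sample(data.frame(age = c(10, 70)))), 0)
  once <- restrict_sample(pan)
  expect_identical(restrict_sample(once), once)
})

test_that("analysis table pairs wave-t outcomes with wave-(t-1) covariates", {
  tab <- build_analysis_table(tiny_panel())
  # person 1 has waves 1..3 -> 2 outcome rows; person 2 -> 1; person 3 -> 0
  expect_equal(nrow(tab), 3)
  expect_equal(table(tab$pid)[["1"]], 2)
  expect_false(3 %in% tab$pid)
  # cell-wise lag checks against the hand-built fixture
  r12 <- tab[tab$pid == 1 & tab$wave == 2, ]
  expect_equal(r12$unemployed_lag, 0L)        # employed at wave 1
  expect_equal(r12$tenure_lag, factor("owner", levels = c("owner", "renter")))
  expect_equal(r12$pcs_lag, 55)
  expect_equal(r12$caseness_lag, 0L)          # ghq 1 at wave 1
  expect_equal(r12$log_income_lag, log(1500))
  r13 <- tab[tab$pid == 1 & tab$wave == 3, ]
  expect_equal(r13$unemployed_lag, 0L)
  expect_equal(r13$n_children_lag, 1L)
  r22 <- tab[tab$pid == 2 & tab$wave == 2, ]
  expect_equal(r22$unemployed_lag, 1L)
  expect_equal(r22$mcs_lag, 45)
  expect_equal(tab$age_sq, tab$age^2)
})

test_that("lagging never mixes persons and ignores gapped waves", {
  pan <- tiny_panel()
  # permuting person blocks leaves the (sorted) result unchanged
  perm <- pan[order(-pan$pid, pan$wave), ]
  t1 <- build_analysis_table(pan)
  t2 <- build_analysis_table(perm)
  expect_equal(t1[order(t1$pid, t1$wave), ], t2[order(t2$pid, t2$wave), ],
               ignore_attr = TRUE)
  # a gap (missing wave 2) removes the lag for wave 3
  gap <- pan[!(pan$pid == 1 & pan$wave == 2), ]
  t3 <- build_analysis_table(gap)
  expect_false(any(t3$pid == 1 & t3$wave == 3))
  # duplicated person-wave errors
  expect_error(build_analysis_table(rbind(pan, pan[1, ])), "duplicate")
})

test_that("role assignments must be disjoint", {
  expect_error(variable_roles(exposure = "caseness"), "more than one role")
})
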