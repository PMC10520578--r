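# Small deterministic fixtures shared across tests.

# A hand-built 3-person panel with known lag structure.
tiny_panel <- function() {
  data.frame(
    pid = c(1, 1, 1, 2, 2, 3),
    wave = c(1, 2, 3, 1, 2, 1),
    age = c(30, 31, 32, 50, 51, 40),
    gender = factor(c("male", "male", "male", "female", "female", "male"),
                    levels = c("male", "female")),
    ethnicity = factor(rep("white", 6), levels = c("white", "nonwhite")),
    education = factor(c(rep("high", 3), rep("low", 2), "medium"),
                       levels = c("high", "medium", "low")),
    region = factor(rep("r01", 6), levels = sprintf("r%02d", 1:12)),
    tenure = factor(c("owner", "owner", "renter", "renter", "renter",
                      "owner"), levels = c("owner", "renter")),
    benefits = c(0L, 0L, 1L, 1L, 1L, 0L),
    relationship = factor(c("coupled", "coupled", "single", "single",
                            "coupled", "coupled"),
                          levels = c("single", "coupled")),
    n_children = c(0L, 1L, 1L, 2L, 2L, 0L),
    pcs = c(55, 54, 53, 40, 41, 50),
    mcs = c(52, 50, 48, 45, 46, 51),
    employed = c(1L, 1L, 0L, 0L, 1L, 1L),
    income = c(1500, 1600, 1200, 700, 900, 2000),
    ghq = c(1L, 2L, 5L, 6L, 3L, 0L)
  )
}

# A moderately sized default simulation, cached per session.
default_sim_table <- local({
  cache <- NULL
  function(n = 2500, seed = 421) {
    if (is.null(cache)) {
      panel <- generate_panel(sim_params(n, seed = seed))
      cache <<- build_analysis_table(panel)
    }
    cache
  }
})

# Minimal roles + table for closed-form weight checks: one binary
# confounder z, everything else noise-free plumbing.
toy_weight_table <- function(n = 20000, seed = 99,
                             p_a_z = c(`0` = 0.3, `1` = 0.6)) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  a <- rbinom(n, 1, p_a_z[as.character(z)])
  data.frame(
    pid = seq_len(n), wave = 2L,
    unemployed = a, z = z,
    age = runif(n, 30, 50), age_sq = NA_real_,
    unemployed_lag = rbinom(n, 1, 0.3),
    log_income = rnorm(n, 7, 0.5),
    poverty = rbinom(n, 1, 0.2),
    caseness = rbinom(n, 1, 0.2)
  ) |> transform(age_sq = age^2)
}

toy_roles <- function() {
  variable_roles(baseline = "z", time_varying = character(0),
                 lag_extra = "unemployed")
}
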