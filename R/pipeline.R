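effect_row <- function(label, eff) {
  data.frame(
    effect = label,
    odds_ratio = eff$odds_ratio,
    or_lower = eff$or_ci[1], or_upper = eff$or_ci[2],
    risk_difference_pp = eff$risk_difference_pp,
    rd_lower = eff$rd_ci[1], rd_upper = eff$rd_ci[2],
    prevalence_unexposed_pp = eff$prevalence_unexposed_pp,
    prev_lower = eff$prev_ci[1], prev_upper = eff$prev_ci[2],
    paf_pct = eff$paf_pct,
    n_individuals = eff$n_individuals,
    n_observations = eff$n_observations
  )
}

mediation_table <- function(res, label = "full_sample") {
  out <- rbind(effect_row("total", res$te), effect_row("direct", res$cde))
  out$analysis <- label
  out$pct_mediation <- res$pct_mediation
  out$pct_lower <- res$pct_ci[1]
  out$pct_upper <- res$pct_ci[2]
  out[, c("analysis", setdiff(names(out), "analysis"))]
}

#' Run the full mediation pipeline
#'
#' Executes the whole analysis from a validated configuration: obtain
#' the panel (simulate or read CSV), restrict to working age, derive
#' analysis variables, build the lagged analysis table, apply the
#' high-missingness drop rule, estimate the total and controlled direct
#' effects with percentage mediation and cluster-bootstrap intervals
#' (imputing if the data have missing values, unless `complete_case`),
#' and optionally the transition (job gain/loss) and stratified
#' analyses. When `output_dir` is set, writes `table1.csv` (TE/CDE, PAF,
#' percent mediation), `table2.csv` (transitions), `table3.csv`
#' (strata), `balance_te.csv` / `balance_cde.csv`, `panel.csv` (for
#' simulated input), and `manifest.json` echoing configuration, seeds
#' and stage row counts.
#'
#' @param config A `pipeline_config` from [load_validate_config()] /
#'   [build_pipeline_config()], or a named list with that structure.
#' @param panel Optional pre-loaded panel overriding the config input.
#' @return A list (class `pipeline_report`) with the analysis table,
#'   results, balance reports and manifest, invisibly when writing.
#' @export
run_full_pipeline <- function(config, panel = NULL) {
  if (!inherits(config, "pipeline_config")) {
    config <- build_pipeline_config(config)
  }
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- "input"
  result <- tryCatch({
    if (is.null(panel)) {
      panel <- if (!is.null(config$simulation)) {
        generate_panel(config$simulation)
      } else {
        read.csv(config$input_csv, stringsAsFactors = TRUE)
      }
    }
    say("input: %d rows, %d persons", nrow(panel),
        length(unique(panel[[config$roles$id]])))

    stage <- "restrict"
    panel <- restrict_sample(panel, msmmed_defaults$age_range)
    say("restrict to ages %d-%d: %d rows",
        msmmed_defaults$age_range[1], msmmed_defaults$age_range[2],
        nrow(panel))

    stage <- "derive"
    panel <- derive_analysis_variables(panel, config$roles)

    stage <- "lag"
    tab <- build_analysis_table(panel, config$roles)
    say("analysis table: %d outcome rows", nrow(tab))

    stage <- "drop_rule"
    tab <- suppressMessages(drop_high_missingness(
      tab, max_missing = msmmed_defaults$max_missing))
    say("drop rule (>%d of 22 missing): removed %d rows",
        msmmed_defaults$max_missing, attr(tab, "n_dropped"))

    stage <- "primary"
    res <- run_mediation(tab, config$roles, B = config$B, m = config$m,
                         seed = config$seed,
                         complete_case = config$complete_case,
                         truncate = config$truncate, conf = config$conf)
    say("primary: TE rd %.2f pp, CDE rd %.2f pp, %% mediation %.2f",
        res$te$risk_difference_pp, res$cde$risk_difference_pp,
        res$pct_mediation)

    stage <- "balance"
    model_cols <- intersect(
      c(config$roles$exposure, config$roles$mediator,
        config$roles$mediator_binary, config$roles$outcome,
        config$roles$baseline, config$roles$age, lag_names(config$roles)),
      names(tab))
    cc <- tab[complete.cases(tab[, model_cols, drop = FALSE]), ,
              drop = FALSE]
    balance <- NULL
    if (nrow(cc) > 50) {
      cc <- rederive_after_imputation(cc)
      ws_te <- fit_exposure_weights(cc, config$roles)
      ws_cde <- fit_mediator_weights(cc, config$roles, ws_te)
      balance <- list(te = balance_report(cc, config$roles, ws_te),
                      cde = balance_report(cc, config$roles, ws_cde))
    }

    transitions <- NULL
    if (config$transitions) {
      stage <- "transitions"
      transitions <- lapply(c(gain = "gain", loss = "loss"), function(d) {
        tt <- transition_table(tab, d, config$roles)
        run_mediation(tt, B = config$B, m = config$m,
                      seed = config$seed + if (d == "gain") 101L else 202L,
                      complete_case = config$complete_case,
                      truncate = config$truncate, conf = config$conf)
      })
    }

    strata <- NULL
    if (length(config$strata)) {
      stage <- "strata"
      strata <- stratified_run(tab, config$roles, strata = config$strata,
                               B = config$B, m = config$m,
                               seed = config$seed,
                               complete_case = config$complete_case,
                               min_persons = config$min_persons)
    }

    list(panel = panel, table = tab, primary = res, balance = balance,
         transitions = transitions, strata = strata)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package = "msmmed",
    seed = config$seed,
    B = config$B, m = config$m,
    complete_case = config$complete_case,
    truncation = config$truncate,
    defaults = msmmed_defaults[c("smd_negligible", "smd_reasonable",
                                 "caseness_cut", "poverty_fraction",
                                 "max_missing")],
    mi_bootstrap_scheme = paste(
      "point estimate pooled over m imputations;",
      "bootstrap resamples persons from the pre-imputation table,",
      "one imputation per replicate"),
    cde_mediator = "continuous log income density ratio; poverty as outcome-model covariate",
    poverty_line = "0.6 x sample median equivalised income (unweighted)",
    log = log_lines
  )
  report <- structure(c(result, list(manifest = manifest, config = config,
                                     log = log_lines)),
                      class = "pipeline_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, config$output_dir)
    return(invisible(report))
  }
  report
}

write_report <- function(report, dir) {
  w <- function(df, file) {
    write.csv(df, file.path(dir, file), row.names = FALSE)
  }
  w(mediation_table(report$primary), "table1.csv")
  if (!is.null(report$transitions)) {
    t2 <- rbind(mediation_table(report$transitions$gain, "becoming_employed"),
                mediation_table(report$transitions$loss,
                                "becoming_unemployed"))
    w(t2, "table2.csv")
  }
  if (!is.null(report$strata)) {
    rows <- list()
    for (sv in names(report$strata)) {
      for (g in names(report$strata[[sv]])) {
        rows[[paste(sv, g)]] <-
          mediation_table(report$strata[[sv]][[g]], paste(sv, g, sep = ":"))
      }
    }
    if (length(rows)) w(do.call(rbind, rows), "table3.csv")
  }
  if (!is.null(report$balance)) {
    w(as.data.frame(report$balance$te), "balance_te.csv")
    w(as.data.frame(report$balance$cde), "balance_cde.csv")
  }
  if (!is.null(report$config$simulation)) {
    w(report$panel, "panel.csv")
    truth <- oracle_effects(report$config$simulation, n_mc = 1e5)
    report$manifest$sim_truth <- truth[c("oracle_te_rd", "oracle_cde_rd",
                                         "oracle_pct_mediation",
                                         "monte_carlo_se")]
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$primary)
  invisible(x)
}
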