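# Central table of numeric defaults used by the pipeline. Every value
# is part of the analysis definition and is echoed into the manifest.
msmmed_defaults <- list(
  m = 20L,                 # imputed datasets
  B = 1000L,               # bootstrap re-samplings
  smd_negligible = 0.1,    # SMD threshold: negligible difference
  smd_reasonable = 0.2,    # SMD threshold: reasonable balance
  caseness_cut = 4L,       # GHQ-12 score defining CMD caseness
  poverty_fraction = 0.6,  # of the sample median, after housing costs
  age_range = c(25L, 64L), # working age
  max_missing = 9L,        # of the 22 required variables
  log_income_floor = 1,    # GBP/month floor before logging
  truncation = NULL        # weight truncation percentiles, off by default
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys, fills defaults
#' (m = 20 imputations, B = 1000 bootstrap re-samplings, SMD thresholds
#' 0.1/0.2, caseness cut 4, poverty line at 60% of the median, working
#' age 25--64, weight truncation off), and checks that exactly one input
#' source is present (`input_csv` or a `simulation` block).
#'
#' Top-level keys: `input_csv` or `simulation` (passed to
#' [sim_params()]), optional `roles` (arguments to [variable_roles()]),
#' `analysis` (`B`, `m`, `complete_case`, `transitions`, `strata`,
#' `min_persons`), `weights` (`truncate: [lower, upper]`),
#' `imputation` (`n_iterations`, `pmm_k`), `output_dir`, `seed`.
#'
#' @param path Path to a YAML file.
#' @return A validated object of class `pipeline_config`.
#' @export
load_validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  build_pipeline_config(raw)
}

#' @rdname load_validate_config
#' @param config A named list with the same structure as the YAML file.
#' @export
build_pipeline_config <- function(config) {
  allowed <- c("input_csv", "simulation", "roles", "analysis", "weights",
               "imputation", "output_dir", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  has_csv <- !is.null(config$input_csv)
  has_sim <- !is.null(config$simulation)
  if (has_csv == has_sim) {
    stop("exactly one of 'input_csv' or 'simulation' must be given",
         call. = FALSE)
  }
  an <- config$analysis %||% list()
  known_an <- c("B", "m", "complete_case", "transitions", "strata",
                "min_persons", "conf")
  unknown <- setdiff(names(an), known_an)
  if (length(unknown)) {
    stop("unknown analysis key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)
  sim <- NULL
  if (has_sim) {
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% seed
    sim <- do.call(sim_params, sim_args)
  }
  roles <- do.call(variable_roles, config$roles %||% list())
  cfg <- list(
    input_csv = config$input_csv,
    simulation = sim,
    roles = roles,
    B = as.integer(an$B %||% msmmed_defaults$B),
    m = as.integer(an$m %||% msmmed_defaults$m),
    complete_case = isTRUE(an$complete_case),
    transitions = isTRUE(an$transitions),
    strata = an$strata %||% character(0),
    min_persons = as.integer(an$min_persons %||% 100L),
    conf = an$conf %||% 0.95,
    truncate = config$weights$truncate %||% msmmed_defaults$truncation,
    imputation = list(
      n_iterations = as.integer(config$imputation$n_iterations %||% 10L),
      pmm_k = as.integer(config$imputation$pmm_k %||% 5L)),
    output_dir = config$output_dir,
    seed = seed,
    defaults = msmmed_defaults
  )
  if (cfg$B < 1) stop("B must be >= 1", call. = FALSE)
  if (cfg$m < 1) stop("m must be >= 1", call. = FALSE)
  if (length(cfg$strata)) {
    bad <- setdiff(cfg$strata, c("gender", "education", "age_band",
                                 "poverty"))
    if (length(bad)) stop("unknown strata: ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  input:", if (!is.null(x$input_csv)) x$input_csv
      else sprintf("simulation (n = %d, %d waves)",
                   x$simulation$n_individuals, x$simulation$n_waves), "\n")
  cat("  B =", x$B, " m =", x$m, " seed =", x$seed,
      " complete_case =", x$complete_case, "\n")
  if (length(x$strata)) cat("  strata:", paste(x$strata, collapse = ", "),
                            "\n")
  invisible(x)
}
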