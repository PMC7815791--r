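# Run configuration: YAML reading, validation, content hashing, and the
# purpose-keyed uniform draws that implement the common-random-numbers
# contract across the three counterfactual arms.

#' Generate the per-man, per-purpose uniform draws for a paired run
#'
#' Every source of randomness gets its own stream derived from
#' `(seed, purpose)`; the same matrices are consumed by all arms for shared
#' purposes, so adding or reordering arms cannot change any arm's draws.
#' Per-screen purposes are n x K matrices (attendance, PSA, mpMRI,
#' compliance, biopsy); per-man purposes are length-n vectors
#' (misclassification, treatment, survival, cure).
#'
#' @param seed Master seed.
#' @param n Cohort size.
#' @param n_screens Number of screening rounds K.
#' @return A list of uniform draws: matrices `att`, `psa`, `mri`, `comp`,
#'   `bx` and vectors `mis`, `trt`, `surv`, `cure`.
#' @export
make_draws <- function(seed, n, n_screens) {
  mat <- function(purpose) {
    set.seed(seed_for(seed, purpose))
    matrix(stats::runif(n * n_screens), nrow = n)
  }
  vec <- function(purpose) {
    set.seed(seed_for(seed, purpose))
    stats::runif(n)
  }
  list(att = mat("attendance"), psa = mat("psa_episode"),
       mri = mat("mpmri"), comp = mat("biopsy_compliance"),
       bx = mat("biopsy_sensitivity"),
       mis = vec("misclassification"), trt = vec("treatment"),
       surv = vec("survival"), cure = vec("cure"))
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file shaped like [default_config()].
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a run configuration against every module's invariants
#'
#' Runs the demography, natural-history, screening, test, treatment and
#' utility validators; errors name the offending field.
#'
#' @param config A configuration list shaped like [default_config()].
#' @return The configuration, invisibly unchanged, with compiled pieces
#'   checked.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$cohort_size) || config$cohort_size < 1) {
    stop_bad("config: cohort_size must be >= 1")
  }
  if (is.null(config$seed)) stop_bad("config: seed is required")
  compile_nh_params(config$natural_history)
  sc <- config$screening
  tryCatch(
    screening_protocol(sc$start_age, sc$stop_age, sc$interval, sc$attendance),
    error = function(e) stop_bad("screening.attendance/start/stop/interval: ",
                                 conditionMessage(e)))
  build_test_params(config$tests)
  compile_treatment_params(config$treatment)
  ut <- build_utility_table(config$utilities)
  if (any(ut$duration <= 0)) stop_bad("utilities: durations must be positive")
  config_life_table(config) # validates the life table too
  invisible(config)
}

build_test_params <- function(tests) {
  do.call(test_params, tests)
}

build_utility_table <- function(utilities) {
  if (is.null(utilities) || !length(utilities)) {
    stop_bad("config: utilities table is required")
  }
  if (is.data.frame(utilities)) {
    df <- utilities
  } else {
    df <- do.call(rbind, lapply(utilities, function(r) {
      data.frame(label = r$label, utility = r$utility, duration = r$duration)
    }))
  }
  if (!all(c("label", "utility", "duration") %in% names(df))) {
    stop_bad("utilities must have fields label, utility, duration")
  }
  check_prob(df$utility, "utilities.utility")
  df
}

config_life_table <- function(config) {
  lt <- config$life_table
  if (is.null(lt)) return(default_life_table())
  if (is.character(lt)) return(load_life_table(lt))
  if (inherits(lt, "life_table")) return(lt)
  if (is.list(lt) && !is.null(lt$path)) return(load_life_table(lt$path))
  stop_bad("config: life_table must be NULL (synthetic default), a CSV path, ",
           "or a life_table object")
}

#' Content hash of a resolved configuration
#'
#' MD5 of the canonical JSON serialization; recorded in all outputs so runs
#' can be matched to their exact parameterization.
#'
#' @param config A configuration list.
#' @return A hex string.
#' @export
config_hash <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
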