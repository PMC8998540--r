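#' Named study constants
#'
#' `EPDS_CUTOFF`: the Edinburgh Postnatal Depression Scale score (>= 10)
#' that defines a depression case in the source cohort.  The scale itself
#' is never simulated; the cutoff matters only as the definition behind
#' `TARGET_PREVALENCE`, the observed baseline prevalence (34.43%) to which
#' the model threshold is calibrated.
#'
#' @name constants
#' @export
EPDS_CUTOFF <- 10L

#' @rdname constants
#' @export
TARGET_PREVALENCE <- 0.3443

#' Default configuration
#'
#' One nested list holding every tunable of the pipeline: the cohort
#' generator (see [cohort_params()]), the risk-model coefficients (see
#' [coefficient_set()]), the four intervention schedules with their program
#' parameters (minimum wage $8.40 -> $15/h over 10 steps at 40 h/wk,
#' 50 wk/yr; CCB $6,639 phasing out at 7% above $31,120; ACB $1,128
#' phasing out above $26,141; basic-income guarantee $16,989 with 50%
#' clawback), and simulation settings (target prevalence 34.43%, EPDS
#' cutoff 10, significance test, network action parameters).
#'
#' @param seed Master integer seed.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  cp <- unclass(cohort_params())
  cp$seed <- NULL  # the master seed drives per-trial cohort seeds
  list(
    seed = as.integer(seed),
    cohort = cp,
    coefficients = unclass(coefficient_set()),
    interventions = list(
      min_wage = list(wage_start = 8.40, wage_end = 15.00,
                      hours_per_week = 40, weeks_per_year = 50,
                      n_steps = 10L),
      acb = list(benefit_max = 1128, phaseout_start = 26141,
                 phaseout_rate = 0.075),
      ccb = list(benefit_max = 6639, phaseout_start = 31120,
                 phaseout_rate = 0.07),
      ubi = list(ubi_guarantee = 16989, ubi_clawback = 0.5)
    ),
    simulation = list(
      target_prevalence = TARGET_PREVALENCE,
      epds_cutoff = EPDS_CUTOFF,
      test_method = "two_proportion_z",
      p_act = 1.0,
      ties_added_per_act = 1L,
      recompute_da_medians = FALSE
    )
  )
}

# merge user values into the default template; unknown keys are rejected
# and atomic leaves are coerced to the default's type (JSON readers hand
# back lists and doubles)
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config error at '", paste(path, collapse = "."),
         "': expected a section, got a value")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config error: unknown key(s): ",
         paste(paste(c(path, ""), collapse = "."), unknown,
               sep = "", collapse = ", "))
  for (key in names(user)) {
    d <- defaults[[key]]
    u <- user[[key]]
    if (is.list(d) && !is.null(names(d))) {
      defaults[[key]] <- merge_config(d, u, c(path, key))
    } else {
      if (is.list(u)) u <- unlist(u)
      if (is.null(u))
        stop("config error at '", paste(c(path, key), collapse = "."),
             "': null value")
      coerced <- switch(class(d)[1],
                        integer = as.integer(u),
                        numeric = as.numeric(u),
                        logical = as.logical(u),
                        character = as.character(u),
                        u)
      names(coerced) <- names(u)  # base coercions drop names
      if (!is.null(names(d))) {
        if (is.null(names(coerced))) {
          # JSON arrays arrive unnamed; accept positional values
          if (length(coerced) != length(d))
            stop("config error at '", paste(c(path, key), collapse = "."),
                 "': expected ", length(d), " values")
          names(coerced) <- names(d)
        } else {
          if (!setequal(names(d), names(coerced)))
            stop("config error at '", paste(c(path, key), collapse = "."),
                 "': names must be ", paste(names(d), collapse = ", "))
          coerced <- coerced[names(d)]
        }
      }
      defaults[[key]] <- coerced
    }
  }
  defaults
}

#' Validate a configuration
#'
#' Checks bounds and delegates cohort/coefficient validation to their
#' constructors; errors name the offending keys.
#'
#' @param config Configuration list.
#' @return The validated configuration, invisibly usable.
#' @export
validate_config <- function(config) {
  config <- merge_config(default_config(), config)
  sim <- config$simulation
  if (sim$target_prevalence < 0 || sim$target_prevalence > 1)
    stop("config error: simulation.target_prevalence must lie in [0, 1]")
  if (sim$p_act < 0 || sim$p_act > 1)
    stop("config error: simulation.p_act must lie in [0, 1]")
  if (!sim$test_method %in% c("two_proportion_z", "mcnemar"))
    stop("config error: simulation.test_method must be ",
         "'two_proportion_z' or 'mcnemar'")
  if (abs(config$seed) >= 2^31 - 10)
    stop("config error: seed must be a 32-bit integer")
  do.call(cohort_params, c(config$cohort, list(seed = config$seed)))
  do.call(coefficient_set, config$coefficients)
  for (k in names(config$interventions)) {
    kind <- switch(k, min_wage = "min_wage", acb = , ccb = "child_benefit",
                   ubi = "ubi")
    do.call(intervention_schedule,
            c(list(kind = kind), config$interventions[[k]]))
  }
  config
}

#' Load a configuration file
#'
#' Reads a JSON configuration (any subset of the [default_config()] tree),
#' fills in defaults for everything omitted, rejects unknown keys and
#' validates.  An empty file yields the full default configuration.
#'
#' @param path Path to a JSON file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  validate_config(user)
}

#' Write a configuration file
#'
#' @param config Configuration list.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
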