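#' Run one simulation trial
#'
#' A trial (1) computes baseline depression probabilities under the
#' condition's risk model and calibrates the threshold `tau` so that the
#' baseline prevalence matches the target (34.43% by default); (2) iterates
#' steps, each applying the income intervention (recomputed from immutable
#' baseline incomes, so benefits never compound), letting agents act on
#' their networks, and re-thresholding `p >= tau` with `tau` frozen at its
#' baseline value; (3) accounts incident cases (depressed at follow-up but
#' not baseline) and reduced cases (the converse) and tests the prevalence
#' change.
#'
#' The depressed-tie contagion term uses the previous step's depression
#' flags; at baseline, before any depression state exists, it contributes
#' zero.
#'
#' @param agents,das A population, e.g. from [generate_population()].
#' @param coeffs A [coefficient_set()].
#' @param schedule An [intervention_schedule()]; `kind = "none"` is the
#'   null intervention (allowed with any condition, including
#'   income-change conditions, where it yields a no-change control run).
#'   A non-`"none"` schedule with a condition whose `income_change` flag is
#'   off is an error.
#' @param spec A [condition_spec()].
#' @param n_steps Number of steps; defaults to `schedule$n_steps` for
#'   `min_wage` and 1 otherwise (child benefits and the basic-income
#'   top-up are single-shot programs).
#' @param seed Integer seed driving all within-trial randomness.
#' @param target_prevalence Baseline prevalence target.
#' @param test_method Passed to [prevalence_test()].
#' @param recompute_da_medians If `TRUE`, DA median incomes are recomputed
#'   from the agents after each income update (off by default: the
#'   exposure is defined against fixed census medians).
#' @param verbose Emit one `message()` per step (step index, prevalence,
#'   mean income) for CLI logging.
#' @return An object of class `md_trial_result`.
#' @export
run_trial <- function(agents, das, coeffs = coefficient_set(),
                      schedule = intervention_schedule("none"),
                      spec = condition_spec(1),
                      n_steps = NULL, seed = 1L,
                      target_prevalence = 0.3443,
                      test_method = c("two_proportion_z", "mcnemar"),
                      recompute_da_medians = FALSE, verbose = FALSE) {
  stopifnot(inherits(spec, "md_condition"), inherits(schedule, "md_schedule"))
  test_method <- match.arg(test_method)
  if (schedule$kind != "none" && !spec$income_change)
    stop("invalid combination: schedule kind '", schedule$kind,
         "' with a condition that does not change income (condition ",
         spec$condition_id, ")")
  if (is.null(n_steps))
    n_steps <- if (schedule$kind == "min_wage") schedule$n_steps else 1L
  n <- nrow(agents)
  include_network <- spec$remove_depressed_ties || spec$add_ties

  agents$household_income_baseline <- agents$household_income

  lp0 <- linear_predictor(agents, das, coeffs,
                          include_support = spec$include_support_covariate,
                          include_network = include_network,
                          depressed = rep(FALSE, n))
  p0 <- probability(lp0)
  cal <- calibrate_threshold(p0, target_prevalence)
  baseline_flags <- p0 >= cal$tau
  agents$p_depressed <- p0
  agents$depressed <- baseline_flags

  withr::with_seed(seed, {
    for (step in seq_len(n_steps)) {
      if (schedule$kind != "none") {
        agents <- apply_intervention(agents, schedule, step = step)
        if (recompute_da_medians) {
          med <- tapply(agents$household_income, agents$da_id, median)
          das$median_after_tax_income <- as.numeric(
            med[match(das$da_id, names(med))])
        }
      }
      if (include_network)
        agents <- network_step(agents, spec, depressed = agents$depressed)
      lp <- linear_predictor(agents, das, coeffs,
                             include_support = spec$include_support_covariate,
                             include_network = include_network,
                             depressed = agents$depressed)
      agents$p_depressed <- probability(lp)
      agents$depressed <- agents$p_depressed >= cal$tau
      if (verbose)
        message(sprintf("step=%d prevalence=%.4f mean_income=%.0f",
                        step, mean(agents$depressed),
                        mean(agents$household_income)))
    }
  })

  followup_flags <- agents$depressed
  baseline_depressed <- sum(baseline_flags)
  followup_depressed <- sum(followup_flags)
  incident <- sum(followup_flags & !baseline_flags)
  reduced <- sum(baseline_flags & !followup_flags)
  res <- list(
    condition_id = spec$condition_id,
    intervention_kind = schedule$kind,
    n = n,
    baseline_depressed = baseline_depressed,
    followup_depressed = followup_depressed,
    incident_cases = incident,
    reduced_cases = reduced,
    pct_change = pct_change(baseline_depressed, followup_depressed),
    p_value = prevalence_test(baseline_depressed, followup_depressed, n,
                              method = test_method,
                              incident = incident, reduced = reduced),
    seed = seed,
    tau = cal$tau,
    achieved_prevalence = cal$achieved_prevalence,
    n_steps = n_steps,
    baseline_flags = baseline_flags,
    followup_flags = followup_flags
  )
  class(res) <- "md_trial_result"
  validate_trial_counts(res$n, res$baseline_depressed,
                        res$followup_depressed, res$incident_cases,
                        res$reduced_cases)
  res
}

#' Check the baseline/follow-up accounting identity
#'
#' Errors unless `followup = baseline + incident - reduced` and every count
#' lies in `[0, n]`.  Used internally after every trial and exposed so the
#' identity can be checked on externally reported counts.
#'
#' @param n,baseline,followup,incident,reduced Case counts.
#' @return Invisibly `TRUE` when the accounting is consistent.
#' @export
#' @examples
#' validate_trial_counts(17863, 6150, 4744, 24, 1430)
validate_trial_counts <- function(n, baseline, followup, incident, reduced) {
  counts <- c(baseline, followup, incident, reduced)
  if (any(counts < 0) || any(c(baseline, followup) > n))
    stop("counts out of range [0, n]")
  if (followup != baseline + incident - reduced)
    stop("accounting identity violated: ", baseline, " + ", incident,
         " - ", reduced, " != ", followup)
  invisible(TRUE)
}

#' @export
print.md_trial_result <- function(x, ...) {
  cat(sprintf(
    "Trial (condition %d, %s): n = %d\n  baseline %d (%.2f%%) -> follow-up %d | incident %d, reduced %d\n  %% change %.2f, p = %.4g\n",
    x$condition_id, x$intervention_kind, x$n,
    x$baseline_depressed, 100 * x$baseline_depressed / x$n,
    x$followup_depressed, x$incident_cases, x$reduced_cases,
    x$pct_change, x$p_value))
  invisible(x)
}

# per-trial seed stream derived from the master seed; kept below 2^31
trial_seed <- function(master, i) {
  as.integer((as.numeric(master) * 10007 + i * 257) %% 2147483647)
}

#' Run the full simulation suite
#'
#' Reproduces the study design: four intervention trials under the
#' income-only condition (minimum wage, Alberta child benefit, Canada
#' child benefit, basic-income top-up) followed by the eight
#' network-condition trials (minimum wage wherever the condition changes
#' income, no intervention otherwise).  Each trial regenerates its own
#' population from a seed stream derived from the master seed, so trials
#' are independent yet the whole suite is reproducible.
#'
#' @param config A configuration list from [default_config()] /
#'   [load_config()].
#' @return A list of 12 [run_trial()] results, class `md_suite`;
#'   `as.data.frame()` renders it as a results table.
#' @export
run_suite <- function(config = default_config()) {
  config <- validate_config(config)
  seed <- config$seed
  sim <- config$simulation
  coeffs <- do.call(coefficient_set, config$coefficients)
  schedules <- list(
    min_wage = do.call(intervention_schedule,
                       c(list(kind = "min_wage"), config$interventions$min_wage)),
    acb = do.call(intervention_schedule,
                  c(list(kind = "child_benefit"), config$interventions$acb)),
    ccb = do.call(intervention_schedule,
                  c(list(kind = "child_benefit"), config$interventions$ccb)),
    ubi = do.call(intervention_schedule,
                  c(list(kind = "ubi"), config$interventions$ubi))
  )
  none <- intervention_schedule("none")

  plan <- c(
    lapply(c("min_wage", "acb", "ccb", "ubi"), function(k)
      list(spec = condition_spec(1), schedule = schedules[[k]], label = k)),
    lapply(1:8, function(cid) {
      spec <- condition_spec(cid, p_act = sim$p_act,
                             ties_added_per_act = sim$ties_added_per_act)
      list(spec = spec,
           schedule = if (spec$income_change) schedules$min_wage else none,
           label = paste0("condition_", cid))
    })
  )

  results <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    s <- trial_seed(seed, i)
    params <- do.call(cohort_params, c(config$cohort, list(seed = s)))
    pop <- generate_population(params)
    message(sprintf("trial %2d [%s]: n = %d, seed = %d",
                    i, plan[[i]]$label, nrow(pop$agents), s))
    results[[i]] <- run_trial(
      pop$agents, pop$das, coeffs,
      schedule = plan[[i]]$schedule, spec = plan[[i]]$spec,
      seed = s + 1L,
      target_prevalence = sim$target_prevalence,
      test_method = sim$test_method,
      recompute_da_medians = sim$recompute_da_medians
    )
    results[[i]]$label <- plan[[i]]$label
  }
  structure(results, class = "md_suite", seed = seed)
}

#' @export
as.data.frame.md_suite <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(
      label = r$label, condition_id = r$condition_id,
      intervention = r$intervention_kind, n = r$n,
      baseline_depressed = r$baseline_depressed,
      baseline_pct = round(100 * r$baseline_depressed / r$n, 2),
      followup_depressed = r$followup_depressed,
      followup_pct = round(100 * r$followup_depressed / r$n, 2),
      incident_cases = r$incident_cases, reduced_cases = r$reduced_cases,
      pct_change = r$pct_change, p_value = r$p_value, seed = r$seed
    )
  }))
}

#' @export
print.md_suite <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Simulation suite (master seed", attr(x, "seed"), "):\n")
  print(df, row.names = FALSE)
  invisible(x)
}
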