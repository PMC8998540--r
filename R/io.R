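#' Write and read cohort tables
#'
#' Plain-CSV persistence for the agent and DA tables, so a generated
#' population can be inspected or an external cohort substituted for the
#' generator.  The agent schema is one row per agent with columns
#' `agent_id, da_id, age, education, born_in_canada, white, income_band,
#' income_before_tax, household_income, gov_support,
#' prenatal_care_access, safety, crime, social_support_present, ties,
#' depressed, p_depressed`, where `ties` holds semicolon-separated agent
#' ids (empty string for none).  `read_cohort()` accepts exactly this
#' schema and reconstructs types, so write -> read is an identity.
#'
#' @param agents Agent data frame.
#' @param path CSV path.
#' @return `path` (writers, invisibly) or the reconstructed data frame
#'   (readers).
#' @export
write_cohort <- function(agents, path) {
  out <- agents
  out$ties <- vapply(agents$ties, paste, character(1), collapse = ";")
  out$education <- as.character(out$education)
  write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("agent_id", "da_id", "age", "education", "household_income",
              "ties")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  df$education <- factor(df$education,
                         levels = c("high_school_or_less",
                                    "some_or_completed_postsecondary",
                                    "some_or_completed_graduate"))
  df$ties <- lapply(strsplit(as.character(df$ties), ";", fixed = TRUE),
                    function(x) as.integer(x[nzchar(x)]))
  df$social_support_present <- lengths(df$ties) >= 1L
  class(df) <- c("md_agents", "data.frame")
  df
}

#' @rdname write_cohort
#' @param das DA data frame.
#' @export
write_das <- function(das, path) {
  write.csv(as.data.frame(das), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_das <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("da_id", "median_after_tax_income", "pct_lico",
              "pct_shelter_over_30", "pct_recent_immigrants")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("DA file lacks column(s): ", paste(missing, collapse = ", "))
  class(df) <- c("md_das", "data.frame")
  df
}

#' Write suite results
#'
#' CSV in the published results-table column order (n, baseline and
#' follow-up counts and percentages, incident and reduced cases, % change
#' to two decimals, p-value), or JSON carrying every `md_trial_result`
#' field including the seed.
#'
#' @param results An `md_suite` (or list of `md_trial_result`).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (length(results) == 0L) stop("'results' must be nonempty")
  if (!inherits(results, "md_suite")) class(results) <- "md_suite"
  if (format == "csv") {
    df <- as.data.frame(results)
    df$pct_change <- sprintf("%.2f", df$pct_change)
    df$baseline_pct <- sprintf("%.2f", df$baseline_pct)
    df$followup_pct <- sprintf("%.2f", df$followup_pct)
    write.csv(df, path, row.names = FALSE)
  } else {
    rows <- lapply(results, function(r) {
      r$baseline_flags <- NULL  # per-agent vectors stay in memory only
      r$followup_flags <- NULL
      unclass(r)
    })
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") read.csv(path, stringsAsFactors = FALSE)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Tabulate benefit curves over an income grid
#'
#' Renders each schedule's income gain over a grid of baseline incomes;
#' handy for eyeballing phase-outs.
#'
#' @param schedules Named list of [intervention_schedule()] objects.
#' @param incomes Income grid (CAD/yr).
#' @return Data frame with one row per (schedule, income).
#' @export
benefit_curves <- function(schedules, incomes = seq(0, 120000, by = 5000)) {
  do.call(rbind, lapply(names(schedules), function(nm) {
    s <- schedules[[nm]]
    gain <- switch(s$kind,
                   none = rep(0, length(incomes)),
                   min_wage = wage_floor_income(
                     incomes, wage_at_step(s, s$n_steps), s) - incomes,
                   child_benefit = child_benefit(incomes, s),
                   ubi = ubi_topup(incomes, s))
    data.frame(schedule = nm, kind = s$kind, income = incomes, gain = gain,
               new_income = incomes + gain)
  }))
}
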