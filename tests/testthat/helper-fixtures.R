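# Small populations used across test files.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

small_params <- function(seed = 101L, n_agents = 800L, n_das = 8L, ...) {
  cohort_params(n_agents = n_agents, n_das = n_das, seed = seed, ...)
}

small_pop <- function(seed = 101L, n_agents = 800L, n_das = 8L, ...) {
  generate_population(small_params(seed = seed, n_agents = n_agents,
                                   n_das = n_das, ...))
}

# one hand-buildable agent row compatible with linear_predictor()
one_agent <- function(da_id = 1L, household_income = 45000,
                      ties = list(integer(0)), depressed = NA) {
  df <- data.frame(
    agent_id = 1L, da_id = da_id, age = 30,
    education = factor("high_school_or_less",
                       levels = c("high_school_or_less",
                                  "some_or_completed_postsecondary",
                                  "some_or_completed_graduate")),
    born_in_canada = TRUE, white = TRUE,
    household_income = household_income,
    gov_support = FALSE, prenatal_care_access = TRUE,
    safety = 0.8, crime = 0.2, social_support_present = FALSE
  )
  df$ties <- ties
  df$depressed <- depressed
  df
}

one_da <- function(da_id = 1L, median_after_tax_income = 62500) {
  data.frame(da_id = da_id,
             median_after_tax_income = median_after_tax_income,
             pct_lico = 0.1, pct_shelter_over_30 = 0.25,
             pct_recent_immigrants = 0.1)
}

# coefficient set with everything zeroed except chosen entries
zero_coeffs <- function(...) {
  overrides <- list(...)
  base <- lapply(coefficient_set(), function(x) 0)
  base[names(overrides)] <- overrides
  do.call(coefficient_set, base)
}

expect_symmetric_ties <- function(ties) {
  for (i in seq_along(ties)) {
    expect_false(i %in% ties[[i]], label = paste("self-tie at", i))
    for (j in ties[[i]])
      expect_true(i %in% ties[[j]],
                  label = paste("asymmetric tie", i, "->", j))
  }
  invisible(TRUE)
}
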