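#' Cohort generator parameters
#'
#' Bundles every knob of the synthetic-population generator.  Defaults
#' reproduce the published baseline marginals of the source cohort of 3,387
#' expectant mothers (age mean 30.60, SD 4.55, range 18-47; education
#' 10.94/73.29/15.77%; born in Canada 78.26%; white 78.64%; before-tax
#' income bands 9.17/22.06/68.77%; government income support 5.38%) and the
#' simulated population of 17,865 agents spread over 183 dissemination
#' areas.
#'
#' Income is sampled in two stages: a categorical band (before-tax), then a
#' truncated lognormal within the band.  After-tax household income, the
#' quantity entering relative income, is a flat fraction
#' (`after_tax_factor`) of the before-tax draw because no published
#' conversion exists.  DA covariates and the agent safety/crime scores are
#' unpublished; they default to lognormal/Beta distributions with plausible
#' urban-Canadian central values and are fully configurable.
#'
#' @param n_mothers Size of the original survey sample; only used by
#'   generator-validation checks.
#' @param n_agents Number of simulated agents.
#' @param n_das Number of dissemination areas.
#' @param age_mean,age_sd,age_min,age_max Truncated-normal age model (years).
#' @param p_education Named probabilities for the three education levels
#'   (must sum to 1).
#' @param p_born_in_canada,p_white,p_gov_support,p_prenatal_care Bernoulli
#'   probabilities for the binary attributes.
#' @param p_income_band Probabilities of the three before-tax income bands
#'   `<40k`, `40-80k`, `>=80k` (must sum to 1).
#' @param income_band_breaks Band boundaries in CAD/yr (length 4,
#'   increasing, last may be `Inf`).
#' @param income_band_meanlog,income_band_sdlog Lognormal parameters per
#'   band, truncated to the band.
#' @param after_tax_factor Flat before-tax to after-tax conversion.
#' @param safety_shape,crime_shape Beta shape pairs for the two
#'   neighbourhood-perception scores in \[0,1\].
#' @param da_income_meanlog,da_income_sdlog Lognormal model of the DA
#'   median after-tax household income (CAD/yr).
#' @param da_lico_shape,da_shelter_shape,da_recent_imm_shape Beta shape
#'   pairs for the three DA census fractions.
#' @param mean_degree Target mean number of within-DA social ties per agent
#'   (Erdos-Renyi style; 0 disables networks).
#' @param seed Integer seed; every generator draw is a deterministic
#'   function of it.
#' @return An object of class `md_cohort_params` (a validated list).
#' @export
#' @examples
#' p <- cohort_params(n_agents = 500, n_das = 5, seed = 42)
#' das <- generate_das(p)
#' agents <- assign_networks(generate_cohort(das, p), p)
cohort_params <- function(n_mothers = 3387L,
                          n_agents = 17865L,
                          n_das = 183L,
                          age_mean = 30.60, age_sd = 4.55,
                          age_min = 18, age_max = 47,
                          p_education = c(high_school_or_less = 0.1094,
                                          some_or_completed_postsecondary = 0.7329,
                                          some_or_completed_graduate = 0.1577),
                          p_born_in_canada = 0.7826,
                          p_white = 0.7864,
                          p_income_band = c(low = 0.0917, mid = 0.2206,
                                            high = 0.6877),
                          p_gov_support = 0.0538,
                          p_prenatal_care = 0.90,
                          income_band_breaks = c(0, 40000, 80000, Inf),
                          income_band_meanlog = log(c(30000, 60000, 105000)),
                          income_band_sdlog = c(0.5, 0.3, 0.4),
                          after_tax_factor = 0.80,
                          safety_shape = c(8, 2),
                          crime_shape = c(2, 8),
                          da_income_meanlog = log(65000),
                          da_income_sdlog = 0.3,
                          da_lico_shape = c(2, 18),
                          da_shelter_shape = c(2.5, 7.5),
                          da_recent_imm_shape = c(2, 18),
                          mean_degree = 3,
                          seed = 1L) {
  params <- list(
    n_mothers = as.integer(n_mothers), n_agents = as.integer(n_agents),
    n_das = as.integer(n_das),
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    p_education = p_education, p_born_in_canada = p_born_in_canada,
    p_white = p_white, p_income_band = p_income_band,
    p_gov_support = p_gov_support, p_prenatal_care = p_prenatal_care,
    income_band_breaks = income_band_breaks,
    income_band_meanlog = income_band_meanlog,
    income_band_sdlog = income_band_sdlog,
    after_tax_factor = after_tax_factor,
    safety_shape = safety_shape, crime_shape = crime_shape,
    da_income_meanlog = da_income_meanlog, da_income_sdlog = da_income_sdlog,
    da_lico_shape = da_lico_shape, da_shelter_shape = da_shelter_shape,
    da_recent_imm_shape = da_recent_imm_shape,
    mean_degree = mean_degree, seed = as.integer(seed)
  )
  class(params) <- "md_cohort_params"
  validate_cohort_params(params)
}

validate_cohort_params <- function(p) {
  stopifnot(inherits(p, "md_cohort_params"))
  if (p$n_das <= 0L) stop("configuration error: n_das must be positive")
  if (p$n_agents < p$n_das)
    stop("configuration error: n_agents must be >= n_das")
  for (nm in c("p_education", "p_income_band")) {
    if (abs(sum(p[[nm]]) - 1) > 1e-9)
      stop("configuration error: ", nm, " must sum to 1 (within 1e-9)")
    if (any(p[[nm]] < 0)) stop("configuration error: ", nm, " has negatives")
  }
  for (nm in c("p_born_in_canada", "p_white", "p_gov_support",
               "p_prenatal_care", "after_tax_factor")) {
    v <- p[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("configuration error: ", nm, " must lie in [0, 1]")
  }
  stopifnot(p$age_min < p$age_max, p$age_sd > 0,
            length(p$income_band_breaks) == length(p$p_income_band) + 1L,
            !is.unsorted(p$income_band_breaks),
            p$mean_degree >= 0,
            abs(p$seed) < 2^31 - 10)
  p
}

#' Generate dissemination areas
#'
#' Draws `n_das` neighbourhoods, each with a median after-tax household
#' income (lognormal) and three census covariates in \[0,1\] (Beta): the
#' fraction of families below the low-income cut-off (LICO), the fraction
#' spending over 30% of income on shelter, and the fraction of recent
#' immigrants.
#'
#' @param params A [cohort_params()] object.
#' @return A data frame of class `md_das` with one row per DA and columns
#'   `da_id`, `median_after_tax_income`, `pct_lico`,
#'   `pct_shelter_over_30`, `pct_recent_immigrants`.
#' @export
generate_das <- function(params) {
  params <- validate_cohort_params(params)
  n <- params$n_das
  das <- withr::with_seed(params$seed, {
    data.frame(
      da_id = seq_len(n),
      median_after_tax_income = rlnorm(n, params$da_income_meanlog,
                                       params$da_income_sdlog),
      pct_lico = rbeta(n, params$da_lico_shape[1], params$da_lico_shape[2]),
      pct_shelter_over_30 = rbeta(n, params$da_shelter_shape[1],
                                  params$da_shelter_shape[2]),
      pct_recent_immigrants = rbeta(n, params$da_recent_imm_shape[1],
                                    params$da_recent_imm_shape[2])
    )
  })
  class(das) <- c("md_das", "data.frame")
  das
}

# inverse-CDF draw from lognormal truncated to [lo, hi)
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(plo + runif(n) * (phi - plo), meanlog, sdlog)
}

# inverse-CDF draw from normal truncated to [lo, hi]
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate the agent cohort
#'
#' Draws `n_agents` expectant mothers with attributes sampled independently
#' from the configured marginal distributions, assigned uniformly at random
#' to the supplied DAs.  Incomes are drawn as a before-tax band plus a
#' truncated lognormal within the band; `household_income` is the after-tax
#' conversion used throughout the simulation.  Depression state is left
#' unset: it is assigned later by prevalence calibration (see
#' [calibrate_threshold()]).
#'
#' @param das Data frame from [generate_das()].
#' @param params A [cohort_params()] object.
#' @return A data frame of class `md_agents`, one row per agent, with a
#'   `ties` list-column (empty until [assign_networks()] is called).
#' @export
generate_cohort <- function(das, params) {
  params <- validate_cohort_params(params)
  if (is.null(das) || nrow(das) == 0L) stop("'das' must be a nonempty DA table")
  n <- params$n_agents
  agents <- withr::with_seed(params$seed + 1L, {
    band <- sample.int(length(params$p_income_band), n, replace = TRUE,
                       prob = params$p_income_band)
    income_before_tax <- numeric(n)
    for (b in seq_along(params$p_income_band)) {
      idx <- which(band == b)
      income_before_tax[idx] <- rlnorm_trunc(
        length(idx),
        params$income_band_meanlog[b], params$income_band_sdlog[b],
        params$income_band_breaks[b], params$income_band_breaks[b + 1L]
      )
    }
    edu_levels <- names(params$p_education)
    data.frame(
      agent_id = seq_len(n),
      da_id = sample(das$da_id, n, replace = TRUE),
      age = rnorm_trunc(n, params$age_mean, params$age_sd,
                        params$age_min, params$age_max),
      education = factor(
        edu_levels[sample.int(length(edu_levels), n, replace = TRUE,
                              prob = params$p_education)],
        levels = edu_levels
      ),
      born_in_canada = runif(n) < params$p_born_in_canada,
      white = runif(n) < params$p_white,
      income_band = band,
      income_before_tax = income_before_tax,
      household_income = income_before_tax * params$after_tax_factor,
      gov_support = runif(n) < params$p_gov_support,
      prenatal_care_access = runif(n) < params$p_prenatal_care,
      safety = rbeta(n, params$safety_shape[1], params$safety_shape[2]),
      crime = rbeta(n, params$crime_shape[1], params$crime_shape[2])
    )
  })
  agents$social_support_present <- FALSE
  agents$ties <- rep(list(integer(0)), n)
  agents$depressed <- NA
  agents$p_depressed <- NA_real_
  class(agents) <- c("md_agents", "data.frame")
  agents
}

#' Assign baseline social networks
#'
#' Draws within-DA random ties (Erdos-Renyi style) with configured mean
#' degree.  Ties are symmetric by construction and never connect agents in
#' different DAs.  `social_support_present` is then defined as having at
#' least one tie, mirroring the single survey item ("how many close friends
#' and/or close relatives do you have").
#'
#' @param agents Data frame from [generate_cohort()].
#' @param params A [cohort_params()] object.
#' @return `agents` with the `ties` list-column and
#'   `social_support_present` filled in.
#' @export
assign_networks <- function(agents, params) {
  params <- validate_cohort_params(params)
  n <- nrow(agents)
  ties <- rep(list(integer(0)), n)
  if (params$mean_degree > 0) {
    ties <- withr::with_seed(params$seed + 2L, {
      for (members in split(seq_len(n), agents$da_id)) {
        m <- length(members)
        if (m < 2L) next
        p_edge <- min(1, params$mean_degree / (m - 1))
        npairs <- m * (m - 1) / 2
        n_edges <- rbinom(1L, npairs, p_edge)
        if (n_edges == 0L) next
        pick <- sample.int(npairs, n_edges)
        # map linear pair index k (1-based, column-major over i<j) to (i,j)
        j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
        i <- pick - (j - 1) * (j - 2) / 2
        a <- members[i]; b <- members[j]
        for (e in seq_along(a)) {
          ties[[a[e]]] <- c(ties[[a[e]]], b[e])
          ties[[b[e]]] <- c(ties[[b[e]]], a[e])
        }
      }
      lapply(ties, sort)
    })
  }
  agents$ties <- ties
  agents$social_support_present <- lengths(ties) >= 1L
  agents
}

#' Generate a complete population
#'
#' Convenience wrapper: DAs, agents and networks in one call.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `md_population` with elements `agents` and `das`.
#' @export
generate_population <- function(params = cohort_params()) {
  das <- generate_das(params)
  agents <- assign_networks(generate_cohort(das, params), params)
  structure(list(agents = agents, das = das), class = "md_population")
}

#' @export
print.md_population <- function(x, ...) {
  cat("Synthetic population:", nrow(x$agents), "agents in",
      nrow(x$das), "dissemination areas\n")
  cat("  mean age:", round(mean(x$agents$age), 2),
      "| % white:", round(100 * mean(x$agents$white), 2),
      "| mean after-tax income:",
      round(mean(x$agents$household_income)), "CAD\n")
  cat("  mean degree:", round(mean(lengths(x$agents$ties)), 2),
      "| % with social support:",
      round(100 * mean(x$agents$social_support_present), 2), "\n")
  invisible(x)
}
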