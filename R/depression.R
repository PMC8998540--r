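#' Logistic risk-model coefficients
#'
#' The depression logit is
#' `intercept + beta_relative_income * (household_income - DA median) + ...`
#' over the individual covariates (education contrasts against
#' high-school-or-less, age, ethnicity, nativity, government support,
#' prenatal-care access, perceived safety and crime), the DA census
#' covariates, an optional social-support indicator, and two network terms:
#' a protective per-tie effect (`beta_network_size`, negative) and a
#' contagion-like per-depressed-tie effect (`beta_depressed_ties`, positive
#' and smaller in magnitude, so that dropping a depressed tie raises risk
#' on net).
#'
#' The original model was fitted on restricted cohort data and its
#' coefficients were never published; these defaults carry the signs the
#' epidemiological literature supports, with magnitudes chosen so the
#' default synthetic population lands near the observed 34% prevalence
#' before threshold calibration.  The calibration threshold, not the
#' intercept, absorbs any residual miscalibration.
#'
#' @param intercept Logit-scale intercept.
#' @param beta_relative_income Logit per CAD of relative income (negative:
#'   earning less than the neighbourhood median raises risk).
#' @param beta_edu_postsecondary,beta_edu_graduate Education contrasts
#'   vs. high-school-or-less.
#' @param beta_age Logit per year of age.
#' @param beta_white,beta_born_in_canada,beta_gov_support,
#'   beta_prenatal_care_access Binary-covariate effects.
#' @param beta_safety,beta_crime Effects of the two \[0,1\] perception scores.
#' @param beta_social_support_present Effect of having at least one tie;
#'   only entered under conditions that include the support covariate.
#' @param beta_pct_lico,beta_pct_shelter_over_30,beta_pct_recent_immigrants
#'   DA census-covariate effects.
#' @param beta_da_median_income Optional direct effect of the DA median
#'   income (logit per CAD); 0 by default so that income enters only
#'   through relative income.
#' @param beta_network_size Logit per social tie (expected negative).
#' @param beta_depressed_ties Logit per currently depressed tie (expected
#'   positive, `|beta_depressed_ties| < |beta_network_size|`).
#' @return An object of class `md_coefficients`.
#' @export
coefficient_set <- function(intercept = 0.7,
                            beta_relative_income = -1e-5,
                            beta_edu_postsecondary = -0.3,
                            beta_edu_graduate = -0.5,
                            beta_age = -0.02,
                            beta_white = -0.2,
                            beta_born_in_canada = 0.05,
                            beta_gov_support = 0.3,
                            beta_prenatal_care_access = -0.3,
                            beta_safety = -0.4,
                            beta_crime = 0.4,
                            beta_social_support_present = -0.4,
                            beta_pct_lico = 0.8,
                            beta_pct_shelter_over_30 = 0.5,
                            beta_pct_recent_immigrants = 0.3,
                            beta_da_median_income = 0,
                            beta_network_size = -0.3,
                            beta_depressed_ties = 0.1) {
  coeffs <- mget(names(formals(coefficient_set)))
  coeffs <- lapply(coeffs, as.numeric)
  if (!all(vapply(coeffs, is.finite, logical(1))))
    stop("all coefficients must be finite")
  structure(coeffs, class = "md_coefficients")
}

# design columns shared by linear_predictor() and fit_logistic(); order is
# the contract between the two
model_covariates <- c(
  "relative_income", "edu_postsecondary", "edu_graduate", "age", "white",
  "born_in_canada", "gov_support", "prenatal_care_access", "safety",
  "crime", "pct_lico", "pct_shelter_over_30", "pct_recent_immigrants",
  "da_median_income"
)

required_agent_fields <- c(
  "da_id", "age", "education", "white", "born_in_canada", "gov_support",
  "prenatal_care_access", "safety", "crime", "household_income",
  "social_support_present"
)

#' Relative income
#'
#' The primary exposure: an agent's after-tax household income minus the
#' median after-tax household income of her dissemination area.  The sign
#' is preserved (a below-median household has negative relative income).
#'
#' @param agents Agent data frame (needs `da_id`, `household_income`).
#' @param das DA data frame; every `agents$da_id` must appear in it.
#' @return Numeric vector, CAD per year.
#' @export
#' @examples
#' das <- data.frame(da_id = 1, median_after_tax_income = 62500,
#'                   pct_lico = .1, pct_shelter_over_30 = .2,
#'                   pct_recent_immigrants = .1)
#' relative_income(data.frame(da_id = 1, household_income = 45000), das)
relative_income <- function(agents, das) {
  pos <- match(agents$da_id, das$da_id)
  if (anyNA(pos))
    stop("DA mismatch: agents reference da_id values absent from 'das'")
  agents$household_income - das$median_after_tax_income[pos]
}

# depressed-tie count per agent given the current depressed flags
count_depressed_ties <- function(ties, depressed) {
  vapply(ties, function(t) sum(depressed[t]), numeric(1))
}

#' Linear predictor of the depression model
#'
#' Computes the logit for every agent: intercept plus coefficient-weighted
#' covariates, with relative income as the income term.  The social-support
#' indicator enters only when `include_support = TRUE` (experimental
#' condition 2) and the two network terms only when
#' `include_network = TRUE` (conditions with network dynamics).  The
#' depressed-tie term uses the `depressed` flags passed in; before any
#' depression state exists (baseline calibration) it contributes zero.
#'
#' @param agents Agent data frame.
#' @param das DA data frame.
#' @param coeffs A [coefficient_set()].
#' @param include_support Include `beta_social_support_present`?
#' @param include_network Include network size/contagion terms?
#' @param depressed Logical vector of current depression flags used for the
#'   depressed-tie count; defaults to all-`FALSE`.
#' @return Numeric vector of logits.
#' @export
linear_predictor <- function(agents, das, coeffs,
                             include_support = FALSE,
                             include_network = FALSE,
                             depressed = NULL) {
  stopifnot(inherits(coeffs, "md_coefficients"))
  missing_fields <- setdiff(required_agent_fields, names(agents))
  if (length(missing_fields))
    stop("missing covariate: ", paste(missing_fields, collapse = ", "))
  if (anyNA(agents[required_agent_fields]))
    stop("missing covariate values (NA) in: ",
         paste(required_agent_fields[
           vapply(agents[required_agent_fields], anyNA, logical(1))],
           collapse = ", "))
  pos <- match(agents$da_id, das$da_id)
  if (anyNA(pos)) stop("DA mismatch: unknown da_id in agents")

  lp <- coeffs$intercept +
    coeffs$beta_relative_income * relative_income(agents, das) +
    coeffs$beta_edu_postsecondary *
      (agents$education == "some_or_completed_postsecondary") +
    coeffs$beta_edu_graduate *
      (agents$education == "some_or_completed_graduate") +
    coeffs$beta_age * agents$age +
    coeffs$beta_white * agents$white +
    coeffs$beta_born_in_canada * agents$born_in_canada +
    coeffs$beta_gov_support * agents$gov_support +
    coeffs$beta_prenatal_care_access * agents$prenatal_care_access +
    coeffs$beta_safety * agents$safety +
    coeffs$beta_crime * agents$crime +
    coeffs$beta_pct_lico * das$pct_lico[pos] +
    coeffs$beta_pct_shelter_over_30 * das$pct_shelter_over_30[pos] +
    coeffs$beta_pct_recent_immigrants * das$pct_recent_immigrants[pos] +
    coeffs$beta_da_median_income * das$median_after_tax_income[pos]
  if (include_support)
    lp <- lp + coeffs$beta_social_support_present * agents$social_support_present
  if (include_network) {
    if (is.null(depressed)) depressed <- rep(FALSE, nrow(agents))
    lp <- lp + coeffs$beta_network_size * lengths(agents$ties) +
      coeffs$beta_depressed_ties * count_depressed_ties(agents$ties, depressed)
  }
  lp
}

#' Inverse logit
#'
#' @param logit Numeric vector of logits (finite).
#' @return `1 / (1 + exp(-logit))`.
#' @export
probability <- function(logit) {
  stopifnot(all(is.finite(logit)))
  1 / (1 + exp(-logit))
}

#' Calibrate the depression threshold
#'
#' Chooses the probability cut-point `tau` such that the share of agents
#' with `p >= tau` is the closest achievable to the target prevalence (the
#' observed 34.43% under the default configuration), breaking ties toward
#' at-or-above the target.  Depression state is then the deterministic
#' thresholding `p >= tau` -- no Bernoulli sampling.
#'
#' @param probs Nonempty numeric vector of depression probabilities.
#' @param target Target prevalence in \[0,1\].
#' @return A list of class `md_calibration` with `tau`,
#'   `achieved_prevalence` and `target_prevalence`.
#' @export
#' @examples
#' calibrate_threshold(c(0.1, 0.2, 0.3, 0.4), target = 0.5)
calibrate_threshold <- function(probs, target = 0.3443) {
  if (length(probs) == 0L) stop("'probs' must be nonempty")
  stopifnot(target >= 0, target <= 1, all(probs >= 0), all(probs <= 1))
  n <- length(probs)
  k <- floor(n * target)
  # pick k or k+1, whichever share is closer; ties toward >= target
  if (k < n && (n * target - k) >= 0.5) k <- k + 1L
  sorted <- sort(probs, decreasing = TRUE)
  if (k == 0L) {
    # closest achievable share is 0: place tau just above the largest prob
    # (capped at 1, so a degenerate all-ones input keeps tau in [0,1])
    tau <- min(1, max(probs) * (1 + 1e-12) + 1e-300)
  } else {
    tau <- sorted[k]
  }
  achieved <- mean(probs >= tau)
  structure(list(tau = tau, achieved_prevalence = achieved,
                 target_prevalence = target),
            class = "md_calibration")
}

#' @export
print.md_calibration <- function(x, ...) {
  cat(sprintf("Calibration: tau = %.6f, achieved prevalence %.2f%% (target %.2f%%)\n",
              x$tau, 100 * x$achieved_prevalence, 100 * x$target_prevalence))
  invisible(x)
}

#' Fit the logistic model by maximum likelihood
#'
#' Fits depression outcomes on the full covariate set (relative income,
#' individual and DA covariates, social support).  Used for
#' parameter-recovery validation and for the optional path where a real
#' cohort table is supplied; the simulation itself uses a fixed
#' [coefficient_set()].
#'
#' @param agents Agent data frame.
#' @param outcomes Logical/0-1 vector of depression outcomes.
#' @param das DA data frame.
#' @param include_support Include the social-support indicator.
#' @param penalize Apply a mild ridge penalty (via data augmentation) as a
#'   remedy for perfect separation.
#' @return A list of class `md_fit` with a `coefficients`
#'   [coefficient_set()] (network betas zero: not identifiable from a
#'   cross-section), the underlying `glm` object, and `ci`, a matrix of
#'   Wald 95% confidence intervals.
#' @export
fit_logistic <- function(agents, outcomes, das, include_support = TRUE,
                         penalize = FALSE) {
  outcomes <- as.logical(outcomes)
  if (length(unique(outcomes)) < 2L)
    stop("degenerate outcomes: both classes must be present")
  df <- data.frame(
    y = outcomes,
    relative_income = relative_income(agents, das),
    edu_postsecondary =
      as.numeric(agents$education == "some_or_completed_postsecondary"),
    edu_graduate =
      as.numeric(agents$education == "some_or_completed_graduate"),
    age = agents$age,
    white = as.numeric(agents$white),
    born_in_canada = as.numeric(agents$born_in_canada),
    gov_support = as.numeric(agents$gov_support),
    prenatal_care_access = as.numeric(agents$prenatal_care_access),
    safety = agents$safety,
    crime = agents$crime,
    pct_lico = das$pct_lico[match(agents$da_id, das$da_id)],
    pct_shelter_over_30 =
      das$pct_shelter_over_30[match(agents$da_id, das$da_id)],
    pct_recent_immigrants =
      das$pct_recent_immigrants[match(agents$da_id, das$da_id)]
  )
  if (include_support)
    df$social_support_present <- as.numeric(agents$social_support_present)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  if (separated && !penalize)
    stop("perfect (or quasi-perfect) separation detected; ",
         "refit with penalize = TRUE for a ridge-stabilised fit")
  if (separated && penalize) {
    # tiny ridge by prior pseudo-observations on standardised covariates
    xs <- scale(as.matrix(df[-1]))
    aug_x <- rbind(xs, diag(ncol(xs)) * 2, -diag(ncol(xs)) * 2)
    aug_y <- c(df$y, rep(c(TRUE, FALSE), each = ncol(xs)))
    aug_w <- c(rep(1, nrow(xs)), rep(0.5, 2 * ncol(xs)))
    adf <- data.frame(y = aug_y, aug_x)
    fit <- suppressWarnings(glm(y ~ ., data = adf, family = binomial(),
                                weights = aug_w))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  cs <- coefficient_set(
    intercept = est[["(Intercept)"]],
    beta_relative_income = est[["relative_income"]],
    beta_edu_postsecondary = est[["edu_postsecondary"]],
    beta_edu_graduate = est[["edu_graduate"]],
    beta_age = est[["age"]],
    beta_white = est[["white"]],
    beta_born_in_canada = est[["born_in_canada"]],
    beta_gov_support = est[["gov_support"]],
    beta_prenatal_care_access = est[["prenatal_care_access"]],
    beta_safety = est[["safety"]],
    beta_crime = est[["crime"]],
    beta_social_support_present =
      if (include_support) est[["social_support_present"]] else 0,
    beta_pct_lico = est[["pct_lico"]],
    beta_pct_shelter_over_30 = est[["pct_shelter_over_30"]],
    beta_pct_recent_immigrants = est[["pct_recent_immigrants"]],
    beta_da_median_income = 0,
    beta_network_size = 0, beta_depressed_ties = 0
  )
  structure(list(coefficients = cs, glm = fit, ci = ci), class = "md_fit")
}
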