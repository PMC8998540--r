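test_that("relative_income is signed arithmetic against the DA median", {
  da <- one_da(median_after_tax_income = 62500)
  expect_equal(relative_income(one_agent(household_income = 62500), da), 0)
  expect_equal(relative_income(one_agent(household_income = 45000), da),
               -17500)
  expect_equal(relative_income(one_agent(household_income = 100000), da),
               37500)
  expect_error(relative_income(one_agent(da_id = 9L), da), "DA mismatch")
})

test_that("linear_predictor arithmetic matches hand-built cases", {
  da <- one_da()
  expect_equal(linear_predictor(one_agent(), da, zero_coeffs()), 0)

  co <- zero_coeffs(beta_relative_income = -1e-5)
  expect_equal(
    linear_predictor(one_agent(household_income = 45000), da, co),
    0.175)

  # one extra non-depressed tie moves the logit by exactly its coefficient
  co2 <- zero_coeffs(beta_network_size = -0.2)
  a0 <- one_agent(ties = list(integer(0)))
  a1 <- one_agent(ties = list(2L))
  dep <- c(FALSE, FALSE)
  expect_equal(
    linear_predictor(a1, da, co2, include_network = TRUE, depressed = dep) -
      linear_predictor(a0, da, co2, include_network = TRUE, depressed = dep),
    -0.2)

  bad <- one_agent(); bad$age <- NULL
  expect_error(linear_predictor(bad, da, co), "age")
})

test_that("linear_predictor equals a brute-force dot product", {
  pop <- small_pop(seed = 41, n_agents = 100L, n_das = 4L)
  co <- coefficient_set()
  agents <- pop$agents
  agents$depressed <- withr::with_seed(1, runif(100) < 0.3)
  lp <- linear_predictor(agents, pop$das, co, include_support = TRUE,
                         include_network = TRUE,
                         depressed = agents$depressed)
  for (i in seq_len(nrow(agents))) {
    a <- agents[i, ]
    d <- pop$das[pop$das$da_id == a$da_id, ]
    manual <- co$intercept +
      co$beta_relative_income * (a$household_income - d$median_after_tax_income) +
      co$beta_edu_postsecondary * (a$education == "some_or_completed_postsecondary") +
      co$beta_edu_graduate * (a$education == "some_or_completed_graduate") +
      co$beta_age * a$age + co$beta_white * a$white +
      co$beta_born_in_canada * a$born_in_canada +
      co$beta_gov_support * a$gov_support +
      co$beta_prenatal_care_access * a$prenatal_care_access +
      co$beta_safety * a$safety + co$beta_crime * a$crime +
      co$beta_pct_lico * d$pct_lico +
      co$beta_pct_shelter_over_30 * d$pct_shelter_over_30 +
      co$beta_pct_recent_immigrants * d$pct_recent_immigrants +
      co$beta_social_support_present * a$social_support_present +
      co$beta_network_size * length(a$ties[[1]]) +
      co$beta_depressed_ties * sum(agents$depressed[a$ties[[1]]])
    expect_equal(lp[i], manual, tolerance = 1e-12)
  }
})

test_that("probability is the inverse logit and monotone", {
  expect_equal(probability(0), 0.5)
  expect_equal(probability(0.175), 1 / (1 + exp(-0.175)))
  expect_equal(round(probability(0.175), 4), 0.5436)
  x <- seq(-30, 30, length.out = 500)
  expect_false(is.unsorted(probability(x)))
  expect_gt(probability(30), 1 - 1e-12)
  expect_error(probability(Inf))
})

test_that("default signs: higher income never raises depression risk", {
  pop <- small_pop(seed = 43)
  co <- coefficient_set()
  expect_lt(co$beta_relative_income, 0)
  expect_lt(co$beta_network_size, 0)
  expect_gt(co$beta_depressed_ties, 0)
  expect_lt(abs(co$beta_depressed_ties), abs(co$beta_network_size))

  p_before <- probability(linear_predictor(pop$agents, pop$das, co))
  richer <- pop$agents
  richer$household_income <- richer$household_income +
    withr::with_seed(2, runif(nrow(richer), 0, 20000))
  p_after <- probability(linear_predictor(richer, pop$das, co))
  expect_true(all(p_after <= p_before + 1e-15))
})

test_that("calibrate_threshold matches a brute-force order-statistic oracle", {
  # worked example
  cal <- calibrate_threshold(c(0.1, 0.2, 0.3, 0.4), target = 0.5)
  expect_true(cal$tau > 0.2 && cal$tau <= 0.3)
  expect_equal(cal$achieved_prevalence, 0.5)

  cal1 <- calibrate_threshold(c(0.2, 0.5, 0.9), target = 1)
  expect_lte(cal1$tau, 0.2)
  expect_equal(cal1$achieved_prevalence, 1)

  expect_error(calibrate_threshold(numeric(0), 0.5), "nonempty")

  # oracle: the best achievable share is over taus at the order statistics
  withr::with_seed(99, {
    for (rep in 1:20) {
      probs <- runif(sample(5:200, 1))
      target <- runif(1)
      cal <- calibrate_threshold(probs, target)
      shares <- vapply(c(probs, Inf),
                       function(t) mean(probs >= t), numeric(1))
      best <- min(abs(shares - target))
      expect_lte(abs(cal$achieved_prevalence - target), best + 1e-12)
      expect_equal(mean(probs >= cal$tau), cal$achieved_prevalence)
    }
  })

  # exactness within 1/n on tie-free inputs
  withr::with_seed(7, {
    probs <- runif(5000)
    cal <- calibrate_threshold(probs, 0.3443)
    expect_lte(abs(cal$achieved_prevalence - 0.3443), 1 / 5000)
  })
})

test_that("fit_logistic rejects one-class outcomes and flags separation", {
  pop <- small_pop(seed = 47, n_agents = 300L)
  expect_error(
    fit_logistic(pop$agents, rep(TRUE, 300), pop$das),
    "both classes")

  # outcome perfectly determined by a covariate => separation error + hint
  sep_y <- pop$agents$safety > 0.8
  expect_error(
    fit_logistic(pop$agents, sep_y, pop$das),
    "penalize")
  # the suggested remedy produces a finite fit
  fit <- fit_logistic(pop$agents, sep_y, pop$das, penalize = TRUE)
  expect_true(all(is.finite(unlist(fit$coefficients))))
})

test_that("zero-signal data yields small, non-significant slopes", {
  # type-I error check: outcomes independent of covariates
  pop <- small_pop(seed = 53, n_agents = 4000L, n_das = 10L)
  n_sig <- 0L
  reps <- 20L
  withr::with_seed(17, {
    for (r in seq_len(reps)) {
      y <- runif(4000) < 0.35
      fit <- fit_logistic(pop$agents, y, pop$das)
      z <- coef(fit$glm)["relative_income"] /
        sqrt(diag(vcov(fit$glm))["relative_income"])
      if (abs(z) > qnorm(0.995)) n_sig <- n_sig + 1L
    }
  })
  expect_lte(n_sig / reps, 0.05 + 1e-9)
})
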