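test_that("generate_das respects invariants, degenerate n and determinism", {
  p <- cohort_params(seed = 3)
  das <- generate_das(p)
  expect_equal(nrow(das), 183L)
  expect_true(all(das$median_after_tax_income > 0))
  for (col in c("pct_lico", "pct_shelter_over_30", "pct_recent_immigrants"))
    expect_true(all(das[[col]] >= 0 & das[[col]] <= 1))

  expect_identical(das, generate_das(p))  # same seed, field-by-field

  p1 <- small_params(n_das = 1L, n_agents = 50L)
  das1 <- generate_das(p1)
  expect_equal(nrow(das1), 1L)
  agents1 <- generate_cohort(das1, p1)
  expect_true(all(agents1$da_id == das1$da_id))

  expect_error(cohort_params(n_das = 0), "n_das")
})

test_that("generate_cohort marginals, band consistency and determinism", {
  p <- cohort_params(seed = 11)
  das <- generate_das(p)
  agents <- generate_cohort(das, p)
  expect_equal(nrow(agents), p$n_agents)
  expect_error(generate_cohort(das[0, ], p), "nonempty")

  # incomes agree with their band, before tax
  br <- p$income_band_breaks
  expect_true(all(agents$income_before_tax >= br[agents$income_band] &
                    agents$income_before_tax < br[agents$income_band + 1L]))
  expect_equal(agents$household_income,
               agents$income_before_tax * p$after_tax_factor)
  expect_true(all(agents$age >= 18 & agents$age <= 47))

  # every configured proportion recovered within 3 binomial SEs
  n <- p$n_agents
  check3se <- function(obs_count, prob) {
    se <- sqrt(prob * (1 - prob) / n)
    expect_lt(abs(obs_count / n - prob), 3 * se + 1e-12)
  }
  check3se(sum(agents$white), p$p_white)
  check3se(sum(agents$born_in_canada), p$p_born_in_canada)
  check3se(sum(agents$gov_support), p$p_gov_support)
  for (i in seq_along(p$p_education))
    check3se(sum(as.integer(agents$education) == i), p$p_education[i])

  # income bands inside the exact binomial 99% CI at n = 17,865
  for (b in seq_along(p$p_income_band)) {
    ci <- qbinom(c(0.005, 0.995), n, p$p_income_band[b])
    obs <- sum(agents$income_band == b)
    expect_true(obs >= ci[1] && obs <= ci[2],
                label = sprintf("band %d count %d in [%d, %d]",
                                b, obs, ci[1], ci[2]))
  }

  expect_identical(agents, generate_cohort(das, p))
})

test_that("large-sample white fraction lands within 1% of 78.64%", {
  p <- cohort_params(n_agents = 100000L, seed = 5)
  agents <- generate_cohort(generate_das(p), p)
  expect_lt(abs(mean(agents$white) - 0.7864), 0.01)
})

test_that("point-mass category probabilities give constant attributes", {
  p <- small_params(
    n_agents = 200L,
    p_education = c(high_school_or_less = 0,
                    some_or_completed_postsecondary = 1,
                    some_or_completed_graduate = 0),
    p_white = 1, p_born_in_canada = 0
  )
  agents <- generate_cohort(generate_das(p), p)
  expect_true(all(agents$education == "some_or_completed_postsecondary"))
  expect_true(all(agents$white))
  expect_false(any(agents$born_in_canada))
})

test_that("assign_networks is symmetric, within-DA, and defines support", {
  pop <- small_pop(seed = 23, n_agents = 600L, n_das = 6L)
  agents <- pop$agents
  expect_symmetric_ties(agents$ties)
  for (i in seq_len(nrow(agents)))
    expect_true(all(agents$da_id[agents$ties[[i]]] == agents$da_id[i]))
  expect_identical(agents$social_support_present, lengths(agents$ties) >= 1L)

  # mean degree 0 disables the network entirely
  p0 <- small_params(seed = 23, n_agents = 200L, mean_degree = 0)
  a0 <- assign_networks(generate_cohort(generate_das(p0), p0), p0)
  expect_true(all(lengths(a0$ties) == 0L))
  expect_false(any(a0$social_support_present))
})

test_that("degree distribution matches the configured model (chi-square GOF)", {
  p <- cohort_params(seed = 31)
  pop <- generate_population(p)
  deg <- lengths(pop$agents$ties)
  n <- length(deg)

  # expected degree pmf: mixture over realized DA sizes of
  # Binomial(m - 1, mean_degree / (m - 1)); computed independently of the
  # sampler
  sizes <- table(pop$agents$da_id)
  kmax <- max(deg)
  exp_pmf <- rep(0, kmax + 1L)
  for (m in as.integer(sizes)) {
    pe <- min(1, p$mean_degree / (m - 1))
    exp_pmf <- exp_pmf + m * dbinom(0:kmax, m - 1L, pe)
  }
  exp_counts <- exp_pmf / n * n  # per-agent weights already sum to n
  obs <- tabulate(deg + 1L, nbins = kmax + 1L)

  # pool cells with small expected counts so every cell has >= 5
  keep <- exp_counts >= 5
  tail_obs <- sum(obs[!keep]); tail_exp <- sum(exp_counts[!keep])
  o <- c(obs[keep], tail_obs); e <- c(exp_counts[keep], tail_exp)
  chisq <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  expect_gt(pchisq(chisq, df, lower.tail = FALSE), 0.01)
})

test_that("identical params give an identical full population", {
  p <- small_params(seed = 77)
  expect_identical(generate_population(p), generate_population(p))
})
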