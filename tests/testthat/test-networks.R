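test_that("condition_table encodes the eight-condition design", {
  tab <- condition_table()
  expect_length(tab, 8L)
  flag_mat <- t(vapply(tab, function(s)
    c(s$income_change, s$include_support_covariate,
      s$remove_depressed_ties, s$add_ties), logical(4)))
  expect_equal(nrow(unique(flag_mat)), 8L)  # all distinct

  expect_equal(unname(flag_mat[1, ]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(flag_mat[2, ]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(flag_mat[3, ]), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(flag_mat[4, ]), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unname(flag_mat[5, ]), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(unname(flag_mat[6, ]), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(unname(flag_mat[7, ]), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(flag_mat[8, ]), c(FALSE, FALSE, FALSE, TRUE))
  expect_error(condition_spec(9))
})

test_that("act removes depressed ties symmetrically and skips saturated DAs", {
  # 4 agents, one DA; agent 1 tied to 2, 3, 4; agents 2 and 3 depressed
  ties <- list(c(2L, 3L, 4L), c(1L), c(1L), c(1L))
  depressed <- c(FALSE, TRUE, TRUE, FALSE)
  spec <- condition_spec(6)  # remove only

  out <- act(ties, 1L, depressed, da_members = 1:4, spec = spec)
  expect_equal(out$ties[[1]], 4L)
  expect_equal(out$ties[[2]], integer(0))
  expect_equal(out$ties[[3]], integer(0))
  expect_equal(out$ties[[4]], 1L)
  expect_equal(out$skipped, 0L)

  # no depressed ties -> unchanged
  out2 <- act(ties, 1L, rep(FALSE, 4), da_members = 1:4, spec = spec)
  expect_equal(out2$ties, ties)

  # saturated 2-agent DA: addition impossible, one skip logged
  spec8 <- condition_spec(8)
  out3 <- act(list(2L, 1L), 1L, c(FALSE, FALSE), da_members = 1:2,
              spec = spec8)
  expect_equal(out3$ties, list(2L, 1L))
  expect_equal(out3$skipped, 1L)
})

test_that("network_step preserves symmetry under all eight conditions", {
  pop <- small_pop(seed = 83, n_agents = 400L, n_das = 4L)
  agents <- pop$agents
  agents$depressed <- withr::with_seed(3, runif(400) < 0.34)
  for (spec in condition_table()) {
    out <- withr::with_seed(11, network_step(agents, spec))
    expect_symmetric_ties(out$ties)
    expect_identical(out$social_support_present, lengths(out$ties) >= 1L)
    # within-DA only, even after additions
    for (i in seq_len(nrow(out)))
      expect_true(all(out$da_id[out$ties[[i]]] == out$da_id[i]))
  }
})

test_that("network_step with p_act = 0 is the identity", {
  pop <- small_pop(seed = 89, n_agents = 300L)
  agents <- pop$agents
  agents$depressed <- withr::with_seed(4, runif(300) < 0.34)
  spec <- condition_spec(5, p_act = 0)
  out <- withr::with_seed(5, network_step(agents, spec))
  expect_identical(out$ties, agents$ties)
})

test_that("removal drops exactly the ties to depressed agents", {
  pop <- small_pop(seed = 97, n_agents = 500L, n_das = 5L)
  agents <- pop$agents
  agents$depressed <- withr::with_seed(6, runif(500) < 0.34)
  out <- withr::with_seed(7, network_step(agents, condition_spec(6)))
  # with every agent acting, any tie touching a depressed agent is gone:
  # non-depressed agents keep exactly their non-depressed ties, depressed
  # agents are fully isolated (their neighbours dropped them symmetrically)
  dep_ids <- which(agents$depressed)
  for (i in seq_len(nrow(out))) {
    if (agents$depressed[i]) {
      expect_length(out$ties[[i]], 0L)
    } else {
      expect_equal(out$ties[[i]], sort(setdiff(agents$ties[[i]], dep_ids)))
    }
  }
})

test_that("network_offset arithmetic and the removal trade-off", {
  co <- coefficient_set(beta_network_size = -0.3, beta_depressed_ties = 0.1)
  depressed <- c(FALSE, TRUE, FALSE, FALSE)
  expect_equal(network_offset(integer(0), depressed, co), 0)
  expect_equal(network_offset(c(2L, 3L, 4L), depressed, co), -0.8)
  expect_equal(network_offset(c(3L, 4L), depressed, co), -0.6)
  # losing the depressed tie raised the logit by 0.2
  expect_equal(network_offset(c(3L, 4L), depressed, co) -
                 network_offset(c(2L, 3L, 4L), depressed, co), 0.2)
})

test_that("add-only lowers mean risk, remove-only raises it (default coeffs)", {
  pop <- small_pop(seed = 103, n_agents = 2000L, n_das = 20L)
  co <- coefficient_set()
  lp0 <- linear_predictor(pop$agents, pop$das, co, include_network = TRUE,
                          depressed = rep(FALSE, 2000))
  cal <- calibrate_threshold(probability(lp0), 0.3443)
  agents <- pop$agents
  agents$depressed <- probability(lp0) >= cal$tau

  p_now <- function(a) mean(probability(
    linear_predictor(a, pop$das, co, include_network = TRUE,
                     depressed = agents$depressed)))
  p_base <- p_now(agents)

  add <- withr::with_seed(8, network_step(agents, condition_spec(8)))
  expect_lt(p_now(add), p_base)

  rem <- withr::with_seed(9, network_step(agents, condition_spec(6)))
  expect_gt(p_now(rem), p_base)
})
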