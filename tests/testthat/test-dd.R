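test_that("next_offer applies the halving bisection rule", {
  cfg <- dd_config("mobile")
  expect_equal(next_offer(character(), cfg), 5)
  expect_equal(next_offer("sooner", cfg), 2.5)
  expect_equal(next_offer(c("sooner", "later"), cfg), 3.75)
  expect_error(next_offer(rep("later", 5), cfg), "n_choices")
  expect_error(next_offer("maybe", cfg), "sooner")
})

test_that("run_staircase reproduces the canonical extreme and hyperbolic traces", {
  cfg <- dd_config("mobile")
  always_later <- run_staircase(function(o) "later", cfg, delay = 30)
  expect_equal(always_later$choices$offer_sooner, c(5, 7.5, 8.75, 9.375, 9.6875))
  expect_equal(always_later$later_propensity, 1)
  expect_equal(always_later$indifference_estimate, 9.84375)

  always_sooner <- run_staircase(function(o) "sooner", cfg, delay = 30)
  expect_equal(always_sooner$later_propensity, 0)
  expect_equal(always_sooner$indifference_estimate, 0.15625)

  # deterministic hyperbolic agent, k = 0.01/day at 180 days: V = 3.5714
  blk <- run_staircase(det_agent(0.01, 180), cfg, delay = 180)
  expect_equal(blk$choices$choice, c("sooner", "later", "sooner", "later", "later"))
  expect_equal(blk$later_propensity, 0.6)
  expect_equal(blk$indifference_estimate, 3.59375)
})

test_that("staircase agrees with brute-force enumeration of all 2^5 sequences", {
  cfg <- dd_config("mobile")
  grid <- expand.grid(rep(list(c("sooner", "later")), 5), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    seq_i <- unlist(grid[i, ])
    oracle <- enumerate_staircase(seq_i)
    pos <- 0
    agent <- function(o) { pos <<- pos + 1; seq_i[pos] }
    blk <- run_staircase(agent, cfg, delay = 30)
    expect_equal(blk$choices$offer_sooner, oracle$offers)
    expect_equal(blk$indifference_estimate, oracle$estimate)
    expect_equal(blk$later_propensity, mean(seq_i == "later"))
    expect_equal(blk$sooner_cumulative + blk$later_propensity, 1)
  }
})

test_that("the deterministic indifference estimate brackets the present value", {
  cfg <- dd_config("mobile")
  half_final <- cfg$initial_step / 2^(cfg$n_choices - 1)
  for (k in c(0.002, 0.01, 0.05, 0.2)) for (D in c(30, 180, 365)) {
    V <- 10 / (1 + k * D)
    blk <- run_staircase(det_agent(k, D), cfg, delay = D)
    expect_lte(abs(blk$indifference_estimate - V), half_final + 1e-12)
  }
})

test_that("indifference estimates are monotone in discount rate and delay", {
  # A titrating staircase tracks the indifference point, so the monotone
  # readout is the indifference estimate (the propensity oscillates around
  # the bisection pattern except for extreme discounting).
  cfg <- dd_config("mobile")
  ks <- c(0.001, 0.005, 0.02, 0.1, 0.5)
  est_k <- vapply(ks, function(k)
    run_staircase(det_agent(k, 180), cfg, delay = 180)$indifference_estimate,
    numeric(1))
  expect_true(all(diff(est_k) <= 0))
  delays <- c(7, 30, 90, 180, 365)
  est_d <- vapply(delays, function(D)
    run_staircase(det_agent(0.02, D), cfg, delay = D)$indifference_estimate,
    numeric(1))
  expect_true(all(diff(est_d) <= 0))
  # extreme discounting drives the propensity to its limits
  expect_gte(run_staircase(det_agent(1e-5, 30), cfg, 30)$later_propensity, 0.8)
  expect_lte(run_staircase(det_agent(10, 365), cfg, 365)$later_propensity, 0.2)
})

test_that("score_dd tabulates propensities and rejects duplicate blocks", {
  cfg <- dd_config("mobile")
  b30 <- run_staircase(det_agent(0.01, 30), cfg, delay = 30)
  b180 <- run_staircase(det_agent(0.01, 180), cfg, delay = 180)
  tab <- score_dd(list(b30, b180))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$later_propensity[tab$delay == 180], 0.6)
  expect_equal(tab$sooner_cumulative, 1 - tab$later_propensity)
  expect_error(score_dd(list(b30, b30)), "duplicate")
})

test_that("the lab preset staircase converges before 30 trials", {
  cfg <- dd_config("lab")
  blk <- run_staircase(det_agent(0.01, 180), cfg, delay = 180)
  expect_lt(nrow(blk$choices), 30)
  # converged: the bracketing half-step is below 1% of the larger amount
  half <- cfg$initial_step / 2^(nrow(blk$choices) - 1)
  expect_lt(half / 2, 0.01 * cfg$larger_amount)
  expect_lte(abs(blk$indifference_estimate - 10 / (1 + 0.01 * 180)), half)
})

test_that("estimate_k recovers deterministic agents and flags boundaries", {
  cfg <- dd_config("mobile")
  cell <- diff(log10(default_k_grid()))[1]
  for (k in c(0.001, 0.01, 0.1)) {
    blocks <- lapply(c(30, 180, 365), function(D)
      run_staircase(det_agent(k, D), cfg, delay = D))
    fit <- estimate_k(blocks)
    expect_lte(abs(log10(fit$k) - log10(k)), cell + 1e-9)
  }
  all_later <- lapply(c(30, 180), function(D)
    run_staircase(function(o) "later", cfg, delay = D))
  fit_low <- estimate_k(all_later)
  expect_true(fit_low$boundary)
  expect_equal(fit_low$k, min(default_k_grid()))

  # block order cannot change a product likelihood
  blocks <- lapply(c(30, 180, 365), function(D)
    run_staircase(det_agent(0.02, D), cfg, delay = D))
  expect_equal(estimate_k(blocks)$k, estimate_k(rev(blocks))$k)
})
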