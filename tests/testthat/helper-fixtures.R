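# Shared fixtures built in code at test time.

# Published six-factor loading fixture and its assignments.
table_loadings <- function() sd_loadings()

# A small simulated study reused by pipeline tests (12 participants keeps
# the default test run fast; acceptance tests use the full n = 100).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_participants = 12, seed = 42)
      cache <<- list(config = cfg,
                     dataset = simulate_study(sample_cohort(cfg), config = cfg))
    }
    cache
  }
})

# Deterministic hyperbolic agent for staircase tests.
det_agent <- function(k, delay, A = 10) hyperbolic_chooser(k, delay, A, beta = Inf)

# Enumerate a staircase for an arbitrary fixed choice sequence (independent
# brute-force oracle for the adjusting-amount update rule).
enumerate_staircase <- function(choices, start = 5, step0 = 2.5) {
  offers <- numeric(length(choices))
  off <- start
  for (i in seq_along(choices)) {
    offers[i] <- off
    st <- step0 / 2^(i - 1)
    off <- off + if (choices[i] == "sooner") -st else st
  }
  half <- step0 / 2^(length(choices) - 1)
  est <- offers[length(choices)] +
    if (choices[length(choices)] == "later") half else -half
  list(offers = offers, estimate = est)
}
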