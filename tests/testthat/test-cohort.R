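test_that("cohort sampling is deterministic with stable per-participant substreams", {
  cfg <- cohort_config(n_participants = 5, seed = 11, n_days = 3)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a, b)

  bigger <- sample_cohort(cohort_config(n_participants = 8, seed = 11, n_days = 3))
  expect_identical(bigger[1:5], a)  # growing the cohort preserves early draws

  dsa <- simulate_study(a, config = cfg)
  dsb <- simulate_study(b, config = cfg)
  expect_identical(dsa$sd, dsb$sd)
  expect_identical(dsa$gng, dsb$gng)
})

test_that("trait links propagate into task parameters and questionnaire scales", {
  cfg <- cohort_config(n_participants = 2000, seed = 21)
  coh <- sample_cohort(cfg)
  thrill <- vapply(coh, function(p) p$traits[["thrill"]], numeric(1))
  pumps <- vapply(coh, function(p) p$bart_params$mean_target_pumps, numeric(1))
  expect_gt(cor(thrill, pumps), 0.3)  # positive thrill -> pumping link

  sens <- vapply(coh, function(p)
    p$scales$value[p$scales$scale == "upps_sensation"], numeric(1))
  # analytic correlation implied by the linear scale model
  d <- list(w = c(-0.10, -0.15, 0.05, 0.00, 0.55, -0.35), s = 0.70)
  r_expected <- d$w[5] / sqrt(sum(d$w^2) + d$s^2)
  expect_lt(abs(cor(thrill, sens) - r_expected), 0.05)

  k <- vapply(coh, function(p) p$dd_params$k, numeric(1))
  intent <- vapply(coh, function(p) p$traits[["intentional"]], numeric(1))
  expect_lt(cor(intent, log(k)), -0.2)  # intentionality slows discounting
})

test_that("evening states shift in the configured directions", {
  cfg <- cohort_config(n_participants = 150, seed = 31, n_days = 4)
  ds <- simulate_study(sample_cohort(cfg), config = cfg)
  ema <- ds$sd[ds$sd$slot %in% c("morning", "evening"), ]
  means <- tapply(ema$value, list(ema$item_index, ema$slot), mean)
  diff_ev <- means[, "evening"] - means[, "morning"]
  dyn <- cfg$state_dynamics
  shifted <- as.character(dyn$index[dyn$evening_shift_sign != 0])
  signs <- dyn$evening_shift_sign[dyn$evening_shift_sign != 0]
  expect_true(all(sign(diff_ev[shifted]) == signs))
  # unshifted items stay close to balanced
  flat <- as.character(dyn$index[dyn$evening_shift_sign == 0])
  expect_true(all(abs(diff_ev[flat]) < abs(cfg$evening_shift_mag * cfg$scale_sd) / 2))
})

test_that("with vanishing daily noise, momentary responses equal the person means", {
  cfg <- cohort_config(n_participants = 3, seed = 7, n_days = 5,
                       state_noise_sd = 1e-9)
  ds <- simulate_study(sample_cohort(cfg), config = cfg)
  morn <- ds$sd[ds$sd$slot == "morning", ]
  spread <- tapply(morn$value, list(morn$participant_id, morn$item_index), sd)
  expect_lt(max(spread, na.rm = TRUE), 1e-6)
})

test_that("discount rates of deterministic cohort agents are recoverable", {
  cfg <- cohort_config(n_participants = 100, seed = 13)
  coh <- sample_cohort(cfg)
  dcfg <- dd_config("mobile")
  cell <- diff(log10(default_k_grid()))[1]
  errs <- vapply(coh, function(p) {
    blocks <- lapply(c(30, 180, 365), function(D) run_staircase(
      hyperbolic_chooser(p$dd_params$k, D, 10, beta = Inf), dcfg, delay = D))
    abs(log10(estimate_k(blocks)$k) - log10(p$dd_params$k))
  }, numeric(1))
  # the 5-trial staircase brackets indifference to +/- 0.156 reward units,
  # which for some k/delay combinations is slightly coarser than one log cell
  expect_gte(mean(errs <= cell + 1e-9), 0.9)
  expect_true(all(errs <= 2 * cell + 1e-9))
})

test_that("factor-model data generation reproduces the implied covariance", {
  L <- table_loadings()
  set.seed(14)
  X <- generate_sd_from_factor_model(L, n = 5000)
  Z <- scale(X)
  comm <- rowSums(L^2)
  implied <- (L %*% t(L)) / sqrt(outer(comm + pmax(1 - comm, 0.05),
                                       comm + pmax(1 - comm, 0.05)))
  emp <- cor(Z)
  off <- upper.tri(emp)
  expect_lt(mean(abs(emp[off] - implied[off])), 0.05)

  set.seed(15)
  noise_only <- generate_sd_from_factor_model(matrix(0, 20, 6), n = 3000,
                                              noise = "independent")
  emp0 <- cor(noise_only)
  expect_lt(max(abs(emp0[upper.tri(emp0)])), 0.08)
})

test_that("simulated datasets flatten into schema-valid, plan-consistent records", {
  st <- small_study()
  recs <- study_to_records(st$dataset)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(recs, path)
  back <- read_session_log(path)
  expect_equal(nrow(back), nrow(recs))
  one <- recs[recs$participant_id == "p001", ]
  adh <- compute_adherence(st$dataset$plan, one)
  expect_equal(adh$completion_fraction, 1)  # simulator skips nothing
})
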