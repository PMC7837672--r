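test_that("varimax rotation preserves the total explained variance", {
  set.seed(1)
  X <- generate_sd_from_factor_model(n = 1200)
  pc <- pca_varimax(X, 6)
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  unrotated_ss <- sum(p$sdev[1:6]^2)
  expect_equal(sum(pc$explained_per_component) * 20 / 100, unrotated_ss,
               tolerance = 1e-8)
  expect_equal(pc$total_explained, sum(pc$explained_per_component))
  # sign convention: each component's largest-magnitude loading is positive
  for (j in 1:6) expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
})

test_that("an exact two-factor structure is recovered up to permutation and sign", {
  L2 <- matrix(0, 12, 2)
  L2[1:6, 1] <- 0.85
  L2[7:12, 2] <- c(0.9, 0.85, 0.8, 0.8, 0.75, 0.7)
  set.seed(2)
  X <- generate_sd_from_factor_model(L2, n = 5000)
  pc <- pca_varimax(X, 2)
  fc <- factor_congruence(pc, L2)
  expect_equal(fc$n_matched, 12)
  expect_true(all(fc$congruence > 0.98))
  perm <- pc$loadings[, order(fc$mapping)]
  for (j in 1:2) if (sum(perm[, j] * L2[, j]) < 0) perm[, j] <- -perm[, j]
  # primary loadings recover tightly; zero cross-loadings wobble a little
  # more under sampling because the rotation criterion is nearly flat there
  expect_lt(max(abs(perm - L2)[L2 != 0]), 0.05)
  expect_lt(max(abs(perm - L2)), 0.1)
})

test_that("pca_varimax rejects degenerate inputs", {
  X <- matrix(rnorm(100), 20, 5)
  X[, 3] <- 7
  colnames(X) <- paste0("item", 1:5)
  expect_error(pca_varimax(X, 2), "item3")
  expect_error(pca_varimax(matrix(rnorm(20), 4, 5), 2), "more respondents")
})

test_that("correlation cells match the brute-force Pearson formula", {
  x <- c(1, 4, 2, 7)
  y <- c(2, 5, 1, 9)
  brute_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tab <- validity_table(data.frame(f = x), data.frame(s = y))
  expect_equal(tab$r, brute_r)
  n <- 4
  brute_t <- brute_r * sqrt((n - 2) / (1 - brute_r^2))
  expect_equal(tab$p, 2 * pt(-abs(brute_t), n - 2))
  expect_equal(tab$n, 4)

  # symmetry and affine invariance
  rev_tab <- validity_table(data.frame(f = y), data.frame(s = x))
  expect_equal(rev_tab$r, tab$r)
  scaled <- validity_table(data.frame(f = 3 * x - 10), data.frame(s = y))
  expect_equal(scaled$p, tab$p)

  ident <- validity_table(data.frame(f = x), data.frame(s = x))
  expect_equal(ident$r, 1)
  expect_lt(ident$p, 1e-6)

  few <- validity_table(data.frame(f = c(1, 2, NA, NA)),
                        data.frame(s = c(1, NA, 3, 4)))
  expect_true(is.na(few$r))  # below the n >= 3 floor
})

test_that("paired contrasts match the textbook formula and degenerate identities", {
  sd_tab <- dplyr::bind_rows(lapply(1:3, function(p) tibble::tibble(
    participant_id = paste0("p", p),
    day = c(0L, 1L, 1L), slot = c("baseline", "morning", "evening"),
    item_index = 20L, value = c(50, c(55, 60, 40)[p], c(52, 71, 39)[p]))))
  # per-person morning/evening single values; hand paired t for m vs e
  m <- c(55, 60, 40); e <- c(52, 71, 39)
  d <- m - e
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  tab <- test_retest_contrasts(list(sd = sd_tab), items = 20L)
  row <- tab[tab$pair == "morning_vs_evening", ]
  expect_equal(row$t, t_hand)
  expect_equal(row$df, 2)
  expect_equal(row$r, cor(m, e))

  same <- sd_tab
  same$value[same$slot == "evening"] <- same$value[same$slot == "morning"]
  tab2 <- test_retest_contrasts(list(sd = same), items = 20L)
  row2 <- tab2[tab2$pair == "morning_vs_evening", ]
  expect_equal(row2$t, 0)
  expect_equal(row2$r, 1)
})

test_that("morning and evening responses aggregate to person means before correlating", {
  # two mornings per person; the correlation must use their mean
  sd_tab <- dplyr::bind_rows(lapply(1:4, function(p) tibble::tibble(
    participant_id = paste0("p", p),
    day = c(1L, 2L, 1L), slot = c("morning", "morning", "evening"),
    item_index = 4L, value = c(10 * p, 10 * p + 4, 12 * p))))
  tab <- test_retest_contrasts(list(sd = sd_tab), items = 4L,
                               pairs = list(c("morning", "evening")))
  expect_equal(tab$r, cor(10 * (1:4) + 2, 12 * (1:4)))
})

test_that("mood-state cells recover a perfect coupling and reject absent streams", {
  n <- 30
  set.seed(6)
  val <- sample(1:4, n, replace = TRUE)
  pam <- tibble::tibble(participant_id = paste0("p", 1:n), day = 1L,
                        slot = "morning", pam_index = 1L,
                        valence = val, arousal = 1L,
                        positive = 0, negative = 0)
  sd_tab <- tibble::tibble(participant_id = paste0("p", 1:n), day = 1L,
                           slot = "morning", item_index = 20L,
                           value = as.numeric(val))
  tab <- mood_state_table(list(sd = sd_tab, pam = pam), items = 20L)
  cell <- tab[tab$metric == "valence" & tab$slot == "morning", ]
  expect_equal(cell$r, 1)
  expect_error(mood_state_table(list(sd = sd_tab, pam = NULL)), "affect-meter")
})

test_that("independent mood and state leave correlations near zero", {
  n <- 600
  set.seed(8)
  pam <- tibble::tibble(participant_id = paste0("p", 1:n), day = 1L,
                        slot = "morning", pam_index = 1L,
                        valence = sample(1:4, n, TRUE),
                        arousal = sample(1:4, n, TRUE),
                        positive = runif(n), negative = runif(n))
  sd_tab <- tibble::tibble(participant_id = paste0("p", 1:n), day = 1L,
                           slot = "morning", item_index = 20L,
                           value = runif(n, 0, 100))
  tab <- mood_state_table(list(sd = sd_tab, pam = pam), items = 20L)
  expect_true(all(abs(tab$r[tab$slot == "morning"]) < 0.12))
})

test_that("study factor scores expose the six factors per participant", {
  st <- small_study()
  fs <- study_factor_scores(st$dataset)
  expect_equal(nrow(fs), st$config$n_participants)
  expect_setequal(names(fs)[-1], sd_factor_names())
  expect_true(all(abs(as.matrix(fs[-1])) <= 1))
})
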