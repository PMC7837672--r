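#' Balloon risk task configuration
#'
#' The balloon task presents a sequence of virtual balloons.  Each pump adds
#' `reward_per_pump` to the balloon's provisional earnings; each balloon has
#' a hidden pop threshold drawn uniformly on `{1, ..., threshold_max}`, and
#' pumping to or past it loses the balloon's earnings.  The primary score is
#' the adjusted average: mean pumps over unexploded balloons.
#'
#' Presets: `"mobile"` is the short in-app game (15 balloons, threshold
#' support 1..12); `"lab"` is the computerized laboratory task (30 balloons,
#' threshold support 1..128).  The uniform threshold distribution and the
#' reward increment are conventions of the standard task family; the mobile
#' maximum is sized for a ~2-minute game.
#'
#' @param preset `"mobile"` or `"lab"`.
#' @param n_balloons,threshold_max,reward_per_pump Override preset values.
#' @return A `bart_config` list.
#' @examples
#' bart_config("mobile")
#' @export
bart_config <- function(preset = c("mobile", "lab"), n_balloons = NULL,
                        threshold_max = NULL, reward_per_pump = NULL) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    mobile = list(n_balloons = 15L, threshold_max = 12L, reward_per_pump = 0.05),
    lab    = list(n_balloons = 30L, threshold_max = 128L, reward_per_pump = 0.05))
  cfg$n_balloons <- as.integer(n_balloons %||% cfg$n_balloons)
  cfg$threshold_max <- as.integer(threshold_max %||% cfg$threshold_max)
  cfg$reward_per_pump <- reward_per_pump %||% cfg$reward_per_pump
  cfg$preset_name <- preset
  stopifnot(cfg$n_balloons >= 1, cfg$threshold_max >= 1, cfg$reward_per_pump > 0)
  structure(cfg, class = "bart_config")
}

#' Sample balloon pop thresholds
#'
#' Integer uniform on `{1, ..., threshold_max}`, drawn from the current RNG
#' state (seed with [set.seed()] for reproducibility).
#'
#' @param config A [bart_config()].
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @export
sample_pop_threshold <- function(config, n = 1L) {
  stopifnot(inherits(config, "bart_config"))
  sample.int(config$threshold_max, n, replace = TRUE)
}

#' Play a balloon task session
#'
#' The player is abstracted to a target-pump policy: a function of the
#' balloon index returning the intended number of pumps.  The balloon pops
#' if its hidden threshold is at or below the target; pumps delivered are
#' `min(target, threshold)`.
#'
#' @param policy Function `(balloon_index) -> non-negative integer`.
#' @param config A [bart_config()].
#' @return Tibble with one row per balloon: `balloon, target, pumps,
#'   exploded, earned`.
#' @examples
#' set.seed(1)
#' trials <- play_bart(function(i) 4L, bart_config("mobile"))
#' score_bart(trials, bart_config("mobile"))
#' @export
play_bart <- function(policy, config) {
  stopifnot(inherits(config, "bart_config"))
  n <- config$n_balloons
  targets <- vapply(seq_len(n), function(i) as.numeric(policy(i)), numeric(1))
  if (any(is.na(targets)) || any(targets < 0))
    stop("policy must return non-negative pump targets", call. = FALSE)
  targets <- as.integer(round(targets))
  thresholds <- sample_pop_threshold(config, n)
  exploded <- thresholds <= targets
  pumps <- pmin(targets, thresholds)
  earned <- ifelse(exploded, 0, pumps * config$reward_per_pump)
  tibble::tibble(balloon = seq_len(n), target = targets, pumps = pumps,
                 exploded = exploded, earned = earned)
}

#' Score a balloon task session
#'
#' @param trials Tibble from [play_bart()] (or with columns `pumps`,
#'   `exploded`, `earned`).
#' @param config A [bart_config()].
#' @return A one-row tibble: `adjusted_avg_pumps` (mean pumps over
#'   unexploded balloons; `NA` if every balloon exploded), `n_explosions`,
#'   `total_pumps`, `total_earnings`.
#' @export
score_bart <- function(trials, config) {
  stopifnot(inherits(config, "bart_config"))
  if (!nrow(trials)) stop("cannot score an empty balloon session", call. = FALSE)
  unexploded <- trials$pumps[!trials$exploded]
  tibble::tibble(
    adjusted_avg_pumps = if (length(unexploded)) mean(unexploded) else NA_real_,
    n_explosions = sum(trials$exploded),
    total_pumps = sum(trials$pumps),
    total_earnings = sum(trials$earned))
}

#' Expected earnings of a fixed-target policy
#'
#' Closed form for a constant target of `t` pumps under the uniform
#' threshold: the balloon survives with probability `(N - t)/N`, paying
#' `t * reward_per_pump`, so the per-balloon expectation is
#' `reward_per_pump * t * (N - t) / N`.
#'
#' @param t Fixed pump target, `0 <= t <= threshold_max`.
#' @param config A [bart_config()].
#' @return Expected earnings per balloon.
#' @export
expected_earnings_fixed_policy <- function(t, config) {
  stopifnot(inherits(config, "bart_config"))
  if (t < 0 || t > config$threshold_max)
    stop("t must lie in [0, threshold_max]", call. = FALSE)
  N <- config$threshold_max
  config$reward_per_pump * t * (N - t) / N
}

# Stochastic pumping agent used by the synthetic cohort: per-balloon target
# drawn around the participant's characteristic pump level.
bart_agent_policy <- function(mean_target, sd_target) {
  force(mean_target); force(sd_target)
  function(i) max(0L, as.integer(round(rnorm(1, mean_target, sd_target))))
}
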