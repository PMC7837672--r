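#' Delay-discounting staircase configuration
#'
#' Adjusting-amount titration: the participant repeatedly chooses between a
#' variable smaller-sooner offer and a fixed larger-later reward `A`
#' (hypothetical US $10 for the money variant; hours of free time for the
#' time variant, a labeled stand-in since the original denomination is
#' unspecified).  The first offer is `A/2` and each subsequent offer moves
#' down (after a sooner choice) or up (after a later choice) by a step that
#' halves every trial — bisection titration toward the indifference point.
#'
#' Presets: `"mobile"` gives exactly 5 choices per delay block, with money
#' delays \{30, 180\} days and time delays \{180, 365\} days (1 month,
#' 6 months, 1 year).  `"lab"` runs up to 30 trials per delay, stopping
#' early once the step falls below 1% of `A`; its delays \{2, 30, 180,
#' 365\} days are a convention of adjusting-amount procedures (not printed
#' for the source task).
#'
#' @param preset `"mobile"` or `"lab"`.
#' @param variant `"money"` or `"time"`.
#' @param n_choices,larger_amount,delays,start_offer,initial_step,converge_frac
#'   Override preset values.  `converge_frac` (lab preset: 0.01) stops the
#'   staircase once the next step < `converge_frac * larger_amount`; `NULL`
#'   disables early stopping.
#' @return A `dd_config` list.
#' @export
dd_config <- function(preset = c("mobile", "lab"), variant = c("money", "time"),
                      n_choices = NULL, larger_amount = NULL, delays = NULL,
                      start_offer = NULL, initial_step = NULL,
                      converge_frac = NULL) {
  preset <- match.arg(preset)
  variant <- match.arg(variant)
  A <- larger_amount %||% 10
  cfg <- list(
    n_choices = as.integer(n_choices %||% if (preset == "mobile") 5L else 30L),
    larger_amount = A,
    delays = delays %||% if (preset == "lab") c(2, 30, 180, 365)
             else if (variant == "money") c(30, 180) else c(180, 365),
    variant = variant,
    start_offer = start_offer %||% A / 2,
    initial_step = initial_step %||% A / 4,
    converge_frac = if (preset == "lab") converge_frac %||% 0.01 else converge_frac,
    preset_name = preset)
  stopifnot(cfg$start_offer > 0, cfg$start_offer < cfg$larger_amount,
            cfg$initial_step > 0, all(cfg$delays > 0),
            !anyDuplicated(cfg$delays), cfg$n_choices >= 1)
  structure(cfg, class = "dd_config")
}

#' Next offer of the adjusting-amount staircase
#'
#' Offer 1 is `start_offer`; after choice *i* the offer moves by
#' `initial_step / 2^(i-1)`, downward if the sooner reward was just taken,
#' upward otherwise.
#'
#' @param history Character vector of choices so far (`"sooner"`/`"later"`).
#' @param config A [dd_config()].
#' @return The next smaller-sooner offer.
#' @examples
#' cfg <- dd_config("mobile")
#' next_offer(character(), cfg)              # 5
#' next_offer("sooner", cfg)                 # 2.5
#' next_offer(c("sooner", "later"), cfg)     # 3.75
#' @export
next_offer <- function(history, config) {
  stopifnot(inherits(config, "dd_config"))
  k <- length(history)
  if (k >= config$n_choices)
    stop("staircase history already has n_choices entries", call. = FALSE)
  if (k && !all(history %in% c("sooner", "later")))
    stop("choices must be 'sooner' or 'later'", call. = FALSE)
  offer <- config$start_offer
  if (k) for (i in seq_len(k)) {
    step <- config$initial_step / 2^(i - 1)
    offer <- offer + if (history[i] == "sooner") -step else step
  }
  offer
}

#' Run one staircase block
#'
#' Presents up to `n_choices` offers (stopping early under the lab preset's
#' convergence rule), then brackets the indifference point: after `n`
#' choices the estimate is the final offer moved once more by
#' `initial_step / 2^(n-1)` — upward if the last choice was later, downward
#' otherwise (i.e. the offer the staircase would have presented next).
#'
#' @param choose Function `offer -> "sooner"|"later"`; see
#'   [hyperbolic_chooser()] for the model-based agent.
#' @param config A [dd_config()].
#' @param delay Delay of the larger-later reward, in days.
#' @return A `dd_block` list: `delay`, `variant`, `choices` (tibble `trial,
#'   offer_sooner, choice`), `indifference_estimate`, `later_propensity`,
#'   `sooner_cumulative`.
#' @examples
#' blk <- run_staircase(function(o) "later", dd_config("mobile"), delay = 30)
#' blk$choices$offer_sooner       # 5, 7.5, 8.75, 9.375, 9.6875
#' blk$indifference_estimate      # 9.84375
#' @export
run_staircase <- function(choose, config, delay) {
  stopifnot(inherits(config, "dd_config"))
  offers <- numeric(0); choices <- character(0)
  offer <- config$start_offer
  for (i in seq_len(config$n_choices)) {
    offers[i] <- offer
    ch <- choose(offer)
    if (!ch %in% c("sooner", "later"))
      stop("choose() must return 'sooner' or 'later'", call. = FALSE)
    choices[i] <- ch
    step <- config$initial_step / 2^(i - 1)
    offer <- offer + if (ch == "sooner") -step else step
    if (!is.null(config$converge_frac) &&
        step / 2 < config$converge_frac * config$larger_amount) break
  }
  n <- length(choices)
  half <- config$initial_step / 2^(n - 1)
  est <- offers[n] + if (choices[n] == "later") half else -half
  structure(list(
    delay = delay, variant = config$variant,
    choices = tibble::tibble(trial = seq_len(n), offer_sooner = offers,
                             choice = choices),
    indifference_estimate = est,
    later_propensity = mean(choices == "later"),
    sooner_cumulative = mean(choices == "sooner")),
    class = "dd_block")
}

#' Choice propensities per delay block
#'
#' @param blocks List of `dd_block` objects.
#' @return Tibble with one row per `(variant, delay)`: `later_propensity`,
#'   `sooner_cumulative` (their complement), `indifference_estimate`,
#'   `n_choices`.  Duplicate `(variant, delay)` pairs are an error.
#' @export
score_dd <- function(blocks) {
  if (!length(blocks)) stop("no staircase blocks to score", call. = FALSE)
  out <- dplyr::bind_rows(lapply(blocks, function(b)
    tibble::tibble(variant = b$variant, delay = b$delay,
                   later_propensity = b$later_propensity,
                   sooner_cumulative = b$sooner_cumulative,
                   indifference_estimate = b$indifference_estimate,
                   n_choices = nrow(b$choices))))
  if (anyDuplicated(out[c("variant", "delay")]))
    stop("duplicate (variant, delay) block", call. = FALSE)
  out
}

#' Hyperbolic discounting agent
#'
#' Values the delayed reward at `V = A / (1 + k * delay)` and prefers the
#' later reward whenever `V` exceeds the sooner offer.  With finite `beta`
#' the preference is a logistic (softmax) choice in the value difference;
#' `beta = Inf` gives the deterministic agent.
#'
#' @param k Discount rate per day, `k >= 0`.
#' @param delay Delay in days.
#' @param A Larger-later amount.
#' @param beta Inverse temperature (per reward unit).
#' @return Function `offer -> "sooner"|"later"`.
#' @export
hyperbolic_chooser <- function(k, delay, A, beta = Inf) {
  force(k); force(delay); force(A); force(beta)
  V <- A / (1 + k * delay)
  function(offer) {
    if (is.infinite(beta)) return(if (V > offer) "later" else "sooner")
    if (runif(1) < plogis(beta * (V - offer))) "later" else "sooner"
  }
}

#' Default grid for discount-rate estimation
#'
#' Log-spaced over `[1e-4, 10]` per day, 10 points per decade.
#' @export
default_k_grid <- function() 10^seq(-4, 1, by = 0.1)

#' Maximum-likelihood hyperbolic discount rate
#'
#' Grid search under the hyperbolic value model `V = A/(1 + kD)` with a
#' logistic choice rule of fixed inverse temperature.  Ties in the
#' likelihood resolve to the smaller `k`.  When every choice in every block
#' is identical the data only bound `k`, and the returned grid endpoint is
#' flagged as a boundary estimate.
#'
#' @param blocks List of `dd_block` objects (from one participant, any mix
#'   of delays/variants; the likelihood is a product over choices, so block
#'   order is irrelevant).
#' @param A Larger-later amount the blocks were run with.
#' @param grid Candidate `k` values (log-spaced recommended).
#' @param beta Logistic inverse temperature used for the fit.
#' @return List: `k`, `beta`, `boundary` (flag), `loglik`.
#' @export
estimate_k <- function(blocks, A = 10, grid = default_k_grid(), beta = 2) {
  if (!length(blocks)) stop("need at least one block", call. = FALSE)
  grid <- sort(grid)
  offers <- unlist(lapply(blocks, function(b) b$choices$offer_sooner))
  later <- unlist(lapply(blocks, function(b) b$choices$choice == "later"))
  delays <- unlist(lapply(blocks, function(b) rep(b$delay, nrow(b$choices))))
  ll <- vapply(grid, function(k) {
    p <- plogis(beta * (A / (1 + k * delays) - offers))
    sum(log(ifelse(later, p, 1 - p)))
  }, numeric(1))
  best <- which.max(ll)  # first index on ties -> smaller k
  all_same <- length(unique(later)) == 1L
  at_edge <- best %in% c(1L, length(grid))
  list(k = grid[best], beta = beta, boundary = all_same || at_edge,
       loglik = ll[best])
}
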