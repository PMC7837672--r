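#' Cued go/no-go configuration
#'
#' Each trial runs fixation cross (250 ms), blank (250 ms), an orientation
#' cue (vertical or horizontal white rectangle) shown for one of six
#' stimulus onset asynchronies (100, 200, 300, 400, 500, 750 ms), then a go
#' or no-go target (green or blue rectangle) displayed until response or for
#' 500 ms, followed by a 250 ms intertrial interval.  Cues signal the target
#' type with 70% validity.
#'
#' Presets: `"mobile"` has 75 trials and maps the horizontal cue to go;
#' `"lab"` has 250 trials and maps the vertical cue to go (the two published
#' descriptions differ on the mapping, so it is preserved per preset rather
#' than resolved).  Timing parameters are only printed for the mobile task
#' and are reused for the lab preset as a convention.
#'
#' @param preset `"mobile"` or `"lab"`.
#' @param n_trials,cue_validity,soa_set,fixation_ms,blank_ms,target_window_ms,iti_ms,go_cue_orientation
#'   Override preset values.
#' @return A `gng_config` list.
#' @export
gng_config <- function(preset = c("mobile", "lab"), n_trials = NULL,
                       cue_validity = NULL, soa_set = NULL, fixation_ms = NULL,
                       blank_ms = NULL, target_window_ms = NULL, iti_ms = NULL,
                       go_cue_orientation = NULL) {
  preset <- match.arg(preset)
  cfg <- list(n_trials = if (preset == "mobile") 75L else 250L,
              cue_validity = 0.7,
              soa_set = c(100, 200, 300, 400, 500, 750),
              fixation_ms = 250, blank_ms = 250, target_window_ms = 500,
              iti_ms = 250,
              go_cue_orientation = if (preset == "mobile") "horizontal" else "vertical",
              preset_name = preset)
  cfg$n_trials <- as.integer(n_trials %||% cfg$n_trials)
  cfg$cue_validity <- cue_validity %||% cfg$cue_validity
  cfg$soa_set <- soa_set %||% cfg$soa_set
  cfg$fixation_ms <- fixation_ms %||% cfg$fixation_ms
  cfg$blank_ms <- blank_ms %||% cfg$blank_ms
  cfg$target_window_ms <- target_window_ms %||% cfg$target_window_ms
  cfg$iti_ms <- iti_ms %||% cfg$iti_ms
  cfg$go_cue_orientation <- match.arg(cfg$go_cue_orientation,
                                      c("horizontal", "vertical"))
  stopifnot(cfg$n_trials >= 1, cfg$cue_validity > 0, cfg$cue_validity < 1,
            length(cfg$soa_set) >= 1, !anyDuplicated(cfg$soa_set),
            all(cfg$soa_set > 0), cfg$fixation_ms > 0, cfg$blank_ms > 0,
            cfg$target_window_ms > 0, cfg$iti_ms > 0)
  structure(cfg, class = "gng_config")
}

#' Generate a go/no-go trial schedule
#'
#' Cue orientation is a fair coin per trial; the target is cue-congruent
#' with probability `cue_validity` (realized per-trial Bernoulli, since an
#' exact 70% of 75 trials is not an integer); the SOA is uniform over
#' `soa_set`.  Responses are unset.  Seed the RNG for a reproducible
#' schedule.
#'
#' @param config A [gng_config()].
#' @return Tibble: `trial, cue_orientation, soa, congruent, target`.
#' @examples
#' set.seed(7)
#' sched <- generate_gng_schedule(gng_config("mobile"))
#' table(sched$cue_orientation, sched$target)
#' @export
generate_gng_schedule <- function(config) {
  stopifnot(inherits(config, "gng_config"))
  n <- config$n_trials
  cue <- ifelse(runif(n) < 0.5, "horizontal", "vertical")
  congruent <- runif(n) < config$cue_validity
  cue_signals_go <- cue == config$go_cue_orientation
  target <- ifelse(xor(cue_signals_go, !congruent), "go", "no_go")
  soa <- sample(config$soa_set, n, replace = TRUE)
  tibble::tibble(trial = seq_len(n), cue_orientation = cue, soa = soa,
                 congruent = congruent, target = target)
}

#' Score a completed go/no-go session
#'
#' Commission = response on a no-go trial; omission = no response inside the
#' target window on a go trial.  A response at exactly
#' `target_window_ms` counts as responded; beyond it, the trial is treated
#' as unanswered.  `error_rate` counts commissions and omissions jointly
#' over all trials; `mean_rt_go` averages reaction time over correct go
#' responses.
#'
#' @param trials Schedule tibble with `responded` (logical) and `rt`
#'   (ms, `NA` when not responded) columns filled in.
#' @param config A [gng_config()].
#' @return One-row tibble: `commissions, omissions, error_rate, mean_rt_go,
#'   response_rate, n_go, n_nogo`.
#' @export
score_gng <- function(trials, config) {
  stopifnot(inherits(config, "gng_config"))
  if (!nrow(trials)) stop("cannot score an empty go/no-go session", call. = FALSE)
  if (!all(c("responded", "rt") %in% names(trials)))
    stop("trials must carry responded/rt columns", call. = FALSE)
  in_window <- trials$responded & !is.na(trials$rt) &
    trials$rt <= config$target_window_ms
  go <- trials$target == "go"
  commissions <- sum(!go & in_window)
  omissions <- sum(go & !in_window)
  go_rts <- trials$rt[go & in_window]
  tibble::tibble(
    commissions = commissions, omissions = omissions,
    error_rate = (commissions + omissions) / nrow(trials),
    mean_rt_go = if (length(go_rts)) mean(go_rts) else NA_real_,
    response_rate = mean(in_window),
    n_go = sum(go), n_nogo = sum(!go))
}

#' Simulate responses to a go/no-go schedule
#'
#' The responding agent of the synthetic cohort.  On go trials it responds
#' with probability `1 - omission_prob`, with a lognormal reaction time;
#' draws that land beyond the target window are omissions.  On no-go trials
#' it fails to inhibit with a probability that increases as the SOA
#' shortens (logistic in the SOA, centered on the schedule's mean SOA), the
#' standard cue-dependence of activation/inhibition in this task family.
#'
#' @param schedule Tibble from [generate_gng_schedule()].
#' @param params List: `rt_meanlog`, `rt_sdlog` (lognormal RT, ms),
#'   `commission_prob_base` (inhibition-failure probability at the mean
#'   SOA), `omission_prob`, and `soa_slope` (logit change per 100 ms of
#'   SOA; default 0.3).
#' @param config A [gng_config()].
#' @return The schedule with `responded` and `rt` columns filled.
#' @export
simulate_gng_responses <- function(schedule, params, config) {
  stopifnot(inherits(config, "gng_config"))
  n <- nrow(schedule)
  slope <- params$soa_slope %||% 0.3
  soa_c <- (schedule$soa - mean(config$soa_set)) / 100
  p_commit <- plogis(qlogis(params$commission_prob_base) - slope * soa_c)
  go <- schedule$target == "go"
  wants_response <- ifelse(go, runif(n) >= params$omission_prob,
                           runif(n) < p_commit)
  rt <- rlnorm(n, params$rt_meanlog, params$rt_sdlog)
  responded <- wants_response & rt <= config$target_window_ms
  schedule$responded <- responded
  schedule$rt <- ifelse(responded, rt, NA_real_)
  schedule
}
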