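#' Synthetic cohort configuration
#'
#' The generative model behind the simulator.  Each participant carries six
#' latent trait factors (standard normal, orthogonal by default — the
#' factors of the published solution are varimax-orthogonal), from which
#' everything else derives:
#'
#' \itemize{
#'   \item \strong{Trait questionnaire scores} (three attention/motor/
#'     nonplanning subscales plus total, and four urgency/premeditation/
#'     perseverance/sensation-seeking subscales plus total) are linear
#'     trait combinations plus noise, with weights chosen to echo the sign
#'     pattern of the published convergent-validity table.
#'   \item \strong{Task parameters} come from configurable linear
#'     cross-modal links: characteristic balloon pumping rises with the
#'     thrill factor, go/no-go inhibition failure rises with
#'     inefficiency/impulsivity, response rate falls with thrill seeking,
#'     and the log discount rate rises with impulsivity.
#'   \item \strong{Momentary states}: each state item has a person-level
#'     morning mean and evening mean that are bivariate normal with a
#'     per-item correlation calibrated (see below) against the published
#'     morning-evening correlations, an additive evening shift with the
#'     published direction (more impulsive, distracted, aimless, tired,
#'     pessimistic and thrill-seeking in the evening), and day-to-day AR(1)
#'     fluctuation around those means.
#'   \item \strong{Mood}: affect-meter valence and arousal are linear
#'     functions of the current states plus noise, with coupling signs per
#'     the published mood-state table, discretized onto the 4 x 4 grid.
#' }
#'
#' Calibration: averaging `n_days` AR(1) daily fluctuations attenuates the
#' person-level morning-evening correlation by `1/(1 + vbar)` where `vbar`
#' is the exact variance of an AR(1) mean; the latent correlation is
#' inflated by `(1 + vbar)` so the recovered correlation matches the
#' configured target.
#'
#' @param n_participants Cohort size.
#' @param seed Root seed.  Each participant uses an independent derived
#'   sub-seed, so growing the cohort never perturbs earlier participants.
#' @param n_days Days of morning/evening sampling (default 21).
#' @param state_dynamics Tibble `index, morning_evening_r,
#'   evening_shift_sign`; defaults to the packaged fixture of published
#'   values.
#' @param evening_shift_mag Evening shift magnitude in latent SD units
#'   (default 0.2, a small-to-moderate standardized diurnal effect in line
#'   with the published paired contrasts).
#' @param ar1_rho,state_noise_sd AR(1) autocorrelation and marginal SD of
#'   the daily state fluctuation (defaults 0.4, 0.5: states are mostly
#'   stable person attributes with moderate daily wobble).
#' @param baseline_trait_r Shared variance fraction between the
#'   general-form ("feel in general") latent and the momentary means
#'   (default 0.32, putting baseline-vs-daily correlations in the published
#'   moderate range).
#' @param mood_coupling Tibble `index, valence_w, arousal_w`; defaults to
#'   the packaged fixture (signs per the published mood-state table).
#' @param mood_noise_sd Residual SD of latent valence/arousal (default 0.8).
#' @param scale_center,scale_sd Affine map from latent units to the 0-100
#'   response scale (defaults 50, 12; responses are clipped to the scale).
#' @param links Optional overrides for the cross-modal link parameters; see
#'   `default_crossmodal_links()` in the source for the fields.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 100L, seed = 1L, n_days = 21L,
                          state_dynamics = NULL, evening_shift_mag = 0.2,
                          ar1_rho = 0.4, state_noise_sd = 0.5,
                          baseline_trait_r = 0.32, mood_coupling = NULL,
                          mood_noise_sd = 0.8, scale_center = 50,
                          scale_sd = 12, links = list()) {
  stopifnot(n_participants >= 1, abs(ar1_rho) < 1, state_noise_sd > 0,
            baseline_trait_r > 0, baseline_trait_r <= 1)
  sd_dyn <- state_dynamics %||%
    tibble::as_tibble(utils::read.csv(path_extdata("state_dynamics.csv")))
  stopifnot(all(abs(sd_dyn$morning_evening_r) <= 1))
  mood <- mood_coupling %||%
    tibble::as_tibble(utils::read.csv(path_extdata("mood_coupling.csv")))
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    n_days = as.integer(n_days), state_dynamics = sd_dyn,
    evening_shift_mag = evening_shift_mag, ar1_rho = ar1_rho,
    state_noise_sd = state_noise_sd, baseline_trait_r = baseline_trait_r,
    mood_coupling = mood, mood_noise_sd = mood_noise_sd,
    scale_center = scale_center, scale_sd = scale_sd,
    links = utils::modifyList(default_crossmodal_links(), links)),
    class = "cohort_config")
}

# Cross-modal link defaults: intercepts/weights tying latent traits to task
# parameters.  Weights are on the (inefficient, negative, calm, unhealthy,
# thrill, intentional) trait vector.
default_crossmodal_links <- function() list(
  bart_mean_base = 4.5, bart_thrill_w = 0.9, bart_mean_noise = 0.9,
  bart_pump_sd = 2,
  gng_rt_meanlog_base = log(400), gng_rt_thrill_w = -0.03,
  gng_rt_person_sd = 0.12, gng_rt_sdlog = 0.15,
  gng_commission_base = 0.20, gng_commission_w = 0.5,
  gng_commission_noise = 0.3, gng_soa_slope = 0.3,
  gng_omission_base = 0.04, gng_omission_thrill_w = 0.4,
  gng_omission_noise = 0.3,
  dd_logk_base = log(0.01), dd_logk_w = 0.6, dd_logk_noise = 0.6,
  dd_beta = 2)

# Questionnaire-scale generators: weights on the six traits + residual SD.
external_scale_defs <- function() list(
  bis15_motor        = list(w = c(0.30, 0.00, -0.15, 0.00, 0.10, -0.50), s = 0.70),
  bis15_nonplanning  = list(w = c(0.35, 0.00,  0.10, 0.00, 0.00, -0.25), s = 0.80),
  bis15_attention    = list(w = c(0.45, 0.20, -0.30, 0.00, 0.00, -0.15), s = 0.70),
  upps_urgency       = list(w = c(0.35, 0.10, -0.15, 0.10, 0.00, -0.40), s = 0.75),
  upps_premeditation = list(w = c(0.30, 0.00,  0.00, 0.00, 0.30, -0.30), s = 0.80),
  upps_perseverance  = list(w = c(0.55, 0.15, -0.20, 0.10, 0.00, -0.05), s = 0.70),
  upps_sensation     = list(w = c(-0.10, -0.15, 0.05, 0.00, 0.55, -0.35), s = 0.70))

# Variance of the mean of n consecutive values of a stationary AR(1) process
# with marginal variance s2 and lag-1 autocorrelation rho (exact).
var_mean_ar1 <- function(n, rho, s2) {
  if (n == 1) return(s2)
  k <- seq_len(n - 1)
  s2 / n^2 * (n + 2 * sum((n - k) * rho^k))
}

#' Sample one synthetic participant
#'
#' Draws latent traits, questionnaire scores, task parameters and
#' person-level state means from the current RNG state (see
#' [sample_cohort()] for seeded per-participant substreams).
#'
#' @param config A [cohort_config()].
#' @param participant_id Identifier for the profile.
#' @return A `participant_profile` list: `traits` (named 6-vector),
#'   `scales` (tibble), `bart_params`, `gng_params`, `dd_params`, and
#'   `state_means` (per state item: general/morning/evening latent means).
#' @export
sample_participant <- function(config, participant_id = "p1") {
  stopifnot(inherits(config, "cohort_config"))
  L <- sd_loadings()
  comm <- rowSums(L^2)
  traits <- stats::setNames(rnorm(6), sd_factor_names())
  g20 <- as.numeric(L %*% traits) / sqrt(comm)   # standardized projections

  defs <- external_scale_defs()
  sc <- vapply(defs, function(d) sum(d$w * traits) + rnorm(1, 0, d$s), numeric(1))
  scales <- tibble::tibble(scale = c(names(defs), "bis15_total", "upps_total"),
                           value = c(sc, sum(sc[1:3]), sum(sc[4:7])))

  lk <- config$links
  impuls <- (traits[["inefficient"]] - traits[["intentional"]]) / sqrt(2)
  bart_params <- list(
    mean_target_pumps = lk$bart_mean_base + lk$bart_thrill_w * traits[["thrill"]] +
      rnorm(1, 0, lk$bart_mean_noise),
    pump_sd = lk$bart_pump_sd)
  gng_params <- list(
    rt_meanlog = lk$gng_rt_meanlog_base + lk$gng_rt_thrill_w * traits[["thrill"]] +
      rnorm(1, 0, lk$gng_rt_person_sd),
    rt_sdlog = lk$gng_rt_sdlog,
    commission_prob_base = plogis(qlogis(lk$gng_commission_base) +
      lk$gng_commission_w * impuls + rnorm(1, 0, lk$gng_commission_noise)),
    omission_prob = plogis(qlogis(lk$gng_omission_base) +
      lk$gng_omission_thrill_w * traits[["thrill"]] +
      rnorm(1, 0, lk$gng_omission_noise)),
    soa_slope = lk$gng_soa_slope)
  dd_params <- list(
    k = exp(lk$dd_logk_base + lk$dd_logk_w * impuls +
              rnorm(1, 0, lk$dd_logk_noise)),
    beta = lk$dd_beta)

  # Person-level latent means for the 10 state items.  The general-form
  # latent b, morning mean m and evening mean e share the trait projection;
  # the m-e correlation is the calibrated (attenuation-inflated) target.
  dyn <- config$state_dynamics
  vbar <- var_mean_ar1(config$n_days, config$ar1_rho, config$state_noise_sd^2)
  rp <- pmin(dyn$morning_evening_r * (1 + vbar), 0.995)
  g_state <- g20[dyn$index]
  u_m <- rnorm(nrow(dyn)); u_e <- rnorm(nrow(dyn))
  state_means <- tibble::tibble(
    index = dyn$index,
    general = sqrt(config$baseline_trait_r) * g_state +
      sqrt(1 - config$baseline_trait_r) * rnorm(nrow(dyn)),
    morning = sqrt(rp) * g_state + sqrt(1 - rp) * u_m,
    evening = sqrt(rp) * g_state + sqrt(1 - rp) * u_e +
      dyn$evening_shift_sign * config$evening_shift_mag)
  # General-form latents for the 10 non-state items (trait form only).
  other <- setdiff(1:20, dyn$index)
  general_other <- tibble::tibble(
    index = other,
    general = sqrt(config$baseline_trait_r) * g20[other] +
      sqrt(1 - config$baseline_trait_r) * rnorm(length(other)))

  structure(list(participant_id = participant_id, traits = traits,
                 scales = scales, bart_params = bart_params,
                 gng_params = gng_params, dd_params = dd_params,
                 state_means = state_means, general_other = general_other),
            class = "participant_profile")
}

#' Sample a cohort with independent per-participant substreams
#'
#' @param config A [cohort_config()].
#' @return List of `participant_profile`s, named `p001`, `p002`, ...
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- sprintf("p%03d", seq_len(config$n_participants))
  profiles <- lapply(seq_along(ids), function(i) {
    set.seed(derive_seed(config$seed, i, stream = 0L))
    sample_participant(config, ids[i])
  })
  stats::setNames(profiles, ids)
}

# One AR(1) path of length n with marginal sd s and autocorrelation rho.
ar1_path <- function(n, rho, s) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, s)
  if (n > 1) for (d in 2:n) x[d] <- rho * x[d - 1] + rnorm(1, 0, s * sqrt(1 - rho^2))
  x
}

to_scale <- function(latent, config) {
  clamp(config$scale_center + config$scale_sd * latent, 0, 100)
}

# Map latent valence/arousal onto the 1..4 grid by standard-normal quartiles.
discretize_affect <- function(latent, spread) {
  cuts <- qnorm(c(0.25, 0.5, 0.75)) * spread
  findInterval(latent, cuts) + 1L
}

#' Simulate a full study
#'
#' Walks every participant through the plan: semantic-differential forms,
#' affect-meter readings, and the slot's task sessions played by the
#' profile's model-based agents (pumping policy, go/no-go responder,
#' hyperbolic chooser).  Fully reproducible from `config$seed`.
#'
#' @param cohort List of profiles from [sample_cohort()].
#' @param plan Plan from [build_protocol()] (defaults to a fresh plan drawn
#'   under the cohort seed).
#' @param config The [cohort_config()] the cohort was drawn with.
#' @return A `study_dataset` list of tibbles: `sd` (semantic-differential
#'   responses), `pam` (affect readings), `bart`, `gng`, `dd` (per-session
#'   scores), `scales` (questionnaire scores), `profiles` (true latent
#'   parameters, for recovery tests), and the `plan`.
#' @export
simulate_study <- function(cohort, plan = NULL, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(plan)) {
    set.seed(derive_seed(config$seed, 0L, stream = 9L))
    plan <- build_protocol(protocol_config(n_days = config$n_days))
  }
  mood <- config$mood_coupling
  wnorm_v <- sqrt(sum(mood$valence_w^2))
  wnorm_a <- sqrt(sum(mood$arousal_w^2))
  state_sd_marginal <- sqrt(1 + config$state_noise_sd^2)
  affect_spread <- sqrt(1 + config$mood_noise_sd^2)

  one <- function(prof, idx) {
    set.seed(derive_seed(config$seed, idx, stream = 1L))
    nd <- config$n_days
    items <- prof$state_means$index
    ni <- length(items)
    wm <- vapply(seq_len(ni), function(j)
      ar1_path(nd, config$ar1_rho, config$state_noise_sd), numeric(nd))
    we <- vapply(seq_len(ni), function(j)
      ar1_path(nd, config$ar1_rho, config$state_noise_sd), numeric(nd))

    # Accumulate plain vectors; build tibbles once per participant.
    sd_day <- list(); sd_slot <- list(); sd_item <- list(); sd_val <- list()
    pam_day <- integer(0); pam_slot <- character(0); pam_idx <- integer(0)
    bart_rows <- list(); gng_rows <- list(); dd_rows <- list()
    stamp <- function(tab, day, slot) {
      tab$participant_id <- prof$participant_id
      tab$day <- day; tab$slot <- slot
      tab
    }
    cfg_bart <- bart_config("mobile")
    cfg_gng <- gng_config("mobile")
    cfg_dd <- list(money = dd_config("mobile", variant = "money"),
                   time = dd_config("mobile", variant = "time"))
    for (s in seq_len(nrow(plan))) {
      day <- plan$day[s]; slot <- plan$slot[s]
      if (slot %in% c("baseline", "day21")) {
        latent20 <- numeric(20)
        latent20[items] <- prof$state_means$general
        latent20[prof$general_other$index] <- prof$general_other$general
        latent20 <- latent20 + rnorm(20, 0, config$state_noise_sd)
        sd_day[[s]] <- rep(day, 20L); sd_slot[[s]] <- rep(slot, 20L)
        sd_item[[s]] <- 1:20; sd_val[[s]] <- to_scale(latent20, config)
        state_z <- latent20[items] / state_sd_marginal
      } else {
        base <- if (slot == "morning") prof$state_means$morning else prof$state_means$evening
        fluct <- if (slot == "morning") wm[day, ] else we[day, ]
        latent <- base + fluct
        sd_day[[s]] <- rep(day, ni); sd_slot[[s]] <- rep(slot, ni)
        sd_item[[s]] <- items; sd_val[[s]] <- to_scale(latent, config)
        state_z <- latent / state_sd_marginal
      }
      if (plan$pam[s]) {
        v_lat <- sum(mood$valence_w * state_z) / wnorm_v +
          rnorm(1, 0, config$mood_noise_sd)
        a_lat <- sum(mood$arousal_w * state_z) / wnorm_a +
          rnorm(1, 0, config$mood_noise_sd)
        valence <- discretize_affect(v_lat, affect_spread)
        arousal <- discretize_affect(a_lat, affect_spread)
        pam_day <- c(pam_day, day); pam_slot <- c(pam_slot, slot)
        pam_idx <- c(pam_idx, (4L - arousal) * 4L + valence)
      }
      for (engine in plan$tasks[[s]]) {
        if (engine == "bart") {
          sc <- score_bart(play_bart(bart_agent_policy(
            prof$bart_params$mean_target_pumps, prof$bart_params$pump_sd),
            cfg_bart), cfg_bart)
          bart_rows[[length(bart_rows) + 1L]] <- stamp(sc, day, slot)
        } else if (engine == "gng") {
          sched <- simulate_gng_responses(generate_gng_schedule(cfg_gng),
                                          prof$gng_params, cfg_gng)
          gng_rows[[length(gng_rows) + 1L]] <- stamp(score_gng(sched, cfg_gng),
                                                     day, slot)
        } else if (engine == "dd") {
          for (variant in c("money", "time")) {
            cfg <- cfg_dd[[variant]]
            blocks <- lapply(cfg$delays, function(D) run_staircase(
              hyperbolic_chooser(prof$dd_params$k, D, cfg$larger_amount,
                                 prof$dd_params$beta), cfg, D))
            dd_rows[[length(dd_rows) + 1L]] <- stamp(score_dd(blocks), day, slot)
          }
        } else {
          stop("no engine registered for task '", engine, "'", call. = FALSE)
        }
      }
    }
    pam <- pam_score(pam_idx)
    pam$participant_id <- prof$participant_id
    pam$day <- pam_day; pam$slot <- pam_slot
    list(sd = tibble::tibble(participant_id = prof$participant_id,
                             day = unlist(sd_day), slot = unlist(sd_slot),
                             item_index = unlist(sd_item),
                             value = unlist(sd_val)),
         pam = pam,
         bart = dplyr::bind_rows(bart_rows), gng = dplyr::bind_rows(gng_rows),
         dd = dplyr::bind_rows(dd_rows))
  }

  parts <- lapply(seq_along(cohort), function(i) one(cohort[[i]], i))
  profiles <- dplyr::bind_rows(lapply(cohort, function(p) tibble::tibble(
    participant_id = p$participant_id,
    !!!stats::setNames(as.list(p$traits), paste0("trait_", names(p$traits))),
    bart_mean_target = p$bart_params$mean_target_pumps,
    gng_rt_meanlog = p$gng_params$rt_meanlog,
    gng_commission_base = p$gng_params$commission_prob_base,
    gng_omission_prob = p$gng_params$omission_prob,
    dd_k = p$dd_params$k, dd_beta = p$dd_params$beta)))
  scales <- dplyr::bind_rows(lapply(cohort, function(p)
    dplyr::mutate(p$scales, participant_id = p$participant_id, .before = 1)))
  structure(list(
    sd = dplyr::bind_rows(lapply(parts, `[[`, "sd")),
    pam = dplyr::bind_rows(lapply(parts, `[[`, "pam")),
    bart = dplyr::bind_rows(lapply(parts, `[[`, "bart")),
    gng = dplyr::bind_rows(lapply(parts, `[[`, "gng")),
    dd = dplyr::bind_rows(lapply(parts, `[[`, "dd")),
    scales = scales, profiles = profiles, plan = plan),
    class = "study_dataset")
}

#' Flatten a study dataset into result records
#'
#' One record per slot per component (semantic-differential form, affect
#' reading, task score), suitable for [write_session_log()] and
#' [compute_adherence()].
#'
#' @param dataset A `study_dataset`.
#' @return Result-record tibble.
#' @export
study_to_records <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  ts <- function(day, slot) sprintf("2026-01-%02dT%s:00:00+00:00",
                                    pmin(day + 1, 28),
                                    ifelse(slot == "evening", "20", "08"))
  recs <- list()
  sd_split <- split(dataset$sd,
                    list(dataset$sd$participant_id, dataset$sd$day,
                         dataset$sd$slot), drop = TRUE)
  for (g in sd_split) {
    recs[[length(recs) + 1L]] <- result_record(
      g$participant_id[1], g$day[1], g$slot[1], "sd", "form",
      ts(g$day[1], g$slot[1]),
      list(items = g$item_index, values = g$value))
  }
  for (i in seq_len(nrow(dataset$pam))) {
    r <- dataset$pam[i, ]
    recs[[length(recs) + 1L]] <- result_record(
      r$participant_id, r$day, r$slot, "pam", "pam",
      ts(r$day, r$slot),
      list(pam_index = r$pam_index, valence = r$valence, arousal = r$arousal,
           positive = r$positive, negative = r$negative))
  }
  add_task <- function(tab, engine) {
    for (i in seq_len(nrow(tab))) {
      r <- tab[i, ]
      payload <- as.list(r[setdiff(names(r), c("participant_id", "day", "slot"))])
      recs[[length(recs) + 1L]] <<- result_record(
        r$participant_id, r$day, r$slot, engine, "score",
        ts(r$day, r$slot), payload)
    }
  }
  add_task(dataset$bart, "bart")
  add_task(dataset$gng, "gng")
  dd_first <- dataset$dd[!duplicated(dataset$dd[c("participant_id", "day", "slot")]), ]
  add_task(dd_first, "dd")
  dplyr::bind_rows(recs)
}

#' Simulate semantic-differential data from a loading matrix
#'
#' Generates `n` respondents from the component model `X = F L' + E` with
#' standard-normal factor scores and per-item unique variance
#' `1 - communality` (floored at `uniqueness_floor`).  Two noise rules:
#'
#' \describe{
#'   \item{`"pca_consistent"` (default)}{Unique variance is placed in the
#'     orthogonal complement of the component space (alternating-projection
#'     construction preserving the per-item variances).  Because component
#'     loadings describe the top of a PCA spectrum, this is the generator
#'     whose PCA round trip returns the loading matrix and its explained
#'     variance; with independent noise the leading components would also
#'     absorb unique variance and overstate it.}
#'   \item{`"independent"`}{Classic common-factor noise, independent across
#'     items.}
#' }
#'
#' @param model Items x components loading matrix (default [sd_loadings()]).
#' @param n Number of respondents (>= 2).
#' @param noise `"pca_consistent"` or `"independent"`.
#' @param scale Response bounds for the affine output map.
#' @param uniqueness_floor Minimum unique variance per item.
#' @return `n` x items numeric matrix on the response scale.
#' @export
generate_sd_from_factor_model <- function(model = sd_loadings(), n,
                                          noise = c("pca_consistent", "independent"),
                                          scale = c(0, 100),
                                          uniqueness_floor = 0.05) {
  noise <- match.arg(noise)
  stopifnot(n >= 2)
  L <- as.matrix(model)
  p <- nrow(L); q <- ncol(L)
  comm <- rowSums(L^2)
  psi <- pmax(1 - comm, uniqueness_floor)
  common <- matrix(rnorm(n * q), n, q) %*% t(L)
  E <- if (noise == "independent") {
    matrix(rnorm(n * p), n, p) %*% diag(sqrt(psi))
  } else {
    # Residual covariance with diag psi confined to the orthogonal
    # complement of the component space (alternating projections).
    U <- eigen(L %*% t(L), symmetric = TRUE)$vectors[, seq_len(q), drop = FALSE]
    P <- diag(p) - U %*% t(U)
    M <- diag(psi)
    for (it in 1:300) {
      M <- P %*% M %*% P; M <- (M + t(M)) / 2
      diag(M) <- psi
    }
    M <- P %*% M %*% P; M <- (M + t(M)) / 2
    em <- eigen(M, symmetric = TRUE)
    half <- em$vectors %*% diag(sqrt(pmax(em$values, 0))) %*% t(em$vectors)
    matrix(rnorm(n * p), n, p) %*% half
  }
  latent <- common + E
  mid <- mean(scale); halfr <- diff(scale) / 2
  clamp(mid + halfr / 3 * latent, scale[1], scale[2])
}
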