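#' Assessment protocol configuration
#'
#' The 21-day schedule: a baseline slot (day 0) with the 20-item trait
#' semantic-differential form, an affect-meter reading and all three active
#' tasks; morning and evening momentary slots on days 1..21 with the
#' 10-item state form, an affect-meter reading and one randomly assigned
#' task; and a day-21 closing slot with the trait form and all three tasks
#' (no affect meter).
#'
#' @param n_days Number of morning/evening days (default 21).
#' @param balanced If `TRUE`, assign tasks to momentary slots in shuffled
#'   balanced blocks of three instead of the default i.i.d. uniform draws.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(n_days = 21L, balanced = FALSE) {
  stopifnot(n_days >= 1)
  structure(list(n_days = as.integer(n_days), balanced = balanced,
                 tasks = registered_engines()),
            class = "protocol_config")
}

#' Build an assessment plan
#'
#' Draws each momentary slot's single task (seed the RNG for a
#' reproducible plan) and lays out the full slot sequence.
#'
#' @param config A [protocol_config()].
#' @return Tibble with one row per slot: `day, slot, sd_form
#'   ("trait20"/"state10"/NA), pam` (logical), and `tasks` (list-column of
#'   engine names).  Default config: 44 rows (baseline + 21 x 2 + day21).
#' @examples
#' set.seed(1)
#' plan <- build_protocol(protocol_config())
#' nrow(plan)  # 44
#' @export
build_protocol <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  n_ema <- 2L * config$n_days
  draws <- if (config$balanced) {
    reps <- ceiling(n_ema / 3)
    unlist(lapply(seq_len(reps), function(i) sample(config$tasks)))[seq_len(n_ema)]
  } else {
    sample(config$tasks, n_ema, replace = TRUE)
  }
  ema <- tibble::tibble(
    day = rep(seq_len(config$n_days), each = 2L),
    slot = rep(c("morning", "evening"), config$n_days),
    sd_form = "state10", pam = TRUE,
    tasks = as.list(draws))
  dplyr::bind_rows(
    tibble::tibble(day = 0L, slot = "baseline", sd_form = "trait20",
                   pam = TRUE, tasks = list(config$tasks)),
    ema,
    tibble::tibble(day = config$n_days, slot = "day21", sd_form = "trait20",
                   pam = FALSE, tasks = list(config$tasks)))
}

#' Completion and bonus eligibility over the momentary slots
#'
#' A morning/evening slot counts as complete only when every scheduled
#' component (state form, affect meter, and its assigned task) has at least
#' one record; completion is the fraction of complete slots among all
#' scheduled morning/evening slots, and the adherence bonus requires at
#' least 80%.
#'
#' @param plan Plan tibble from [build_protocol()].
#' @param records Result-record tibble (see [result_record()]); records
#'   referencing a `(day, slot)` absent from the plan are an error.
#' @return One-row tibble: `n_scheduled_ema, n_completed_ema,
#'   n_partial_ema, completion_fraction, bonus_eligible`.
#' @export
compute_adherence <- function(plan, records) {
  if (nrow(records) == 0) {
    records <- result_record("none", 0, "baseline", "x", "x", "x")[0, ]
  }
  validate_records(records)
  key <- function(day, slot) paste(day, slot, sep = "/")
  plan_keys <- key(plan$day, plan$slot)
  rec_keys <- key(records$day, records$slot)
  bad <- setdiff(unique(rec_keys), plan_keys)
  if (length(bad))
    stop("record references slot(s) not in the plan: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ema <- plan[plan$slot %in% c("morning", "evening"), ]
  status <- vapply(seq_len(nrow(ema)), function(i) {
    rs <- records[rec_keys == key(ema$day[i], ema$slot[i]), ]
    if (!nrow(rs)) return("missing")
    need_sd <- any(rs$task_id == "sd")
    need_pam <- any(rs$task_id == "pam")
    need_task <- all(ema$tasks[[i]] %in% rs$task_id)
    if (need_sd && need_pam && need_task) "complete" else "partial"
  }, character(1))
  n_done <- sum(status == "complete")
  frac <- n_done / nrow(ema)
  tibble::tibble(n_scheduled_ema = nrow(ema), n_completed_ema = n_done,
                 n_partial_ema = sum(status == "partial"),
                 completion_fraction = frac, bonus_eligible = frac >= 0.8)
}
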