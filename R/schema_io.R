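#' Task-definition and session-log formats
#'
#' An assessment is defined by an ordered list of steps, serialized as JSON:
#' \preformatted{
#'   {"task_id": "...", "version": "...",
#'    "steps": [{"step_id": "...", "kind": "instruction|question|active_task",
#'               ...kind-specific payload...}]}
#' }
#' Step kinds and their required payload fields:
#' \describe{
#'   \item{instruction}{\code{text}: the text shown to the participant.}
#'   \item{question}{\code{item}: item reference (e.g. a semantic-differential
#'     item index); \code{scale}: numeric \code{c(lo, hi)} response bounds.}
#'   \item{active_task}{\code{engine}: one of [registered_engines()];
#'     \code{config}: the engine's configuration block.}
#' }
#' Sessions are logged as JSON Lines, one result record per line, with fields
#' \code{participant_id}, \code{day}, \code{slot}, \code{task_id},
#' \code{step_id}, \code{timestamp} (ISO-8601) and a step-specific
#' \code{payload} object.  A long-format CSV export
#' (\code{participant_id, day, slot, task_id, step_id, field, value}) is
#' available via [session_log_to_csv()].
#'
#' @name schema_io
NULL

#' Engines that an active-task step may reference
#'
#' @return Character vector of registered engine names.
#' @export
registered_engines <- function() c("bart", "gng", "dd")

new_task_definition <- function(task_id, steps, version, unknown_fields = character()) {
  structure(
    list(task_id = task_id, version = version, steps = steps,
         unknown_fields = unknown_fields),
    class = "task_definition"
  )
}

#' @export
print.task_definition <- function(x, ...) {
  cat("<task_definition> ", x$task_id, " (v", x$version, "), ",
      length(x$steps), " steps: ",
      paste(vapply(x$steps, function(s) paste0(s$step_id, "[", s$kind, "]"),
                   character(1)), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

validate_step <- function(step, i) {
  where <- sprintf("steps[%d]", i)
  if (is.null(step$step_id) || !nzchar(step$step_id))
    stop(sprintf("%s: missing step_id", where), call. = FALSE)
  kind <- step$kind
  if (is.null(kind) || !kind %in% c("instruction", "question", "active_task"))
    stop(sprintf("%s (%s): kind must be instruction, question or active_task",
                 where, step$step_id), call. = FALSE)
  required <- switch(kind,
    instruction = "text",
    question    = c("item", "scale"),
    active_task = c("engine", "config"))
  missing <- setdiff(required, names(step))
  if (length(missing))
    stop(sprintf("%s (%s): %s step missing field(s) %s",
                 where, step$step_id, kind, paste(missing, collapse = ", ")),
         call. = FALSE)
  if (kind == "active_task" && !step$engine %in% registered_engines())
    stop(sprintf("%s (%s): unknown engine '%s' (registered: %s)",
                 where, step$step_id, step$engine,
                 paste(registered_engines(), collapse = ", ")), call. = FALSE)
  invisible(step)
}

#' Validate a task definition
#'
#' Checks the step-list invariants: non-empty, unique step identifiers, kind
#' determines required payload fields, and active-task engines registered.
#'
#' @param task A `task_definition`.
#' @return The task, invisibly, if valid; otherwise an error naming the
#'   offending step.
#' @export
validate_task_definition <- function(task) {
  if (is.null(task$task_id) || !nzchar(task$task_id))
    stop("task definition: missing task_id", call. = FALSE)
  if (length(task$steps) == 0)
    stop(sprintf("task '%s': step list must be non-empty", task$task_id),
         call. = FALSE)
  for (i in seq_along(task$steps)) validate_step(task$steps[[i]], i)
  ids <- vapply(task$steps, `[[`, character(1), "step_id")
  if (anyDuplicated(ids))
    stop(sprintf("task '%s': duplicate step_id '%s'", task$task_id,
                 ids[duplicated(ids)][1]), call. = FALSE)
  invisible(task)
}

KNOWN_TASK_FIELDS <- c("task_id", "version", "steps")

#' Read a task definition from JSON
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return A validated `task_definition`.  Top-level fields outside the
#'   documented dialect are preserved under `$unknown_fields` and flagged
#'   with a warning.
#' @examples
#' task <- read_task_definition(
#'   system.file("extdata", "tasks", "mbart_task.json", package = "impulsim"))
#' task
#' @export
read_task_definition <- function(source) {
  doc <- tryCatch(
    jsonlite::fromJSON(source, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) stop(sprintf("cannot parse task definition '%s': %s",
                                     substr(source, 1, 60), conditionMessage(e)),
                             call. = FALSE))
  unknown <- setdiff(names(doc), KNOWN_TASK_FIELDS)
  if (length(unknown))
    warning(sprintf("task definition: unknown top-level field(s) preserved: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  task <- new_task_definition(
    task_id = doc$task_id %||% "",
    steps = doc$steps %||% list(),
    version = as.character(doc$version %||% "0"),
    unknown_fields = doc[unknown])
  validate_task_definition(task)
  task
}

#' Serialize a task definition to JSON
#'
#' @param task A validated `task_definition`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_task_definition <- function(task, path = NULL) {
  validate_task_definition(task)
  doc <- c(list(task_id = task$task_id, version = task$version,
                steps = task$steps),
           task$unknown_fields)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Construct a result record
#'
#' One scored or raw result for one step of one assessment slot.
#'
#' @param participant_id Participant identifier.
#' @param day Protocol day index (0 = baseline day).
#' @param slot Slot name: `"baseline"`, `"morning"`, `"evening"` or `"day21"`.
#' @param task_id,step_id Identifiers of the task and step producing it.
#' @param timestamp ISO-8601 text with explicit offset.
#' @param payload Named list of step-specific results.
#' @return A one-row tibble with a list-column `payload`.
#' @export
result_record <- function(participant_id, day, slot, task_id, step_id,
                          timestamp, payload = list()) {
  tibble::tibble(
    participant_id = as.character(participant_id),
    day = as.integer(day), slot = as.character(slot),
    task_id = as.character(task_id), step_id = as.character(step_id),
    timestamp = as.character(timestamp), payload = list(payload))
}

RECORD_FIELDS <- c("participant_id", "day", "slot", "task_id", "step_id",
                   "timestamp", "payload")

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(RECORD_FIELDS, names(records))
  if (length(missing))
    stop("result records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

#' Write a session log (JSON Lines)
#'
#' One record per line; an empty record set produces an empty file.  The log
#' is re-readable losslessly with [read_session_log()].
#'
#' @param records Tibble of result records (see [result_record()]).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(records, path) {
  validate_records(records)
  con <- tryCatch(file(path, open = "w"),
                  error = function(e) stop("cannot open '", path, "' for writing",
                                           call. = FALSE))
  on.exit(close(con))
  if (nrow(records)) {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      obj <- list(participant_id = records$participant_id[i],
                  day = records$day[i], slot = records$slot[i],
                  task_id = records$task_id[i], step_id = records$step_id[i],
                  timestamp = records$timestamp[i],
                  payload = records$payload[[i]])
      as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                    null = "null"))
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a session log (JSON Lines)
#'
#' @param path Path to a log written by [write_session_log()].
#' @return Tibble of result records in file order.  A malformed or
#'   schema-violating line raises an error naming the line number.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(participant_id = character(), day = integer(),
                          slot = character(), task_id = character(),
                          step_id = character(), timestamp = character(),
                          payload = list()))
  }
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                                       simplifyDataFrame = FALSE),
                    error = function(e)
                      stop(sprintf("session log line %d: malformed JSON (%s)",
                                   i, conditionMessage(e)), call. = FALSE))
    scalar <- setdiff(RECORD_FIELDS, "payload")
    missing <- scalar[vapply(scalar, function(f)
      is.null(obj[[f]]) || !nzchar(as.character(obj[[f]])[1]), logical(1))]
    missing <- setdiff(missing, "day")
    if (is.null(obj$day)) missing <- c("day", missing)
    if (length(missing))
      stop(sprintf("session log line %d: missing field(s) %s", i,
                   paste(missing, collapse = ", ")), call. = FALSE)
    result_record(obj$participant_id, obj$day, obj$slot, obj$task_id,
                  obj$step_id, obj$timestamp, obj$payload %||% list())
  })
  dplyr::bind_rows(recs)
}

#' Export a session log as long-format CSV
#'
#' Flattens each record's payload into `(field, value)` rows.
#'
#' @param records Tibble of result records.
#' @param path Optional CSV destination.
#' @return The long tibble (columns `participant_id, day, slot, task_id,
#'   step_id, field, value`), invisibly if `path` is given.
#' @export
session_log_to_csv <- function(records, path = NULL) {
  validate_records(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    pl <- records$payload[[i]]
    flat <- unlist(pl, use.names = TRUE)
    if (is.null(flat)) return(NULL)
    tibble::tibble(participant_id = records$participant_id[i],
                   day = records$day[i], slot = records$slot[i],
                   task_id = records$task_id[i], step_id = records$step_id[i],
                   field = names(flat), value = as.character(flat))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
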