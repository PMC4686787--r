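#' Case lifecycle and activity state machine
#'
#' A patient case is one patient's instance of a workflow. Its activities move
#' through three states:
#'
#' * `executed` — at least one execution exists;
#' * `available` — not executed, and either the activity has no incoming
#'   transition (a start activity) or at least one predecessor is executed;
#' * `locked` — otherwise.
#'
#' An activity with several predecessors becomes available as soon as ANY of
#' them is executed (OR-join): branches model alternative clinical strategies
#' the doctor chooses between, and requiring all of them would deadlock the
#' path not taken. The linter flags such joins so workflow authors know.
#'
#' Re-execution of an executed activity is allowed and versioned: clinical
#' corrections and longitudinal re-entry must not destroy history.
#'
#' @name case-lifecycle
NULL

#' Create a patient case
#'
#' A numeric identifier is generated automatically: 1 for the first case in
#' the store, then strictly increasing. The id tags all of the patient's
#' data from then on.
#'
#' @param store A `flux_store`.
#' @param workflow_id Id of a loaded workflow.
#' @param user Acting user; needs write permission on at least one activity
#'   of the workflow.
#' @return The new `flux_case`.
#' @export
create_case <- function(store, workflow_id, user) {
  wf <- store$workflows[[workflow_id]]
  if (is.null(wf)) {
    stop_flux("flux_unknown_workflow",
              sprintf("workflow '%s' is not loaded", workflow_id))
  }
  if (!can_write_some_activity(store, user, wf)) {
    audit_append(store, user, "create-case", list(workflow = workflow_id),
                 list(reason = "no write permission"), outcome = "denied")
    stop_flux("flux_permission_denied",
              sprintf("user '%s' may not create cases for '%s'",
                      user, workflow_id))
  }
  ids <- as.integer(names(store$cases))
  case_id <- if (length(ids)) max(ids) + 1L else 1L
  case <- structure(
    list(case_id = case_id, workflow_id = workflow_id,
         created_at = format_ts(store$clock()), executions = list()),
    class = "flux_case"
  )
  store$cases[[as.character(case_id)]] <- case
  audit_append(store, user, "create-case",
               list(case_id = case_id, workflow = workflow_id))
  case
}

#' @export
print.flux_execution <- function(x, ...) {
  cat(sprintf("<flux_execution> %s v%d (%s, by %s)\n",
              x$activity_id, x$version, x$executed_at, x$executed_by))
  for (nm in names(x$values)) {
    v <- x$values[[nm]]
    if (inherits(v, "data.frame")) {
      cat(sprintf("  %s: <table, %d row(s)>\n", nm, nrow(v)))
    } else {
      cat(sprintf("  %s: %s\n", nm, render_scalar(v)))
    }
  }
  invisible(x)
}

#' @export
print.flux_case <- function(x, ...) {
  cat(sprintf("<flux_case> #%d (workflow %s, created %s): %d execution(s)\n",
              x$case_id, x$workflow_id, x$created_at, length(x$executions)))
  invisible(x)
}

get_case <- function(store, case_id) {
  case <- store$cases[[as.character(case_id)]]
  if (is.null(case)) {
    stop_flux("flux_unknown_case", sprintf("no case with id %s", case_id))
  }
  case
}

executed_set <- function(case) {
  unique(vapply(case$executions, `[[`, character(1), "activity_id"))
}

#' Activity states of a case
#'
#' @param store A `flux_store`.
#' @param case_id Case identifier.
#' @return Data frame with one row per workflow activity, in workflow order:
#'   `activity_id`, `state` (`executed` / `available` / `locked`).
#' @export
status <- function(store, case_id) {
  case <- get_case(store, case_id)
  wf <- store$workflows[[case$workflow_id]]
  done <- executed_set(case)
  states <- vapply(activity_ids(wf), function(id) {
    if (id %in% done) return("executed")
    preds <- predecessors_of(wf, id)
    if (length(preds) == 0L || any(preds %in% done)) "available" else "locked"
  }, character(1))
  data.frame(activity_id = activity_ids(wf), state = unname(states),
             stringsAsFactors = FALSE)
}

activity_state <- function(store, case, activity_id) {
  st <- status(store, case$case_id)
  st$state[st$activity_id == activity_id]
}

#' Latest values of an executed activity
#'
#' @param store A `flux_store`.
#' @param case_id Case identifier.
#' @param activity_id Activity whose highest-version execution to read.
#' @return Named list of typed attribute values (computed attributes
#'   included).
#' @export
latest_values <- function(store, case_id, activity_id) {
  case <- get_case(store, case_id)
  execs <- Filter(function(e) e$activity_id == activity_id, case$executions)
  if (!length(execs)) {
    stop_flux("flux_never_executed",
              sprintf("activity '%s' has never been executed for case %s",
                      activity_id, case_id))
  }
  versions <- vapply(execs, `[[`, integer(1), "version")
  execs[[which.max(versions)]]$values
}

# Latest values of every executed ancestor, merged in workflow order
# (later activities overwrite earlier ones on name collisions).
ancestor_context <- function(store, case, wf, activity_id) {
  anc <- intersect(activity_ids(wf), ancestors_of(wf, activity_id))
  ctx <- list()
  done <- executed_set(case)
  for (a in anc) {
    if (!a %in% done) next
    vals <- latest_values(store, case$case_id, a)
    for (nm in names(vals)) ctx[[nm]] <- vals[[nm]]
  }
  ctx
}

#' Execute an activity for a case
#'
#' Raw text values are validated against every attribute definition of the
#' activity; all errors are collected and, if any exist, nothing is stored
#' (`flux_validation_error` carries the full error table). On success the
#' computed attributes are evaluated over the union of this activity's values
#' and the latest values of its ancestor activities (the activity's own
#' values shadow ancestors on name collision), a new `ActivityExecution`
#' version is appended, and exactly one audit entry is written.
#'
#' @param store A `flux_store`.
#' @param case_id Case identifier.
#' @param activity_id Activity to execute; must be `available` or `executed`
#'   (re-execution is versioned).
#' @param raw_values Named list: single strings for scalar attributes, data
#'   frames (or lists of named character vectors) for table attributes.
#'   Computed attributes must not be supplied.
#' @param user Acting user; needs write permission on the activity.
#' @return The stored execution (`activity_id`, `version`, `executed_at`,
#'   `executed_by`, `values`).
#' @export
execute_activity <- function(store, case_id, activity_id, raw_values = list(),
                             user) {
  case <- get_case(store, case_id)
  wf <- store$workflows[[case$workflow_id]]
  if (!activity_id %in% activity_ids(wf)) {
    stop_flux("flux_unknown_activity",
              sprintf("workflow '%s' has no activity '%s'",
                      case$workflow_id, activity_id))
  }
  if (!check_permission(store, user, wf$workflow_id, activity_id, "write")) {
    audit_append(store, user, "execute-activity",
                 list(case_id = case$case_id, activity = activity_id),
                 list(reason = "no write permission"), outcome = "denied")
    stop_flux("flux_permission_denied",
              sprintf("user '%s' may not execute '%s'", user, activity_id))
  }
  state <- activity_state(store, case, activity_id)
  if (state == "locked") {
    stop_flux("flux_activity_locked",
              sprintf("activity '%s' is locked: no predecessor has been executed",
                      activity_id))
  }
  activity <- wf$activities[[activity_id]]
  registries <- store$registries[[wf$workflow_id]]

  errors <- no_errors()
  values <- list()
  input_names <- names(raw_values) %||% character()
  for (nm in setdiff(input_names, names(activity$attributes))) {
    errors <- rbind(errors, validation_error(nm, "unknown-attribute",
      sprintf("'%s' is not an attribute of activity '%s'", nm, activity_id)))
  }
  for (at in activity$attributes) {
    if (at$kind == "computed") {
      if (at$name %in% input_names) {
        errors <- rbind(errors, validation_error(at$name, "unknown-attribute",
          sprintf("'%s' is computed and cannot be supplied", at$name)))
      }
      next
    }
    raw <- if (at$name %in% input_names) raw_values[[at$name]] else ""
    res <- validate_value(at, raw, registries)
    if (!res$ok) {
      errors <- rbind(errors, res$errors)
    } else if (!is.null(res$value)) {
      values[[at$name]] <- res$value
    }
  }
  if (nrow(errors)) {
    stop_flux("flux_validation_error",
              paste0("validation failed for activity '", activity_id, "':\n",
                     paste(sprintf("  [%s] %s", errors$code, errors$message),
                           collapse = "\n")),
              errors = errors)
  }
  # computed attributes: own values shadow ancestor values
  ctx <- ancestor_context(store, case, wf, activity_id)
  for (nm in names(values)) ctx[[nm]] <- values[[nm]]
  for (at in activity$attributes) {
    if (at$kind != "computed") next
    v <- tryCatch(evaluate_formula(at$formula, ctx), error = function(e) e)
    if (inherits(v, "flux_eval_error") && v$code == "unbound-name") {
      # an optional input is absent: the derived value is absent too
      next
    }
    if (inherits(v, "error")) {
      stop_flux("flux_validation_error",
                sprintf("computed attribute '%s' failed: %s",
                        at$name, conditionMessage(v)),
                errors = validation_error(at$name, "computed-failed",
                                          conditionMessage(v)))
    }
    values[[at$name]] <- v
    ctx[[at$name]] <- v
  }
  prev <- Filter(function(e) e$activity_id == activity_id, case$executions)
  version <- if (length(prev)) {
    max(vapply(prev, `[[`, integer(1), "version")) + 1L
  } else {
    1L
  }
  execution <- structure(
    list(activity_id = activity_id, version = version,
         executed_at = format_ts(store$clock()),
         executed_by = user, values = values),
    class = "flux_execution")
  case$executions[[length(case$executions) + 1L]] <- execution
  store$cases[[as.character(case$case_id)]] <- case
  audit_append(store, user, "execute-activity",
               list(case_id = case$case_id, activity = activity_id),
               list(version = version,
                    attributes = names(values) %||% character(),
                    raw = audit_raw_values(raw_values)))
  execution
}

# Raw submissions go into the audit detail so the trail can be replayed.
audit_raw_values <- function(raw_values) {
  out <- list()
  for (nm in names(raw_values)) {
    v <- raw_values[[nm]]
    if (inherits(v, "data.frame") || is.list(v)) {
      rows <- table_rows(v) %||% list()
      out[[nm]] <- list(kind = "table", rows = lapply(rows, as.list))
    } else {
      out[[nm]] <- list(kind = "scalar", text = as.character(v))
    }
  }
  out
}

#' Suggested next activities for a case
#'
#' Every suggestion rule whose source activity has been executed is evaluated
#' over that activity's latest values, in declaration order. The suggested
#' activities of rules whose condition holds are concatenated, de-duplicated
#' preserving first occurrence, and filtered to activities that are currently
#' `available`. Rules whose condition fails to evaluate are skipped.
#'
#' @param store A `flux_store`.
#' @param case_id Case identifier.
#' @return Character vector of activity ids (possibly empty).
#' @export
suggest_next <- function(store, case_id) {
  case <- get_case(store, case_id)
  wf <- store$workflows[[case$workflow_id]]
  st <- status(store, case_id)
  available <- st$activity_id[st$state == "available"]
  done <- executed_set(case)
  out <- character()
  for (rule in wf$suggestion_rules) {
    if (!rule$source_activity %in% done) next
    vals <- latest_values(store, case_id, rule$source_activity)
    verdict <- tryCatch(evaluate_formula(rule$condition, vals),
                        error = function(e) e)
    if (inherits(verdict, "error")) next
    truthy <- (is.logical(verdict) && isTRUE(verdict)) ||
      (is.numeric(verdict) && is.finite(verdict) && verdict != 0)
    if (truthy) out <- c(out, rule$suggested_activities)
  }
  intersect(unique(out), available)
}
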