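#' Execute activities in bulk from a value file
#'
#' The batch file is UTF-8 CSV (RFC 4180) with header
#' `case_id,activity,attribute,row_index,column,value`, one row per scalar
#' value (`row_index` 0, `column` empty) or per table cell (`row_index`
#' 1..k, `column` the column name). Rows are grouped by
#' `(case_id, activity)`; each group is one submission through
#' [execute_activity()]. Groups are independent: one group's validation
#' failure does not block the others.
#'
#' Case ids not present in the store are created on the fly, provided they
#' extend the store densely (`max + 1`, `max + 2`, ...); a sparse new id is a
#' group error. Rows naming a computed attribute are ignored — computed
#' values are derived, never submitted — which is what lets a long-CSV
#' export re-import cleanly.
#'
#' @param store A `flux_store`.
#' @param workflow_id Workflow the file belongs to.
#' @param file Path to the batch CSV.
#' @param user Acting user.
#' @return Data frame summarizing each group: `case_id`, `activity`,
#'   `status` (`ok`/`error`), `message`. One audit entry is written per
#'   successful group (by the engine) plus one batch-level entry.
#' @export
batch_execute <- function(store, workflow_id, file, user) {
  wf <- store$workflows[[workflow_id]]
  if (is.null(wf)) {
    stop_flux("flux_unknown_workflow",
              sprintf("workflow '%s' is not loaded", workflow_id))
  }
  rows <- tryCatch(
    utils::read.csv(file, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) e
  )
  if (inherits(rows, "error")) {
    stop_flux("flux_unreadable_file",
              sprintf("cannot read batch file '%s': %s",
                      file, conditionMessage(rows)))
  }
  expected <- c("case_id", "activity", "attribute", "row_index", "column", "value")
  with_version <- c("case_id", "activity", "version", "attribute", "row_index",
                    "column", "value")
  if (identical(names(rows), with_version)) {
    # long-CSV exports carry a version column; each (case, activity, version)
    # becomes its own submission, in file order (exports list activities in
    # workflow order and versions ascending, which is replayable as-is)
  } else if (identical(names(rows), expected)) {
    rows$version <- rep("0", nrow(rows))
  } else {
    stop_flux("flux_unreadable_file",
              sprintf("batch file header must be '%s', found '%s'",
                      paste(expected, collapse = ","),
                      paste(names(rows), collapse = ",")))
  }
  summary <- data.frame(case_id = integer(), activity = character(),
                        status = character(), message = character(),
                        stringsAsFactors = FALSE)
  note <- function(case_id, activity, status, message = "") {
    summary <<- rbind(summary, data.frame(
      case_id = as.integer(case_id), activity = activity, status = status,
      message = message, stringsAsFactors = FALSE))
  }
  if (nrow(rows)) {
    bad_case <- !grepl("^[0-9]+$", rows$case_id)
    bad_idx <- !grepl("^[0-9]+$", rows$row_index)
    for (i in which(bad_case | bad_idx)) {
      note(if (bad_case[i]) NA else rows$case_id[i], rows$activity[i], "error",
           sprintf("line %d: malformed case_id or row_index", i + 1L))
    }
    rows <- rows[!(bad_case | bad_idx), , drop = FALSE]
  }
  group_key <- paste(rows$case_id, rows$activity, rows$version, sep = "\r")
  n_ok <- 0L
  for (key in unique(group_key)) {
    grp <- rows[group_key == key, , drop = FALSE]
    case_id <- as.integer(grp$case_id[1L])
    activity <- grp$activity[1L]
    raw_values <- tryCatch(
      group_to_raw_values(grp, wf, activity),
      error = function(e) e
    )
    if (inherits(raw_values, "error")) {
      note(case_id, activity, "error", conditionMessage(raw_values))
      next
    }
    res <- tryCatch({
      ensure_case(store, workflow_id, case_id, user)
      execute_activity(store, case_id, activity, raw_values, user = user)
    }, flux_error = function(e) e)
    if (inherits(res, "error")) {
      note(case_id, activity, "error", conditionMessage(res))
    } else {
      n_ok <- n_ok + 1L
      note(case_id, activity, "ok",
           sprintf("version %d stored", res$version))
    }
  }
  audit_append(store, user, "batch-execute",
               list(workflow = workflow_id),
               list(file = basename(file),
                    groups = length(unique(group_key)),
                    executed = n_ok,
                    failed = sum(summary$status == "error")))
  summary
}

ensure_case <- function(store, workflow_id, case_id, user) {
  if (!is.null(store$cases[[as.character(case_id)]])) return(invisible(NULL))
  ids <- as.integer(names(store$cases))
  nxt <- if (length(ids)) max(ids) + 1L else 1L
  if (case_id != nxt) {
    stop_flux("flux_unknown_case",
              sprintf("case %d does not exist and cannot be created (next id is %d)",
                      case_id, nxt))
  }
  create_case(store, workflow_id, user)
  invisible(NULL)
}

group_to_raw_values <- function(grp, wf, activity_id) {
  activity <- wf$activities[[activity_id]]
  if (is.null(activity)) {
    stop(sprintf("unknown activity '%s'", activity_id))
  }
  raw <- list()
  for (nm in unique(grp$attribute)) {
    at <- activity$attributes[[nm]]
    if (!is.null(at) && at$kind == "computed") next
    sub <- grp[grp$attribute == nm, , drop = FALSE]
    idx <- as.integer(sub$row_index)
    if (all(idx == 0L)) {
      if (nrow(sub) > 1L) {
        stop(sprintf("attribute '%s' has several scalar rows", nm))
      }
      raw[[nm]] <- sub$value
    } else if (all(idx >= 1L)) {
      rows <- lapply(sort(unique(idx)), function(i) {
        cells <- sub[idx == i, , drop = FALSE]
        stats::setNames(cells$value, cells$column)
      })
      raw[[nm]] <- rows
    } else {
      stop(sprintf("attribute '%s' mixes scalar and table rows", nm))
    }
  }
  raw
}
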