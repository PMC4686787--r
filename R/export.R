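#' Export case data to analysis-ready tables
#'
#' Three dialects serve the downstream statistics and data-mining consumers:
#'
#' * `csv-long` — one row per stored scalar value or table cell, columns
#'   `case_id,activity,version,attribute,row_index,column,value`. Lossless
#'   (tables included) and re-importable through [batch_execute()].
#' * `csv-wide` — one row per (case, activity, version), columns
#'   `case_id,activity,version` then one column per scalar attribute under
#'   its activity-qualified name `activity.attribute`. Repeating tables are
#'   excluded (any flattening would be lossy); missing cells are empty.
#' * `arff` — the wide table in ARFF: NUMERIC for integer/real/computed
#'   attributes, DATE (`yyyy-MM-dd`) for dates, a nominal enumeration in
#'   declared order for choice and register attributes, STRING otherwise;
#'   missing values are `?`.
#'
#' By default only each activity's latest version is exported;
#' `all_versions = TRUE` exports the full history.
#'
#' @param store A `flux_store`.
#' @param workflow_id Workflow whose cases to export.
#' @param dialect One of `"csv-long"`, `"csv-wide"`, `"arff"`.
#' @param destination File path to write.
#' @param user Acting user; needs read permission on every activity.
#' @param all_versions Export every execution version instead of the latest.
#' @return The exported table as a data frame, invisibly.
#' @export
export_cases <- function(store, workflow_id, dialect, destination, user,
                         all_versions = FALSE) {
  wf <- store$workflows[[workflow_id]]
  if (is.null(wf)) {
    stop_flux("flux_unknown_workflow",
              sprintf("workflow '%s' is not loaded", workflow_id))
  }
  dialect <- match.arg(dialect, c("csv-long", "csv-wide", "arff"))
  denied <- Filter(function(a) {
    !check_permission(store, user, workflow_id, a, "read")
  }, activity_ids(wf))
  if (length(denied)) {
    audit_append(store, user, "export", list(workflow = workflow_id),
                 list(dialect = dialect, reason = "no read permission",
                      activities = denied), outcome = "denied")
    stop_flux("flux_permission_denied",
              sprintf("user '%s' lacks read permission on: %s",
                      user, paste(denied, collapse = ", ")))
  }
  tab <- if (dialect == "csv-long") {
    long_table(store, wf, all_versions)
  } else {
    wide_table(store, wf, all_versions)
  }
  lines <- switch(dialect,
    "csv-long" = ,
    "csv-wide" = csv_lines(tab),
    "arff" = arff_lines(tab, wf)
  )
  ok <- tryCatch({
    writeLines(lines, destination, useBytes = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_flux("flux_unwritable_destination",
              sprintf("cannot write '%s': %s", destination,
                      conditionMessage(ok)))
  }
  audit_append(store, user, "export", list(workflow = workflow_id),
               list(dialect = dialect, rows = nrow(tab),
                    destination = basename(destination)))
  invisible(tab)
}

wf_cases_sorted <- function(store, wf) {
  cases <- Filter(function(c) c$workflow_id == wf$workflow_id, store$cases)
  ids <- vapply(cases, `[[`, integer(1), "case_id")
  cases[order(ids)]
}

# executions of one case to export: per activity (workflow order), either
# the latest version or all versions in ascending order
export_executions <- function(case, wf, all_versions) {
  out <- list()
  for (aid in activity_ids(wf)) {
    execs <- Filter(function(e) e$activity_id == aid, case$executions)
    if (!length(execs)) next
    versions <- vapply(execs, `[[`, integer(1), "version")
    if (all_versions) {
      out <- c(out, execs[order(versions)])
    } else {
      out <- c(out, execs[which.max(versions)])
    }
  }
  out
}

long_table <- function(store, wf, all_versions) {
  rows <- list()
  push <- function(case_id, activity, version, attribute, row_index, column, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      case_id = case_id, activity = activity, version = version,
      attribute = attribute, row_index = row_index, column = column,
      value = value, stringsAsFactors = FALSE)
  }
  for (case in wf_cases_sorted(store, wf)) {
    for (ex in export_executions(case, wf, all_versions)) {
      activity <- wf$activities[[ex$activity_id]]
      for (at in activity$attributes) {
        v <- ex$values[[at$name]]
        if (is.null(v)) next
        if (at$kind == "table") {
          for (i in seq_len(nrow(v))) {
            for (cn in names(at$columns)) {
              push(case$case_id, ex$activity_id, ex$version, at$name,
                   i, cn, render_scalar(v[[cn]][i]))
            }
          }
        } else {
          push(case$case_id, ex$activity_id, ex$version, at$name,
               0L, "", render_scalar(v))
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(case_id = integer(), activity = character(),
                      version = integer(), attribute = character(),
                      row_index = integer(), column = character(),
                      value = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# scalar (non-table) attributes in workflow order, activity-qualified
wide_columns <- function(wf) {
  cols <- list()
  for (a in wf$activities) {
    for (at in a$attributes) {
      if (at$kind == "table") next
      cols[[length(cols) + 1L]] <- list(
        name = paste0(a$activity_id, ".", at$name),
        activity = a$activity_id, attribute = at$name, def = at)
    }
  }
  cols
}

wide_table <- function(store, wf, all_versions) {
  cols <- wide_columns(wf)
  col_names <- vapply(cols, `[[`, character(1), "name")
  recs <- list()
  for (case in wf_cases_sorted(store, wf)) {
    for (ex in export_executions(case, wf, all_versions)) {
      rec <- stats::setNames(as.list(rep("", length(cols))), col_names)
      for (col in cols) {
        if (col$activity != ex$activity_id) next
        v <- ex$values[[col$attribute]]
        if (!is.null(v)) rec[[col$name]] <- render_scalar(v)
      }
      recs[[length(recs) + 1L]] <- c(
        list(case_id = case$case_id, activity = ex$activity_id,
             version = ex$version), rec)
    }
  }
  if (!length(recs)) {
    out <- c(list(case_id = integer(), activity = character(),
                  version = integer()),
             stats::setNames(rep(list(character()), length(cols)), col_names))
    return(as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(recs, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
}

csv_quote <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

csv_lines <- function(tab) {
  header <- paste(csv_quote(names(tab)), collapse = ",")
  if (!nrow(tab)) return(header)
  cells <- vapply(seq_along(tab), function(j) {
    csv_quote(as.character(tab[[j]]))
  }, character(nrow(tab)))
  if (nrow(tab) == 1L) cells <- matrix(cells, nrow = 1L)
  body <- apply(cells, 1L, paste, collapse = ",")
  c(header, body)
}

arff_quote <- function(x) {
  if (!nzchar(x)) return("''")
  if (grepl("'", x, fixed = TRUE)) {
    # double quotes sidestep readers that ignore backslash escapes
    paste0('"', gsub('"', "\\\\\"", x), '"')
  } else if (grepl("[ ,{}\"%]", x)) {
    paste0("'", x, "'")
  } else {
    x
  }
}

arff_kind <- function(def) {
  switch(def$kind,
    integer = ,
    real = ,
    computed = "numeric",
    date = "date",
    choice = "nominal",
    register = "nominal",
    "string"
  )
}

arff_lines <- function(tab, wf) {
  cols <- wide_columns(wf)
  header <- c(
    sprintf("@relation %s", arff_quote(wf$workflow_id)),
    "",
    "@attribute case_id numeric",
    sprintf("@attribute activity {%s}",
            paste(vapply(activity_ids(wf), arff_quote, character(1)),
                  collapse = ",")),
    "@attribute version numeric"
  )
  for (col in cols) {
    decl <- switch(arff_kind(col$def),
      numeric = "numeric",
      date = 'date "yyyy-MM-dd"',
      string = "string",
      nominal = {
        domain <- if (col$def$kind == "choice") {
          col$def$choices
        } else {
          wf$registries[[col$def$registry]]$entries
        }
        sprintf("{%s}", paste(vapply(domain, arff_quote, character(1)),
                              collapse = ","))
      }
    )
    header <- c(header, sprintf("@attribute %s %s", arff_quote(col$name), decl))
  }
  data_lines <- character()
  if (nrow(tab)) {
    kinds <- c("numeric", "nominal", "numeric",
               vapply(cols, function(c) arff_kind(c$def), character(1)))
    data_lines <- vapply(seq_len(nrow(tab)), function(i) {
      cells <- vapply(seq_along(tab), function(j) {
        v <- as.character(tab[[j]][i])
        if (!nzchar(v)) return("?")
        if (kinds[j] %in% c("nominal", "string")) arff_quote(v) else v
      }, character(1))
      paste(cells, collapse = ",")
    }, character(1))
  }
  c(header, "", "@data", data_lines)
}

#' Deterministic plain-text report for one case
#'
#' Renders the case header and, for every executed activity in workflow
#' order, the latest values in attribute order. Hints and examples are
#' guidance for data entry, not data, and are omitted; repeating tables are
#' rendered as aligned rows. Output is byte-identical across runs for a
#' fixed store.
#'
#' @param store A `flux_store`.
#' @param case_id Case identifier.
#' @return The report as a single string.
#' @export
case_report <- function(store, case_id) {
  case <- get_case(store, case_id)
  wf <- store$workflows[[case$workflow_id]]
  lines <- c(
    sprintf("Case %d — %s", case$case_id, wf$name),
    sprintf("Workflow: %s (version %s)", wf$workflow_id, wf$version),
    sprintf("Created:  %s", case$created_at)
  )
  done <- executed_set(case)
  for (aid in activity_ids(wf)) {
    if (!aid %in% done) next
    activity <- wf$activities[[aid]]
    execs <- Filter(function(e) e$activity_id == aid, case$executions)
    versions <- vapply(execs, `[[`, integer(1), "version")
    ex <- execs[[which.max(versions)]]
    heading <- sprintf("%s (version %d, %s, by %s)",
                       activity$name, ex$version, ex$executed_at,
                       ex$executed_by)
    lines <- c(lines, "", heading, strrep("-", nchar(heading)))
    for (at in activity$attributes) {
      v <- ex$values[[at$name]]
      if (is.null(v)) next
      if (at$kind == "table") {
        lines <- c(lines, sprintf("  %s:", at$name),
                   aligned_table_lines(v, indent = "    "))
      } else {
        lines <- c(lines, sprintf("  %s: %s", at$name, render_scalar(v)))
      }
    }
  }
  paste(c(lines, ""), collapse = "\n")
}

aligned_table_lines <- function(df, indent = "") {
  cells <- rbind(names(df),
                 do.call(cbind, lapply(df, function(col) {
                   vapply(seq_along(col), function(i) render_scalar(col[i]),
                          character(1))
                 })))
  widths <- apply(nchar(cells), 2L, max)
  vapply(seq_len(nrow(cells)), function(i) {
    paste0(indent, paste(formatC(cells[i, ], width = -widths),
                         collapse = "  "))
  }, character(1))
}
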