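#' Read, check and write workflow definition files
#'
#' Workflow files use a minimal structural subset of XPDL 2.x:
#' `Package` > `WorkflowProcesses` > `WorkflowProcess` with
#' `Activities/Activity` and `Transitions/Transition`; all layout and
#' graphics elements are ignored. The clinical schema rides on
#' `ExtendedAttribute` elements:
#'
#' * one `Name="FLUX_FIELD"` per attribute, on its `Activity`;
#' * `Name="FLUX_REGISTRY"` and `Name="FLUX_SUGGEST"` at `Package` level.
#'
#' Each `Value` is a semicolon-separated `KEY=value` record. Field records
#' use the keys `NAME`, `KIND`, `REQUIRED`, `MIN`, `MAX`, `CHOICES`
#' (comma-separated), `REGISTRY`, `FORMULA`, `COLUMNS` (comma-separated
#' `name:kind` pairs), `EXAMPLE`, `HINT`. Registry records use `NAME`,
#' `EXTENSIBLE`, `ENTRIES`; suggestion records use `ID`, `SOURCE`,
#' `CONDITION`, `SUGGEST`. Unknown keys are lint warnings; unknown kinds are
#' errors. Everything is UTF-8 and case-sensitive.
#'
#' @param source Path to an `.xpdl` file, or a single string of XML.
#' @return [parse_workflow()] returns a `flux_workflow`, or raises a
#'   `flux_parse_error` carrying the lint issues when any error-severity
#'   issue exists. [lint_workflow()] never raises: it returns a data frame
#'   of issues (`severity`, `code`, `location`, `message`), empty when the
#'   document is clean.
#' @seealso [serialize_workflow()]
#' @export
parse_workflow <- function(source) {
  res <- xpdl_analyze(source)
  errs <- res$issues[res$issues$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    cond <- structure(
      class = c("flux_parse_error", "error", "condition"),
      list(
        message = paste0(
          "workflow definition is invalid:\n",
          paste(sprintf("  [%s] %s: %s", errs$code, errs$location, errs$message),
                collapse = "\n")),
        call = NULL, issues = res$issues
      )
    )
    stop(cond)
  }
  res$wf
}

#' @rdname parse_workflow
#' @export
lint_workflow <- function(source) {
  xpdl_analyze(source)$issues
}

KNOWN_FIELD_KEYS <- c("NAME", "KIND", "REQUIRED", "MIN", "MAX", "CHOICES",
                      "REGISTRY", "FORMULA", "COLUMNS", "EXAMPLE", "HINT")
KNOWN_REGISTRY_KEYS <- c("NAME", "EXTENSIBLE", "ENTRIES")
KNOWN_SUGGEST_KEYS <- c("ID", "SOURCE", "CONDITION", "SUGGEST")

# Shared front end of parse_workflow()/lint_workflow(): best-effort build of
# the model plus the complete issue list. Never raises on bad input.
xpdl_analyze <- function(source) {
  issues <- no_issues()
  add <- function(severity, code, location, message) {
    issues <<- rbind(issues, lint_issue(severity, code, location, message))
  }
  doc <- tryCatch(
    xml2::read_xml(source),
    error = function(e) e
  )
  if (inherits(doc, "error")) {
    add("error", "xml-malformed", "document", conditionMessage(doc))
    return(list(wf = NULL, issues = issues))
  }
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "Package") {
    add("error", "missing-package", "document",
        sprintf("root element is <%s>, expected <Package>", xml2::xml_name(root)))
    return(list(wf = NULL, issues = issues))
  }
  wf_id <- xml2::xml_attr(root, "Id")
  wf_name <- xml2::xml_attr(root, "Name")
  if (is.na(wf_id) || !nzchar(wf_id)) {
    add("error", "missing-workflow-id", "package", "<Package> has no Id attribute")
    wf_id <- "unnamed"
  }
  if (is.na(wf_name)) wf_name <- wf_id
  version <- xml2::xml_text(
    xml2::xml_find_first(root, "./RedefinableHeader/Version"))
  if (is.na(version) || !nzchar(version)) version <- "1.0"

  procs <- xml2::xml_find_all(root, "./WorkflowProcesses/WorkflowProcess")
  if (length(procs) == 0L) {
    add("error", "missing-process", "package",
        "no <WorkflowProcesses>/<WorkflowProcess> element found")
    return(list(wf = NULL, issues = issues))
  }
  if (length(procs) > 1L) {
    add("warning", "multiple-processes", "package",
        "several <WorkflowProcess> elements; only the first is read")
  }
  proc <- procs[[1L]]

  # registries (package level)
  registries <- list()
  reg_nodes <- xml2::xml_find_all(
    root, "./ExtendedAttributes/ExtendedAttribute[@Name='FLUX_REGISTRY']")
  for (nd in reg_nodes) {
    rec <- decode_record(xml2::xml_attr(nd, "Value"))
    loc <- paste0("registry:", rec$NAME %||% "?")
    for (k in setdiff(names(rec), KNOWN_REGISTRY_KEYS)) {
      add("warning", "unknown-field-key", loc,
          sprintf("unknown key '%s' in FLUX_REGISTRY record", k))
    }
    if (is.null(rec$NAME) || !nzchar(rec$NAME)) {
      add("error", "bad-field-record", "package",
          "FLUX_REGISTRY record has no NAME")
      next
    }
    entries <- split_list(rec$ENTRIES)
    registries[[rec$NAME]] <- registry_def(
      rec$NAME, entries,
      extensible = tolower(rec$EXTENSIBLE %||% "false") == "true")
  }

  # activities in document order
  act_nodes <- xml2::xml_find_all(proc, "./Activities/Activity")
  activities <- list()
  for (nd in act_nodes) {
    act_id <- xml2::xml_attr(nd, "Id")
    act_name <- xml2::xml_attr(nd, "Name")
    if (is.na(act_id) || !nzchar(act_id)) {
      add("error", "empty-activity-id", "activity:?",
          "<Activity> has no Id attribute")
      next
    }
    if (is.na(act_name)) act_name <- act_id
    field_nodes <- xml2::xml_find_all(
      nd, "./ExtendedAttributes/ExtendedAttribute[@Name='FLUX_FIELD']")
    attrs <- list()
    for (fn in field_nodes) {
      rec <- decode_record(xml2::xml_attr(fn, "Value"))
      loc <- sprintf("activity:%s/attribute:%s", act_id, rec$NAME %||% "?")
      for (k in setdiff(names(rec), KNOWN_FIELD_KEYS)) {
        add("warning", "unknown-field-key", loc,
            sprintf("unknown key '%s' in FLUX_FIELD record", k))
      }
      at <- tryCatch(
        field_record_to_attribute(rec),
        error = function(e) e
      )
      if (inherits(at, "error")) {
        code <- if (grepl("unknown attribute kind", conditionMessage(at))) {
          "unknown-kind"
        } else if (inherits(at, "flux_formula_syntax_error")) {
          "formula-syntax"
        } else {
          "bad-field-record"
        }
        add("error", code, loc, conditionMessage(at))
        next
      }
      attrs[[length(attrs) + 1L]] <- at
    }
    activities[[length(activities) + 1L]] <- activity_def(act_id, act_name, attrs)
  }

  # transitions
  tr_nodes <- xml2::xml_find_all(proc, "./Transitions/Transition")
  tr <- data.frame(
    from = vapply(tr_nodes, function(x) xml2::xml_attr(x, "From") %||% "", character(1)),
    to = vapply(tr_nodes, function(x) xml2::xml_attr(x, "To") %||% "", character(1)),
    stringsAsFactors = FALSE
  )

  # suggestion rules (package level, declaration order = evaluation order)
  rules <- list()
  rule_nodes <- xml2::xml_find_all(
    root, "./ExtendedAttributes/ExtendedAttribute[@Name='FLUX_SUGGEST']")
  for (nd in rule_nodes) {
    rec <- decode_record(xml2::xml_attr(nd, "Value"))
    loc <- paste0("rule:", rec$ID %||% "?")
    for (k in setdiff(names(rec), KNOWN_SUGGEST_KEYS)) {
      add("warning", "unknown-field-key", loc,
          sprintf("unknown key '%s' in FLUX_SUGGEST record", k))
    }
    if (is.null(rec$ID) || is.null(rec$SOURCE) || is.null(rec$CONDITION) ||
        is.null(rec$SUGGEST)) {
      add("error", "bad-field-record", loc,
          "FLUX_SUGGEST needs ID, SOURCE, CONDITION and SUGGEST keys")
      next
    }
    cond <- tryCatch(parse_formula(rec$CONDITION), error = function(e) e)
    if (inherits(cond, "error")) {
      add("error", "rule-syntax", loc, conditionMessage(cond))
      next
    }
    rules[[length(rules) + 1L]] <- suggestion_rule(
      rec$ID, rec$SOURCE, cond, split_list(rec$SUGGEST))
  }

  wf <- workflow_def(wf_id, wf_name, activities, tr, registries, rules,
                     version = version)
  issues <- rbind(issues, check_workflow(wf))
  if (any(issues$severity == "error")) {
    return(list(wf = NULL, issues = issues))
  }
  list(wf = wf, issues = issues)
}

`%||%` <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.atomic(a) && length(a) == 1L && is.na(a)) return(b)
  a
}

decode_record <- function(value) {
  if (is.na(value) || !nzchar(value)) return(list())
  fields <- strsplit(value, ";", fixed = TRUE)[[1]]
  fields <- fields[nzchar(trimws(fields))]
  out <- list()
  for (f in fields) {
    eq <- regexpr("=", f, fixed = TRUE)
    if (eq == -1L) {
      out[[paste0("?", trimws(f))]] <- ""
      next
    }
    key <- toupper(trimws(substr(f, 1L, eq - 1L)))
    out[[key]] <- substr(f, eq + 1L, nchar(f))
  }
  out
}

encode_record <- function(rec) {
  rec <- rec[!vapply(rec, is.null, logical(1))]
  vals <- vapply(rec, as.character, character(1))
  if (any(grepl(";", vals, fixed = TRUE))) {
    stop("record values must not contain ';'")
  }
  paste(paste0(names(rec), "=", vals), collapse = ";")
}

split_list <- function(x) {
  if (is.null(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

field_record_to_attribute <- function(rec) {
  if (is.null(rec$NAME) || !nzchar(rec$NAME)) stop("FLUX_FIELD record has no NAME")
  if (is.null(rec$KIND)) stop(sprintf("attribute '%s' has no KIND", rec$NAME))
  columns <- NULL
  if (!is.null(rec$COLUMNS)) {
    pairs <- split_list(rec$COLUMNS)
    parts <- strsplit(pairs, ":", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2L
    if (any(bad)) {
      stop(sprintf("attribute '%s': COLUMNS entries must be name:kind pairs", rec$NAME))
    }
    columns <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                               vapply(parts, `[`, character(1), 1L))
  }
  attribute_def(
    name = rec$NAME,
    kind = rec$KIND,
    required = tolower(rec$REQUIRED %||% "false") == "true",
    min = if (!is.null(rec$MIN)) as.numeric(rec$MIN),
    max = if (!is.null(rec$MAX)) as.numeric(rec$MAX),
    choices = if (!is.null(rec$CHOICES)) split_list(rec$CHOICES),
    registry = rec$REGISTRY,
    columns = columns,
    formula = rec$FORMULA,
    example = rec$EXAMPLE,
    hint = rec$HINT
  )
}

attribute_to_field_record <- function(at) {
  encode_record(list(
    NAME = at$name,
    KIND = at$kind,
    REQUIRED = if (at$required) "true" else "false",
    MIN = if (!is.null(at$min)) render_scalar(at$min),
    MAX = if (!is.null(at$max)) render_scalar(at$max),
    CHOICES = if (!is.null(at$choices)) paste(at$choices, collapse = ","),
    REGISTRY = at$registry,
    COLUMNS = if (!is.null(at$columns)) {
      paste(paste0(names(at$columns), ":", at$columns), collapse = ",")
    },
    FORMULA = if (!is.null(at$formula)) at$formula$expression,
    EXAMPLE = at$example,
    HINT = at$hint
  ))
}

XPDL_NS <- "http://www.wfmc.org/2008/XPDL2.2"

#' Serialize a workflow definition to XPDL
#'
#' The output re-parses (via [parse_workflow()]) to a workflow structurally
#' equal to the input: same activities in the same order, same attributes in
#' the same order, same transitions, registries and suggestion rules.
#'
#' @param wf A `flux_workflow`.
#' @param path Optional file path; when given the document is written there.
#' @return The XML document as a single string (invisibly when `path` is
#'   given).
#' @export
serialize_workflow <- function(wf, path = NULL) {
  stopifnot(inherits(wf, "flux_workflow"))
  doc <- xml2::xml_new_root("Package", Id = wf$workflow_id, Name = wf$name,
                            xmlns = XPDL_NS)
  hdr <- xml2::xml_add_child(doc, "PackageHeader")
  xml2::xml_add_child(hdr, "XPDLVersion", "2.2")
  xml2::xml_add_child(hdr, "Vendor", "fluxcase")
  rh <- xml2::xml_add_child(doc, "RedefinableHeader")
  xml2::xml_add_child(rh, "Version", wf$version)
  if (length(wf$registries) || length(wf$suggestion_rules)) {
    ext <- xml2::xml_add_child(doc, "ExtendedAttributes")
    for (r in wf$registries) {
      xml2::xml_add_child(ext, "ExtendedAttribute", Name = "FLUX_REGISTRY",
        Value = encode_record(list(
          NAME = r$registry_name,
          EXTENSIBLE = if (r$extensible) "true" else "false",
          ENTRIES = if (length(r$entries)) paste(r$entries, collapse = ","))))
    }
    for (s in wf$suggestion_rules) {
      xml2::xml_add_child(ext, "ExtendedAttribute", Name = "FLUX_SUGGEST",
        Value = encode_record(list(
          ID = s$rule_id, SOURCE = s$source_activity,
          CONDITION = s$condition$expression,
          SUGGEST = paste(s$suggested_activities, collapse = ","))))
    }
  }
  procs <- xml2::xml_add_child(doc, "WorkflowProcesses")
  proc <- xml2::xml_add_child(procs, "WorkflowProcess",
                              Id = paste0(wf$workflow_id, "_process"),
                              Name = wf$name)
  acts <- xml2::xml_add_child(proc, "Activities")
  for (a in wf$activities) {
    an <- xml2::xml_add_child(acts, "Activity", Id = a$activity_id, Name = a$name)
    if (length(a$attributes)) {
      ea <- xml2::xml_add_child(an, "ExtendedAttributes")
      for (at in a$attributes) {
        xml2::xml_add_child(ea, "ExtendedAttribute", Name = "FLUX_FIELD",
                            Value = attribute_to_field_record(at))
      }
    }
  }
  trs <- xml2::xml_add_child(proc, "Transitions")
  if (nrow(wf$transitions)) {
    for (i in seq_len(nrow(wf$transitions))) {
      xml2::xml_add_child(trs, "Transition",
                          Id = sprintf("t%d", i),
                          From = wf$transitions$from[i],
                          To = wf$transitions$to[i])
    }
  }
  tmp <- tempfile(fileext = ".xml")
  on.exit(unlink(tmp), add = TRUE)
  xml2::write_xml(doc, tmp, options = "format")
  out <- paste(readLines(tmp, encoding = "UTF-8"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}
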