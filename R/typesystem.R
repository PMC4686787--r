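#' Typed clinical attributes
#'
#' Every data field of an activity is an attribute with one of eight kinds:
#'
#' * `integer`, `real` — numbers, optionally bounded by inclusive `min`/`max`;
#' * `text` — free text;
#' * `date` — ISO 8601 calendar dates (`YYYY-MM-DD` only);
#' * `choice` — one token from a fixed list declared in the workflow;
#' * `register` — one token that must already exist in a named registry
#'   (a lookup table), preventing free-text misspellings;
#' * `table` — a repeating table with an unbounded number of rows over fixed
#'   scalar columns (e.g. one row per family member);
#' * `computed` — derived at execution time by a formula over other
#'   attributes, never entered by the user.
#'
#' @name attribute-kinds
NULL

ATTRIBUTE_KINDS <- c("integer", "real", "text", "date", "choice",
                     "register", "table", "computed")
SCALAR_KINDS <- c("integer", "real", "text", "date", "choice", "register")

#' Construct an attribute definition
#'
#' @param name Attribute name (token, case-sensitive).
#' @param kind One of the kinds in [attribute-kinds].
#' @param required Must a value be supplied on execution?
#' @param min,max Inclusive bounds, `integer`/`real` kinds only.
#' @param choices Character vector of allowed tokens, `choice` kind only.
#' @param registry Registry name, `register` kind only.
#' @param columns Named character vector `c(colname = "kind", ...)` of scalar
#'   column kinds, `table` kind only.
#' @param formula Expression text or a `flux_formula`, `computed` kind only.
#' @param example,hint Optional guidance text shown to data-entry users.
#' @return An `flux_attribute` list.
#' @export
attribute_def <- function(name, kind, required = FALSE, min = NULL, max = NULL,
                          choices = NULL, registry = NULL, columns = NULL,
                          formula = NULL, example = NULL, hint = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!kind %in% ATTRIBUTE_KINDS) {
    stop(sprintf("unknown attribute kind '%s' for '%s'", kind, name))
  }
  if (!is.null(min) && !is.null(max) && min > max) {
    stop(sprintf("attribute '%s': min (%s) exceeds max (%s)", name, min, max))
  }
  if (kind == "choice") {
    if (is.null(choices) || length(choices) == 0L) {
      stop(sprintf("choice attribute '%s' needs a non-empty choices list", name))
    }
    if (anyDuplicated(choices)) {
      stop(sprintf("choice attribute '%s' has duplicate choices", name))
    }
  }
  if (kind == "register" && (is.null(registry) || !nzchar(registry))) {
    stop(sprintf("register attribute '%s' needs a registry name", name))
  }
  if (kind == "table") {
    if (is.null(columns) || length(columns) == 0L || is.null(names(columns))) {
      stop(sprintf("table attribute '%s' needs named columns", name))
    }
    bad <- !columns %in% SCALAR_KINDS
    if (any(bad)) {
      stop(sprintf("table attribute '%s': column '%s' has non-scalar kind '%s'",
                   name, names(columns)[bad][1L], columns[bad][1L]))
    }
  }
  if (kind == "computed") {
    if (is.null(formula)) {
      stop(sprintf("computed attribute '%s' needs a formula", name))
    }
    if (!inherits(formula, "flux_formula")) formula <- parse_formula(formula)
  }
  structure(
    list(name = name, kind = kind, required = isTRUE(required),
         min = min, max = max, choices = choices, registry = registry,
         columns = columns, formula = formula,
         example = example, hint = hint),
    class = "flux_attribute"
  )
}

validation_error <- function(attribute, code, message, row_index = NA_integer_) {
  data.frame(attribute = attribute, code = code, message = message,
             row_index = as.integer(row_index), stringsAsFactors = FALSE)
}

no_errors <- function() {
  data.frame(attribute = character(), code = character(), message = character(),
             row_index = integer(), stringsAsFactors = FALSE)
}

#' Validate a raw value against an attribute definition
#'
#' Validation is total: any finite text input yields either a typed value or a
#' set of structured errors — it never raises on bad user input. All
#' applicable errors are returned, not just the first. The empty string for a
#' non-required attribute means "absent" (`value` is `NULL`); for a required
#' attribute it is a `missing-required` error.
#'
#' Registry matching is exact and case-sensitive; near misses (edit distance
#' at most 2) are named in the error message but never silently accepted,
#' because the registry kind exists precisely to stop misspellings entering
#' the record.
#'
#' @param attr An `flux_attribute` (kind must not be `computed`; computed
#'   values are produced by the engine, not validated from input).
#' @param raw A single string, or for table attributes a data frame (or list
#'   of named character vectors) of row texts.
#' @param registries Named list of registry definitions (as in a parsed
#'   workflow), consulted for `register` attributes.
#' @return List with `ok` (logical), `value` (typed payload or `NULL`) and
#'   `errors` (data frame with columns attribute, code, message, row_index).
#' @export
validate_value <- function(attr, raw, registries = list()) {
  stopifnot(inherits(attr, "flux_attribute"))
  if (attr$kind == "computed") {
    stop(sprintf("computed attribute '%s' cannot be validated from input", attr$name))
  }
  if (attr$kind == "table") {
    return(validate_table(attr, raw, registries))
  }
  raw <- raw_as_scalar_text(attr, raw)
  if (inherits(raw, "data.frame")) { # scalar attr given a table
    return(failed(validation_error(attr$name, "type-mismatch",
      sprintf("'%s' is a %s attribute, not a table", attr$name, attr$kind))))
  }
  if (is.null(raw) || is.na(raw) || !nzchar(raw)) {
    if (attr$required) {
      return(failed(validation_error(attr$name, "missing-required",
        sprintf("'%s' is required", attr$name))))
    }
    return(list(ok = TRUE, value = NULL, errors = no_errors()))
  }
  errs <- no_errors()
  value <- NULL
  switch(attr$kind,
    integer = {
      if (!grepl("^[+-]?[0-9]+$", raw)) {
        errs <- rbind(errs, validation_error(attr$name, "type-mismatch",
          sprintf("'%s' is not an integer for '%s'", raw, attr$name)))
      } else {
        num <- as.numeric(raw)
        if (abs(num) > .Machine$integer.max) {
          errs <- rbind(errs, validation_error(attr$name, "out-of-range",
            sprintf("%s exceeds the representable integer range for '%s'",
                    raw, attr$name)))
          errs <- rbind(errs, range_errors(attr, num, raw))
        } else {
          value <- as.integer(num)
          errs <- rbind(errs, range_errors(attr, num, raw))
        }
      }
    },
    real = {
      if (!grepl("^[+-]?([0-9]+(\\.[0-9]+)?|\\.[0-9]+)$", raw)) {
        errs <- rbind(errs, validation_error(attr$name, "type-mismatch",
          sprintf("'%s' is not a number for '%s'", raw, attr$name)))
      } else {
        value <- as.numeric(raw)
        if (!is.finite(value)) {
          errs <- rbind(errs, validation_error(attr$name, "out-of-range",
            sprintf("'%s' is too large to represent for '%s'", raw, attr$name)))
          value <- NULL
        } else {
          errs <- rbind(errs, range_errors(attr, value, raw))
        }
      }
    },
    text = {
      value <- raw
    },
    date = {
      if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", raw)) {
        errs <- rbind(errs, validation_error(attr$name, "bad-date",
          sprintf("'%s' is not an ISO date (YYYY-MM-DD) for '%s'", raw, attr$name)))
      } else {
        d <- as.Date(raw, format = "%Y-%m-%d", optional = TRUE)
        # reject normalized-away impossible dates such as 2020-02-30
        if (is.na(d) || format(d, "%Y-%m-%d") != raw) {
          errs <- rbind(errs, validation_error(attr$name, "bad-date",
            sprintf("'%s' is not a real calendar date for '%s'", raw, attr$name)))
        } else {
          value <- d
        }
      }
    },
    choice = {
      if (!raw %in% attr$choices) {
        errs <- rbind(errs, validation_error(attr$name, "not-in-choices",
          sprintf("'%s' is not one of {%s} for '%s'", raw,
                  paste(attr$choices, collapse = ", "), attr$name)))
      } else {
        value <- raw
      }
    },
    register = {
      reg <- registries[[attr$registry]]
      entries <- if (is.null(reg)) character() else reg$entries
      if (!raw %in% entries) {
        near <- registry_near_misses(raw, entries)
        msg <- sprintf("'%s' is not registered in '%s' for '%s'",
                       raw, attr$registry, attr$name)
        if (length(near)) {
          msg <- paste0(msg, sprintf(" (did you mean: %s?)",
                                     paste(near, collapse = ", ")))
        }
        errs <- rbind(errs, validation_error(attr$name, "not-in-registry", msg))
      } else {
        value <- raw
      }
    }
  )
  if (nrow(errs)) failed(errs) else list(ok = TRUE, value = value, errors = no_errors())
}

failed <- function(errs) list(ok = FALSE, value = NULL, errors = errs)

raw_as_scalar_text <- function(attr, raw) {
  if (is.null(raw)) return("")
  if (inherits(raw, "data.frame") || is.list(raw)) return(as.data.frame(raw))
  if (length(raw) != 1L) raw <- paste(raw, collapse = " ")
  as.character(raw)
}

range_errors <- function(attr, value, raw) {
  errs <- no_errors()
  if (!is.null(attr$min) && value < attr$min) {
    errs <- rbind(errs, validation_error(attr$name, "out-of-range",
      sprintf("%s is below the minimum %s for '%s'", raw, attr$min, attr$name)))
  }
  if (!is.null(attr$max) && value > attr$max) {
    errs <- rbind(errs, validation_error(attr$name, "out-of-range",
      sprintf("%s is above the maximum %s for '%s'", raw, attr$max, attr$name)))
  }
  errs
}

registry_near_misses <- function(raw, entries, max_dist = 2L) {
  if (!length(entries)) return(character())
  d <- utils::adist(raw, entries)[1L, ]
  entries[d <= max_dist]
}

validate_table <- function(attr, raw, registries) {
  if (is.null(raw) || (is.character(raw) && length(raw) == 1L && !nzchar(raw))) {
    if (attr$required) {
      return(failed(validation_error(attr$name, "missing-required",
        sprintf("'%s' is required", attr$name))))
    }
    return(list(ok = TRUE, value = NULL, errors = no_errors()))
  }
  rows <- table_rows(raw)
  if (is.null(rows)) {
    return(failed(validation_error(attr$name, "type-mismatch",
      sprintf("'%s' is a table attribute; supply rows of column values", attr$name))))
  }
  if (length(rows) == 0L) {
    if (attr$required) {
      return(failed(validation_error(attr$name, "missing-required",
        sprintf("'%s' is required and has no rows", attr$name))))
    }
    return(list(ok = TRUE, value = NULL, errors = no_errors()))
  }
  cols <- attr$columns
  errs <- no_errors()
  typed <- vector("list", length(cols))
  names(typed) <- names(cols)
  for (cn in names(cols)) typed[[cn]] <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    extra <- setdiff(names(row), names(cols))
    if (length(extra)) {
      errs <- rbind(errs, validation_error(attr$name, "bad-table-row",
        sprintf("row %d of '%s' has unknown column(s): %s",
                i, attr$name, paste(extra, collapse = ", ")), i))
    }
    for (cn in names(cols)) {
      cell_attr <- attribute_def(cn, cols[[cn]], required = FALSE)
      cell_raw <- if (cn %in% names(row)) row[[cn]] else ""
      res <- validate_value(cell_attr, cell_raw, registries)
      if (!res$ok) {
        cell_errs <- res$errors
        cell_errs$attribute <- attr$name
        cell_errs$row_index <- i
        cell_errs$message <- sprintf("row %d, column '%s': %s",
                                     i, cn, cell_errs$message)
        errs <- rbind(errs, cell_errs)
      } else if (!is.null(res$value)) { # NULL assignment would shrink the list
        typed[[cn]][[i]] <- res$value
      }
    }
  }
  if (nrow(errs)) return(failed(errs))
  out <- data.frame(row.names = seq_along(rows))
  for (cn in names(cols)) {
    vals <- typed[[cn]]
    vals[vapply(vals, is.null, logical(1))] <- list(empty_cell(cols[[cn]]))
    col <- do.call(c, vals)
    if (cols[[cn]] == "date") col <- as.Date(col, origin = "1970-01-01")
    out[[cn]] <- col
  }
  list(ok = TRUE, value = out, errors = no_errors())
}

empty_cell <- function(kind) {
  switch(kind,
    integer = NA_integer_,
    real = NA_real_,
    date = as.Date(NA),
    NA_character_
  )
}

table_rows <- function(raw) {
  if (inherits(raw, "data.frame")) {
    if (nrow(raw) == 0L) return(list())
    return(lapply(seq_len(nrow(raw)), function(i) {
      r <- raw[i, , drop = FALSE]
      stats::setNames(as.character(unlist(r, use.names = FALSE)), names(raw))
    }))
  }
  if (is.list(raw)) {
    ok <- all(vapply(raw, function(r) {
      (is.character(r) || is.list(r)) && !is.null(names(r))
    }, logical(1)))
    if (!ok) return(NULL)
    return(lapply(raw, function(r) {
      stats::setNames(vapply(r, as.character, character(1)), names(r))
    }))
  }
  NULL
}

# Render a typed payload back to its canonical text form (the form that
# validates to the same payload). Used by exports, reports and the audit log.
render_scalar <- function(value, kind = NULL) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) return("")
  if (inherits(value, "Date")) return(format(value, "%Y-%m-%d"))
  if (is.integer(value)) return(as.character(value))
  if (is.numeric(value)) {
    out <- format(value, scientific = FALSE, trim = TRUE, digits = 15)
    return(out)
  }
  as.character(value)
}
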