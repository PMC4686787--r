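#' Build a workflow definition programmatically
#'
#' A workflow definition is the single source of truth for one disease
#' protocol: the ordered activities with their typed attributes, the
#' transitions that order them, the registries backing `register` attributes,
#' and the suggestion rules. Workflows are usually read from `.xpdl` files
#' with [parse_workflow()]; these constructors exist for tests, generators
#' and programmatic authoring, and feed [serialize_workflow()].
#'
#' @param workflow_id Short token identifying the protocol.
#' @param name Display name.
#' @param activities List of [activity_def()] values, in protocol order.
#' @param transitions Data frame with columns `from`, `to` (activity ids), or
#'   a list of `c(from, to)` pairs.
#' @param registries List of [registry_def()] values.
#' @param suggestion_rules List of [suggestion_rule()] values.
#' @param version Free-text version label.
#' @return A `flux_workflow` object.
#' @export
workflow_def <- function(workflow_id, name = workflow_id, activities = list(),
                         transitions = NULL, registries = list(),
                         suggestion_rules = list(), version = "1.0") {
  if (is.list(transitions) && !is.data.frame(transitions)) {
    transitions <- if (length(transitions)) {
      data.frame(from = vapply(transitions, `[`, character(1), 1L),
                 to = vapply(transitions, `[`, character(1), 2L),
                 stringsAsFactors = FALSE)
    } else {
      NULL
    }
  }
  if (is.null(transitions)) {
    transitions <- data.frame(from = character(), to = character(),
                              stringsAsFactors = FALSE)
  }
  rownames(transitions) <- NULL
  names(activities) <- vapply(activities, function(a) a$activity_id, character(1))
  names(registries) <- vapply(registries, function(r) r$registry_name, character(1))
  structure(
    list(workflow_id = workflow_id, name = name, version = version,
         activities = activities,
         transitions = transitions[, c("from", "to"), drop = FALSE],
         registries = registries,
         suggestion_rules = suggestion_rules),
    class = "flux_workflow"
  )
}

#' @rdname workflow_def
#' @param activity_id Short token unique within the workflow.
#' @param attributes List of [attribute_def()] values, in form order.
#' @export
activity_def <- function(activity_id, name = activity_id, attributes = list()) {
  names(attributes) <- vapply(attributes, function(a) a$name, character(1))
  structure(list(activity_id = activity_id, name = name,
                 attributes = attributes),
            class = "flux_activity")
}

#' @rdname workflow_def
#' @param registry_name Registry token referenced by `register` attributes.
#' @param entries Character vector of allowed values (unique, case-preserved).
#' @param extensible May users append new entries at run time?
#' @export
registry_def <- function(registry_name, entries = character(),
                         extensible = FALSE) {
  structure(list(registry_name = registry_name,
                 entries = as.character(entries),
                 extensible = isTRUE(extensible)),
            class = "flux_registry")
}

#' @rdname workflow_def
#' @param rule_id Short token identifying the rule.
#' @param source_activity Activity whose latest values feed the condition.
#' @param condition Condition text (or `flux_formula`) over the source
#'   activity's attributes.
#' @param suggested_activities Activity ids to suggest when the condition is
#'   true, in priority order.
#' @export
suggestion_rule <- function(rule_id, source_activity, condition,
                            suggested_activities) {
  if (!inherits(condition, "flux_formula")) condition <- parse_formula(condition)
  structure(list(rule_id = rule_id, source_activity = source_activity,
                 condition = condition,
                 suggested_activities = as.character(suggested_activities)),
            class = "flux_suggestion_rule")
}

#' @export
print.flux_workflow <- function(x, ...) {
  cat(sprintf("<flux_workflow> %s (\"%s\", version %s)\n",
              x$workflow_id, x$name, x$version))
  cat(sprintf("  %d activities, %d transitions, %d registries, %d suggestion rules\n",
              length(x$activities), nrow(x$transitions),
              length(x$registries), length(x$suggestion_rules)))
  for (a in x$activities) {
    cat(sprintf("  - %s (%d attributes)\n", a$activity_id, length(a$attributes)))
  }
  invisible(x)
}

activity_ids <- function(wf) names(wf$activities)

start_activities <- function(wf) {
  setdiff(activity_ids(wf), unique(wf$transitions$to))
}

predecessors_of <- function(wf, activity_id) {
  wf$transitions$from[wf$transitions$to == activity_id]
}

# Backward transitive closure: all activities from which `activity_id` can be
# reached, excluding itself (unless it sits on a cycle).
ancestors_of <- function(wf, activity_id) {
  seen <- character()
  frontier <- predecessors_of(wf, activity_id)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(frontier, predecessors_of, wf = wf))), seen)
  }
  seen
}

reachable_from_starts <- function(wf) {
  seen <- start_activities(wf)
  frontier <- seen
  while (length(frontier)) {
    nxt <- unique(wf$transitions$to[wf$transitions$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
  }
  seen
}

lint_issue <- function(severity, code, location, message) {
  data.frame(severity = severity, code = code, location = location,
             message = message, stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(severity = character(), code = character(), location = character(),
             message = character(), stringsAsFactors = FALSE)
}

# Structural checks shared by the linter and by programmatic construction.
# Returns a lint-issue data frame; error severity means the workflow must not
# be loaded by the engine.
check_workflow <- function(wf) {
  issues <- no_issues()
  add <- function(severity, code, location, message) {
    issues <<- rbind(issues, lint_issue(severity, code, location, message))
  }
  ids <- activity_ids(wf)
  if (!length(ids)) {
    add("error", "no-activities", "package", "workflow declares no activities")
    return(issues)
  }
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    add("error", "duplicate-activity-id", paste0("activity:", d),
        sprintf("activity id '%s' is declared more than once", d))
  }
  for (a in wf$activities) {
    loc <- paste0("activity:", a$activity_id)
    if (!nzchar(a$name)) {
      add("error", "empty-activity-name", loc, "activity has an empty name")
    }
    anames <- names(a$attributes)
    for (d in unique(anames[duplicated(anames)])) {
      add("error", "duplicate-attribute-name", paste0(loc, "/attribute:", d),
          sprintf("attribute '%s' is declared twice in '%s'", d, a$activity_id))
    }
  }
  # transitions
  tr <- wf$transitions
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      loc <- sprintf("transition:%s->%s", tr$from[i], tr$to[i])
      for (endp in c(tr$from[i], tr$to[i])) {
        if (!endp %in% ids) {
          add("error", "unknown-transition-endpoint", loc,
              sprintf("transition endpoint '%s' is not an activity", endp))
        }
      }
      if (identical(tr$from[i], tr$to[i])) {
        add("error", "self-loop-transition", loc,
            sprintf("activity '%s' transitions to itself", tr$from[i]))
      }
    }
    key <- paste(tr$from, tr$to, sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      add("error", "duplicate-transition",
          sprintf("transition:%s->%s", parts[1], parts[2]),
          "transition is declared more than once")
    }
  }
  if (!length(start_activities(wf))) {
    add("error", "no-start-activity", "package",
        "every activity has an incoming transition; no start activity exists")
  }
  # registries referenced by register attributes
  for (a in wf$activities) {
    for (at in a$attributes) {
      loc <- sprintf("activity:%s/attribute:%s", a$activity_id, at$name)
      if (at$kind == "register" && !at$registry %in% names(wf$registries)) {
        add("error", "unknown-registry", loc,
            sprintf("registry '%s' is not declared in the workflow", at$registry))
      }
    }
  }
  for (r in wf$registries) {
    for (d in unique(r$entries[duplicated(r$entries)])) {
      add("error", "duplicate-registry-entry",
          paste0("registry:", r$registry_name),
          sprintf("entry '%s' appears more than once", d))
    }
  }
  # computed formulas: every referenced name must live in the same activity
  # or an ancestor; names present in both places are shadowed (warning).
  structurally_sound <- !any(issues$severity == "error")
  if (structurally_sound) {
    for (a in wf$activities) {
      anc <- ancestors_of(wf, a$activity_id)
      anc_names <- unique(unlist(lapply(wf$activities[anc],
                                        function(x) names(x$attributes))))
      own_names <- names(a$attributes)
      for (at in a$attributes) {
        if (at$kind != "computed") next
        loc <- sprintf("activity:%s/attribute:%s", a$activity_id, at$name)
        for (nm in at$formula$referenced_names) {
          if (!nm %in% c(own_names, anc_names)) {
            add("error", "unknown-formula-symbol", loc,
                sprintf("formula references '%s', which exists neither in '%s' nor in any ancestor activity",
                        nm, a$activity_id))
          } else if (nm %in% setdiff(own_names, at$name) && nm %in% anc_names) {
            add("warning", "shadowed-attribute", loc,
                sprintf("'%s' exists both in '%s' and in an ancestor; the local value shadows the ancestor",
                        nm, a$activity_id))
          }
        }
      }
    }
    # suggestion rules
    for (r in wf$suggestion_rules) {
      loc <- paste0("rule:", r$rule_id)
      if (!r$source_activity %in% ids) {
        add("error", "rule-unknown-activity", loc,
            sprintf("source activity '%s' does not exist", r$source_activity))
      } else {
        src_names <- names(wf$activities[[r$source_activity]]$attributes)
        for (nm in r$condition$referenced_names) {
          if (!nm %in% src_names) {
            add("error", "rule-foreign-symbol", loc,
                sprintf("condition references '%s', which is not an attribute of '%s'",
                        nm, r$source_activity))
          }
        }
      }
      for (s in r$suggested_activities) {
        if (!s %in% ids) {
          add("error", "rule-unknown-activity", loc,
              sprintf("suggested activity '%s' does not exist", s))
        }
      }
    }
    # reachability and join style (informational)
    unreachable <- setdiff(ids, reachable_from_starts(wf))
    for (u in unreachable) {
      add("warning", "unreachable-activity", paste0("activity:", u),
          sprintf("activity '%s' cannot be reached from any start activity", u))
    }
    for (id in ids) {
      if (length(predecessors_of(wf, id)) > 1L) {
        add("warning", "or-join-activity", paste0("activity:", id),
            sprintf("activity '%s' has several predecessors; it becomes available when ANY of them is executed",
                    id))
      }
    }
  }
  issues
}
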