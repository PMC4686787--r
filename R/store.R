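#' An audited record store
#'
#' A `flux_store` holds everything one deployment knows: loaded workflow
#' definitions, the live (possibly extended) registries, patient cases with
#' their activity executions, the users/roles/permissions tables, and an
#' append-only audit trail. It is an R environment mutated in place, so every
#' engine operation sees and records a single consistent state.
#'
#' Every mutating operation appends exactly one audit entry; denied attempts
#' are audited too (with `outcome = "denied"`), because an access-control
#' system without a record of refusals is not accountable. Entries are
#' hash-chained (SHA-256 over the entry content plus the previous hash) so
#' that any rewrite of history is detectable with [verify_audit_chain()].
#'
#' Timestamps come from the store's injectable `clock`, a zero-argument
#' function returning a `POSIXct`; tests and the synthetic generator install
#' a deterministic clock.
#'
#' @param clock Zero-argument function returning the current time.
#' @return A `flux_store` environment.
#' @export
flux_store <- function(clock = NULL) {
  st <- new.env(parent = emptyenv())
  st$workflows <- list()    # workflow_id -> flux_workflow
  st$registries <- list()   # workflow_id -> list(registry_name -> flux_registry)
  st$cases <- list()        # as.character(case_id) -> flux_case
  st$audit <- list()        # append-only
  st$users <- list()        # user_id -> list(user_id, name, role)
  st$permissions <- list()  # list of list(role, workflow_id, activity_id, rights)
  st$clock <- clock %||% function() Sys.time()
  class(st) <- c("flux_store", "environment")
  st
}

#' @export
print.flux_store <- function(x, ...) {
  cat(sprintf("<flux_store> %d workflow(s), %d case(s), %d audit entr%s, %d user(s)\n",
              length(x$workflows), length(x$cases), length(x$audit),
              if (length(x$audit) == 1) "y" else "ies", length(x$users)))
  invisible(x)
}

#' A fixed clock for reproducible stores
#'
#' Returns a clock function that starts at `origin` and advances by `step`
#' seconds on every reading, so repeated runs produce identical timestamps.
#'
#' @param origin Start time (anything `as.POSIXct` accepts).
#' @param step Seconds between consecutive readings.
#' @export
fixed_clock <- function(origin = "2024-01-01 08:00:00", step = 60) {
  t <- as.POSIXct(origin, tz = "UTC")
  n <- 0L
  function() {
    n <<- n + 1L
    t + (n - 1L) * step
  }
}

#' Load a workflow definition into a store
#'
#' Parses (and therefore lints) the definition; a document with any
#' error-severity issue is refused. Loading initializes the store's live
#' registries for that workflow from the declared entries.
#'
#' @param store A `flux_store`.
#' @param source Path/XML string, or an already-parsed `flux_workflow`.
#' @return The loaded `flux_workflow`, invisibly.
#' @export
load_workflow <- function(store, source) {
  wf <- if (inherits(source, "flux_workflow")) {
    issues <- check_workflow(source)
    if (any(issues$severity == "error")) {
      stop("workflow has error-severity lint issues:\n",
           paste(sprintf("  [%s] %s", issues$code, issues$message), collapse = "\n"))
    }
    source
  } else {
    parse_workflow(source)
  }
  store$workflows[[wf$workflow_id]] <- wf
  store$registries[[wf$workflow_id]] <- wf$registries
  invisible(wf)
}

stop_flux <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "flux_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
  stop(cond)
}

format_ts <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# -- audit ------------------------------------------------------------------

audit_append <- function(store, user, action, subject, detail = list(),
                         outcome = "ok") {
  prev_hash <- if (length(store$audit)) {
    store$audit[[length(store$audit)]]$hash
  } else {
    "genesis"
  }
  entry <- list(
    seq = length(store$audit) + 1L,
    timestamp = format_ts(store$clock()),
    user = user,
    action = action,
    subject = subject,
    detail = detail,
    outcome = outcome,
    prev_hash = prev_hash
  )
  entry$hash <- audit_entry_hash(entry)
  store$audit[[entry$seq]] <- entry
  invisible(entry)
}

audit_entry_hash <- function(entry) {
  payload <- entry[c("seq", "timestamp", "user", "action", "subject",
                     "detail", "outcome", "prev_hash")]
  digest::digest(
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null"),
    algo = "sha256", serialize = FALSE)
}

#' Verify the audit trail's hash chain
#'
#' Recomputes every entry's SHA-256 over its content and its predecessor's
#' hash. Any tampering — edited fields, deleted or reordered entries — breaks
#' the chain.
#'
#' @param store A `flux_store`.
#' @return `TRUE` if the chain verifies, otherwise `FALSE`.
#' @export
verify_audit_chain <- function(store) {
  prev <- "genesis"
  for (i in seq_along(store$audit)) {
    e <- store$audit[[i]]
    if (!identical(e$seq, i)) return(FALSE)
    if (!identical(e$prev_hash, prev)) return(FALSE)
    if (!identical(e$hash, audit_entry_hash(e))) return(FALSE)
    prev <- e$hash
  }
  TRUE
}

#' Query the audit trail
#'
#' @param store A `flux_store`.
#' @param case_id,user,action Optional filters.
#' @param caller User id of the caller; needs at least one read permission.
#' @return Data frame of entries in `seq` order (`seq`, `timestamp`, `user`,
#'   `action`, `subject`, `outcome`).
#' @export
audit_log <- function(store, case_id = NULL, user = NULL, action = NULL,
                      caller = NULL) {
  if (!is.null(caller) && !caller_has_any_read(store, caller)) {
    audit_append(store, caller, "export", "audit",
                 list(reason = "no read permission"), outcome = "denied")
    stop_flux("flux_permission_denied",
              sprintf("user '%s' has no read permission", caller))
  }
  entries <- store$audit
  keep <- vapply(entries, function(e) {
    (is.null(case_id) || identical(e$subject$case_id, as.integer(case_id))) &&
      (is.null(user) || identical(e$user, user)) &&
      (is.null(action) || identical(e$action, action))
  }, logical(1))
  entries <- entries[keep]
  data.frame(
    seq = vapply(entries, `[[`, integer(1), "seq"),
    timestamp = vapply(entries, `[[`, character(1), "timestamp"),
    user = vapply(entries, `[[`, character(1), "user"),
    action = vapply(entries, `[[`, character(1), "action"),
    subject = vapply(entries, function(e) subject_label(e$subject), character(1)),
    outcome = vapply(entries, `[[`, character(1), "outcome"),
    stringsAsFactors = FALSE
  )
}

subject_label <- function(subject) {
  if (!length(subject)) return("")
  paste(paste0(names(subject), "=", vapply(subject, function(x)
    paste(as.character(x), collapse = "+"), character(1))), collapse = " ")
}

caller_has_any_read <- function(store, caller) {
  u <- store$users[[caller]]
  if (is.null(u)) return(FALSE)
  any(vapply(store$permissions, function(p) {
    identical(p$role, u$role) && "read" %in% p$rights
  }, logical(1)))
}

# -- users and permissions --------------------------------------------------

#' Manage users, roles and permissions
#'
#' User and permission management is administrative: it is driven by the
#' deployment's configuration (or an administrator at the console), is not
#' itself permission-gated — with an empty permission table nobody could
#' bootstrap otherwise — and is always audited. Authorization for everything
#' else follows default deny: a right is granted only if some permission row
#' matches the user's role, the workflow, the activity (exactly or by the
#' `"*"` wildcard) and includes the right.
#'
#' @param store A `flux_store`.
#' @param user_id,name,role User identity fields.
#' @param actor Identity performing the administrative change (for the audit
#'   trail).
#' @export
add_user <- function(store, user_id, name = user_id, role, actor = "admin") {
  if (!is.null(store$users[[user_id]])) {
    stop_flux("flux_duplicate_user", sprintf("user '%s' already exists", user_id))
  }
  store$users[[user_id]] <- list(user_id = user_id, name = name, role = role)
  audit_append(store, actor, "create-user", list(user = user_id),
               list(role = role))
  invisible(store$users[[user_id]])
}

#' @rdname add_user
#' @param workflow_id Workflow the permission applies to (`"*"` for all).
#' @param activity_id Activity the permission applies to (`"*"` for all).
#' @param rights Character subset of `c("read", "write")`; write covers
#'   executing activities, read covers retrieving values and exporting.
#' @export
grant_permission <- function(store, role, workflow_id, activity_id = "*",
                             rights, actor = "admin") {
  stopifnot(all(rights %in% c("read", "write")))
  store$permissions[[length(store$permissions) + 1L]] <-
    list(role = role, workflow_id = workflow_id, activity_id = activity_id,
         rights = rights)
  audit_append(store, actor, "grant-permission",
               list(role = role, workflow = workflow_id, activity = activity_id),
               list(rights = rights))
  invisible(store$permissions)
}

#' Check whether a user holds a right
#'
#' @param store A `flux_store`.
#' @param user_id User to check; unknown users are denied.
#' @param workflow_id,activity_id Target of the access.
#' @param right `"read"` or `"write"`.
#' @return `TRUE` (allow) or `FALSE` (deny). Default deny: with no matching
#'   permission the answer is `FALSE`.
#' @export
check_permission <- function(store, user_id, workflow_id, activity_id, right) {
  u <- store$users[[user_id]]
  if (is.null(u)) return(FALSE)
  any(vapply(store$permissions, function(p) {
    identical(p$role, u$role) &&
      (identical(p$workflow_id, "*") || identical(p$workflow_id, workflow_id)) &&
      (identical(p$activity_id, "*") || identical(p$activity_id, activity_id)) &&
      right %in% p$rights
  }, logical(1)))
}

# TRUE if the user may write to at least one activity of the workflow;
# used for case creation, which is not tied to a single activity.
can_write_some_activity <- function(store, user_id, wf) {
  any(vapply(c("*", activity_ids(wf)), function(a) {
    check_permission(store, user_id, wf$workflow_id, a, "write")
  }, logical(1)))
}

# -- registries -------------------------------------------------------------

#' Append an entry to an extensible registry
#'
#' Registries back `register` attributes: a value entered by a user must
#' already exist in its registry. Extensible registries let a novel entry
#' (say, a treatment not yet in the pre-built list) become part of the
#' allowed vocabulary; non-extensible registries refuse. Appending an entry
#' that already exists is an audited no-op.
#'
#' @param store A `flux_store`.
#' @param workflow_id Workflow owning the registry.
#' @param registry_name Registry token.
#' @param value Entry text (must not contain `;` or `,`, which delimit the
#'   workflow file encoding).
#' @param user Acting user; needs write permission on the workflow.
#' @return The updated `flux_registry`, invisibly.
#' @export
append_registry_entry <- function(store, workflow_id, registry_name, value, user) {
  wf <- store$workflows[[workflow_id]]
  if (is.null(wf)) {
    stop_flux("flux_unknown_workflow",
              sprintf("workflow '%s' is not loaded", workflow_id))
  }
  reg <- store$registries[[workflow_id]][[registry_name]]
  if (is.null(reg)) {
    audit_append(store, user, "append-registry",
                 list(workflow = workflow_id, registry = registry_name),
                 list(value = value, reason = "unknown registry"),
                 outcome = "denied")
    stop_flux("flux_unknown_registry",
              sprintf("registry '%s' does not exist in workflow '%s'",
                      registry_name, workflow_id))
  }
  if (!can_write_some_activity(store, user, wf)) {
    audit_append(store, user, "append-registry",
                 list(workflow = workflow_id, registry = registry_name),
                 list(value = value, reason = "no write permission"),
                 outcome = "denied")
    stop_flux("flux_permission_denied",
              sprintf("user '%s' may not modify registry '%s'", user, registry_name))
  }
  if (!reg$extensible) {
    audit_append(store, user, "append-registry",
                 list(workflow = workflow_id, registry = registry_name),
                 list(value = value, reason = "registry not extensible"),
                 outcome = "denied")
    stop_flux("flux_registry_not_extensible",
              sprintf("registry '%s' is not extensible", registry_name))
  }
  if (grepl("[;,]", value)) {
    stop_flux("flux_bad_registry_value",
              "registry entries must not contain ';' or ','")
  }
  already <- value %in% reg$entries
  if (!already) {
    reg$entries <- c(reg$entries, value)
    store$registries[[workflow_id]][[registry_name]] <- reg
  }
  audit_append(store, user, "append-registry",
               list(workflow = workflow_id, registry = registry_name),
               list(value = value, noop = already))
  invisible(store$registries[[workflow_id]][[registry_name]])
}

# -- snapshot / restore -----------------------------------------------------

#' Snapshot and restore a store
#'
#' `snapshot()` writes a self-contained archive — workflows (re-serialized to
#' XPDL), live registries, cases with every execution version, users,
#' permissions and the full audit trail — as a single JSON document.
#' `restore_snapshot()` rebuilds a structurally equal store; a truncated or
#' corrupted archive fails integrity checking and produces no partial store.
#'
#' @param store A `flux_store`.
#' @param destination File path to write.
#' @return `snapshot()` returns `destination` invisibly; `restore_snapshot()`
#'   returns a new `flux_store`.
#' @export
snapshot <- function(store, destination) {
  arch <- list(
    format = "fluxcase-snapshot",
    format_version = 1L,
    workflows = lapply(store$workflows, serialize_workflow),
    registries = lapply(store$registries, function(regs) {
      lapply(regs, function(r) r[c("registry_name", "entries", "extensible")])
    }),
    cases = lapply(store$cases, case_to_archive, store = store),
    users = store$users,
    permissions = store$permissions,
    audit = store$audit
  )
  json <- jsonlite::toJSON(arch, auto_unbox = TRUE, digits = NA, null = "null")
  ok <- tryCatch({
    writeLines(json, destination, useBytes = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_flux("flux_unwritable_destination",
              sprintf("cannot write snapshot to '%s': %s",
                      destination, conditionMessage(ok)))
  }
  invisible(destination)
}

case_to_archive <- function(case, store) {
  wf <- store$workflows[[case$workflow_id]]
  list(
    case_id = case$case_id,
    workflow_id = case$workflow_id,
    created_at = case$created_at,
    executions = lapply(case$executions, function(ex) {
      list(
        activity_id = ex$activity_id,
        version = ex$version,
        executed_at = ex$executed_at,
        executed_by = ex$executed_by,
        values = archive_values(ex$values, wf$activities[[ex$activity_id]])
      )
    })
  )
}

# Values are archived as their canonical text rendering; the workflow schema
# re-types them on restore.
archive_values <- function(values, activity) {
  out <- list()
  for (nm in names(values)) {
    v <- values[[nm]]
    if (is.null(v)) next
    at <- activity$attributes[[nm]]
    if (!is.null(at) && at$kind == "table") {
      rows <- lapply(seq_len(nrow(v)), function(i) {
        cells <- lapply(names(v), function(cn) render_scalar(v[[cn]][i]))
        stats::setNames(cells, names(v))
      })
      out[[nm]] <- list(kind = "table", rows = rows)
    } else if (!is.null(at) && at$kind == "computed") {
      # keep integer/double distinction across the text round trip
      out[[nm]] <- list(kind = "computed", text = render_scalar(v),
                        real = is.double(v))
    } else {
      out[[nm]] <- list(kind = "scalar", text = render_scalar(v))
    }
  }
  out
}

#' @rdname snapshot
#' @param source Path to a snapshot file written by `snapshot()`.
#' @param clock Clock for the restored store.
#' @export
restore_snapshot <- function(source, clock = NULL) {
  arch <- tryCatch(
    jsonlite::fromJSON(source, simplifyVector = FALSE),
    error = function(e) e
  )
  if (inherits(arch, "error") ||
      !identical(arch$format, "fluxcase-snapshot")) {
    stop_flux("flux_snapshot_integrity",
              "snapshot archive is truncated or not a fluxcase snapshot")
  }
  store <- flux_store(clock = clock)
  for (wf_xml in arch$workflows) load_workflow(store, wf_xml)
  for (wf_id in names(arch$registries)) {
    store$registries[[wf_id]] <- lapply(arch$registries[[wf_id]], function(r) {
      registry_def(r$registry_name, unlist(r$entries) %||% character(),
                   extensible = isTRUE(r$extensible))
    })
  }
  for (cs in arch$cases) {
    wf <- store$workflows[[cs$workflow_id]]
    if (is.null(wf)) {
      stop_flux("flux_snapshot_integrity",
                sprintf("case %s references missing workflow '%s'",
                        cs$case_id, cs$workflow_id))
    }
    case <- list(
      case_id = as.integer(cs$case_id),
      workflow_id = cs$workflow_id,
      created_at = cs$created_at,
      executions = lapply(cs$executions, function(ex) {
        structure(
          list(
            activity_id = ex$activity_id,
            version = as.integer(ex$version),
            executed_at = ex$executed_at,
            executed_by = ex$executed_by,
            values = unarchive_values(ex$values,
                                      wf$activities[[ex$activity_id]],
                                      store$registries[[cs$workflow_id]])
          ),
          class = "flux_execution")
      })
    )
    class(case) <- "flux_case"
    store$cases[[as.character(case$case_id)]] <- case
  }
  store$users <- lapply(arch$users, function(u) u[c("user_id", "name", "role")])
  store$permissions <- lapply(arch$permissions, function(p) {
    list(role = p$role, workflow_id = p$workflow_id,
         activity_id = p$activity_id, rights = unlist(p$rights))
  })
  store$audit <- lapply(arch$audit, unarchive_audit_entry)
  if (!verify_audit_chain(store)) {
    stop_flux("flux_snapshot_integrity",
              "audit hash chain in the snapshot does not verify")
  }
  store
}

unarchive_audit_entry <- function(e) {
  if (!is.null(e$subject$case_id)) {
    e$subject$case_id <- as.integer(e$subject$case_id)
  }
  list(seq = as.integer(e$seq), timestamp = e$timestamp, user = e$user,
       action = e$action, subject = e$subject,
       detail = e$detail, outcome = e$outcome,
       prev_hash = e$prev_hash, hash = e$hash)
}

unarchive_values <- function(values, activity, registries) {
  out <- list()
  for (nm in names(values)) {
    v <- values[[nm]]
    at <- activity$attributes[[nm]]
    if (identical(v$kind, "table")) {
      rows <- lapply(v$rows, function(r) {
        stats::setNames(vapply(r, as.character, character(1)), names(r))
      })
      res <- validate_value(at, rows, registries)
    } else if (identical(v$kind, "computed") ||
               (!is.null(at) && at$kind == "computed")) {
      out[[nm]] <- if (isTRUE(v$real)) as.numeric(v$text) else retype_computed(v$text)
      next
    } else {
      res <- validate_value(at, v$text, registries)
    }
    if (!res$ok) {
      stop_flux("flux_snapshot_integrity",
                sprintf("archived value for '%s' no longer validates: %s",
                        nm, paste(res$errors$message, collapse = "; ")))
    }
    out[[nm]] <- res$value
  }
  out
}

retype_computed <- function(text) {
  if (grepl("^[+-]?[0-9]+$", text)) as.integer(text) else as.numeric(text)
}

#' Rebuild a store by replaying its audit trail
#'
#' The audit trail records every successful mutation with enough detail
#' (submitted raw values, registry appends, user grants) to reconstruct the
#' store. Replaying from an empty store is the correctness check that the
#' trail really is a complete history: every case's latest values in the
#' replayed store must equal the live store's.
#'
#' @param store The live store whose trail is replayed (workflow definitions
#'   are taken from it; loading workflows is configuration, not a mutation).
#' @param clock Clock for the replayed store.
#' @return A new `flux_store` built only from the audit trail.
#' @export
replay_audit <- function(store, clock = NULL) {
  re <- flux_store(clock = clock %||% fixed_clock())
  for (wf in store$workflows) load_workflow(re, wf)
  for (e in store$audit) {
    if (!identical(e$outcome, "ok")) next
    switch(e$action,
      "create-user" = add_user(re, e$subject$user, role = e$detail$role,
                               actor = e$user),
      "grant-permission" = grant_permission(
        re, role = e$subject$role, workflow_id = e$subject$workflow,
        activity_id = e$subject$activity,
        rights = unlist(e$detail$rights), actor = e$user),
      "create-case" = create_case(re, e$subject$workflow, user = e$user),
      "append-registry" = append_registry_entry(
        re, e$subject$workflow, e$subject$registry, e$detail$value,
        user = e$user),
      "execute-activity" = {
        raw <- replay_raw_values(e$detail$raw)
        execute_activity(re, e$subject$case_id, e$subject$activity,
                         raw, user = e$user)
      },
      NULL # export / batch-execute entries do not mutate case data
    )
  }
  re
}

replay_raw_values <- function(raw) {
  out <- list()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.list(v) && identical(v$kind, "table")) {
      out[[nm]] <- lapply(v$rows, function(r) {
        stats::setNames(vapply(r, as.character, character(1)), names(r))
      })
    } else if (is.list(v)) {
      out[[nm]] <- v$text
    } else {
      out[[nm]] <- as.character(v)
    }
  }
  out
}
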