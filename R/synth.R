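#' Generate synthetic patient cases
#'
#' Fills a store with seeded, fully reproducible synthetic cases so every
#' part of the system is testable without patient data. Values are drawn per
#' attribute kind: integers and reals uniformly within their declared bounds
#' (0..100 when unbounded), dates uniformly in 1950--2020, choice and
#' registry tokens uniformly over their domain, free text from a fixed word
#' list, and repeating tables with 0--4 rows. The values exercise types and
#' structure, not medicine: no clinical realism is claimed.
#'
#' With `invalid_fraction > 0` individual values are deliberately made
#' out-of-domain; the generator then asserts that the engine rejects the
#' whole submission, so deliberately bad data can never enter the store.
#' Attributes whose kind accepts any text are invalidated by submitting an
#' unknown extra attribute instead.
#'
#' A `simulator` user with read/write access to the workflow is created on
#' first use. The RNG state is saved and restored around the run.
#'
#' @param store A `flux_store` (use a [fixed_clock()] for byte-identical
#'   reruns).
#' @param workflow_id Id of a loaded workflow.
#' @param n_cases Number of cases to create.
#' @param seed Integer seed; equal seeds give identical stores.
#' @param completion Probability that an available activity is executed on
#'   each pass.
#' @param passes Number of passes over each case's available activities;
#'   successive passes walk the case deeper into the protocol.
#' @param invalid_fraction Probability that a generated value is deliberately
#'   invalid (for negative-path testing).
#' @return The created cases (list of `flux_case`), invisibly.
#' @export
generate_cases <- function(store, workflow_id, n_cases, seed,
                           completion = 0.8, passes = 2,
                           invalid_fraction = 0) {
  stopifnot(n_cases >= 0, completion >= 0, completion <= 1,
            invalid_fraction >= 0, invalid_fraction <= 1)
  wf <- store$workflows[[workflow_id]]
  if (is.null(wf)) {
    stop_flux("flux_unknown_workflow",
              sprintf("workflow '%s' is not loaded", workflow_id))
  }
  if (is.null(store$users[["simulator"]])) {
    add_user(store, "simulator", "Synthetic case generator",
             role = "simulator", actor = "simulator")
  }
  if (!can_write_some_activity(store, "simulator", wf)) {
    grant_permission(store, "simulator", workflow_id, "*",
                     c("read", "write"), actor = "simulator")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)

  registries <- function() store$registries[[workflow_id]]
  cases <- lapply(seq_len(n_cases), function(i) {
    create_case(store, workflow_id, user = "simulator")
  })
  for (pass in seq_len(passes)) {
    for (case in cases) {
      st <- status(store, case$case_id)
      todo <- st$activity_id[st$state == "available"]
      for (aid in todo) {
        if (stats::runif(1) > completion) next
        sub <- draw_submission(wf$activities[[aid]], registries(),
                               invalid_fraction)
        if (sub$invalid) {
          res <- tryCatch(
            execute_activity(store, case$case_id, aid, sub$raw,
                             user = "simulator"),
            flux_validation_error = function(e) e
          )
          if (!inherits(res, "flux_validation_error")) {
            stop("internal: engine accepted a deliberately invalid submission for '",
                 aid, "'")
          }
        } else {
          execute_activity(store, case$case_id, aid, sub$raw,
                           user = "simulator")
        }
      }
    }
  }
  invisible(cases)
}

SYNTH_WORDS <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                 "theta", "lambda", "sigma", "omega", "north", "south",
                 "river", "valley", "stone", "field")

draw_submission <- function(activity, registries, invalid_fraction) {
  raw <- list()
  invalid <- FALSE
  drawable <- Filter(function(a) a$kind != "computed", activity$attributes)
  for (at in drawable) {
    if (stats::runif(1) < invalid_fraction) {
      bad <- draw_invalid_raw(at)
      if (is.null(bad)) {
        # kind accepts any text: invalidate via an unknown extra attribute
        raw[[paste0(at$name, "__bogus")]] <- "deliberately invalid"
        raw[[at$name]] <- draw_valid_raw(at, registries)
      } else {
        raw[[at$name]] <- bad
      }
      invalid <- TRUE
    } else {
      raw[[at$name]] <- draw_valid_raw(at, registries)
    }
  }
  if (!length(drawable) && stats::runif(1) < invalid_fraction) {
    raw[["__bogus__"]] <- "deliberately invalid"
    invalid <- TRUE
  }
  list(raw = raw, invalid = invalid)
}

draw_valid_raw <- function(at, registries) {
  switch(at$kind,
    integer = {
      lo <- at$min %||% 0
      hi <- at$max %||% 100
      as.character(floor(stats::runif(1, lo, hi + 1)))
    },
    real = {
      lo <- at$min %||% 0
      hi <- at$max %||% 100
      format(round(stats::runif(1, lo, hi), 3), scientific = FALSE,
             trim = TRUE)
    },
    date = {
      span <- as.integer(as.Date("2020-12-31") - as.Date("1950-01-01"))
      d <- as.Date("1950-01-01") + floor(stats::runif(1, 0, span + 1))
      format(d, "%Y-%m-%d")
    },
    choice = sample(at$choices, 1L),
    register = {
      entries <- registries[[at$registry]]$entries
      if (!length(entries)) "" else sample_one(entries)
    },
    table = {
      n <- sample.int(5L, 1L) - 1L
      lapply(seq_len(n), function(i) {
        cells <- vapply(names(at$columns), function(cn) {
          draw_valid_raw(attribute_def(cn, at$columns[[cn]]), registries)
        }, character(1))
        cells
      })
    },
    # text
    paste(sample(SYNTH_WORDS, sample.int(3L, 1L), replace = TRUE),
          collapse = " ")
  )
}

sample_one <- function(x) x[[sample.int(length(x), 1L)]]

# An out-of-domain raw value for the kind, or NULL when every finite text is
# valid (free text, and registers over an empty registry for non-required).
draw_invalid_raw <- function(at) {
  switch(at$kind,
    integer = if (!is.null(at$max)) render_scalar(at$max + 1) else "not-a-number",
    real = "not-a-number",
    date = "2020-13-45",
    choice = "__not_a_choice__",
    register = "__not_registered__",
    table = {
      bad_col <- names(at$columns)[which(at$columns != "text")[1]]
      if (is.na(bad_col)) return(NULL)
      list(stats::setNames(
        vapply(names(at$columns), function(cn) {
          if (cn == bad_col) "__bad_cell__" else ""
        }, character(1)),
        names(at$columns)))
    },
    NULL
  )
}

#' Generate a random valid workflow
#'
#' Produces a seeded random workflow that lints clean: a DAG of up to
#' `n_activities` activities (edges only run forward, so a start activity
#' always exists), each with a random mix of attribute kinds, plus a
#' registry and, sometimes, computed attributes referencing an ancestor.
#' Used by the round-trip and state-machine property checks, where hundreds
#' of structurally varied workflows are worth more than three curated ones.
#'
#' @param seed Integer seed.
#' @param n_activities Number of activities (2--26).
#' @param p_edge Probability of a forward transition between any pair.
#' @return A `flux_workflow`.
#' @export
random_workflow <- function(seed, n_activities = 6, p_edge = 0.35) {
  stopifnot(n_activities >= 2, n_activities <= 26)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  ids <- paste0("act_", letters[seq_len(n_activities)])
  reg <- registry_def("lookup", c("one", "two", "three"),
                      extensible = stats::runif(1) < 0.5)
  acts <- list()
  for (i in seq_along(ids)) {
    n_attr <- sample.int(4L, 1L)
    attrs <- lapply(seq_len(n_attr), function(j) {
      nm <- sprintf("%s_f%d", ids[i], j)
      kind <- sample_one(c("integer", "real", "text", "date", "choice",
                           "register", "table"))
      switch(kind,
        integer = attribute_def(nm, "integer", min = 0, max = 50,
                                required = stats::runif(1) < 0.3),
        real = attribute_def(nm, "real", min = 0, max = 1),
        date = attribute_def(nm, "date"),
        choice = attribute_def(nm, "choice", choices = c("yes", "no", "maybe")),
        register = attribute_def(nm, "register", registry = "lookup"),
        table = attribute_def(nm, "table", columns = c(
          label = "text", amount = "integer", when = "date")),
        attribute_def(nm, "text", hint = "free text")
      )
    })
    acts[[i]] <- activity_def(ids[i], paste("Activity", toupper(letters[i])),
                              attrs)
  }
  edges <- list()
  for (i in seq_len(n_activities - 1L)) {
    for (j in (i + 1L):n_activities) {
      if (stats::runif(1) < p_edge) {
        edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
      }
    }
  }
  wf <- workflow_def(sprintf("rand_%d", seed), sprintf("Random workflow %d", seed),
                     acts, edges, registries = list(reg))
  # sometimes add a computed attribute over one of the activity's own
  # numeric fields (cross-activity references are exercised by the packaged
  # fixtures; with OR-joins a random ancestor may legitimately be unexecuted)
  for (i in seq_along(ids)) {
    if (stats::runif(1) > 0.25) next
    pool <- names(Filter(function(x) x$kind == "integer",
                         wf$activities[[ids[i]]]$attributes))
    if (length(pool) < 1L) next
    ref <- sample_one(pool)
    nm <- sprintf("%s_calc", ids[i])
    wf$activities[[ids[i]]]$attributes[[nm]] <-
      attribute_def(nm, "computed", formula = sprintf("%s * 2 + 1", ref))
  }
  stopifnot(!any(check_workflow(wf)$severity == "error"))
  wf
}
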