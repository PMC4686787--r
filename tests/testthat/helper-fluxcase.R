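# Shared fixtures and independent oracles for the suite.

# A store with a deterministic clock and a fully-permitted clinician.
make_store <- function(..., clinician = "doc") {
  st <- flux_store(clock = fixed_clock())
  add_user(st, clinician, role = "clinician")
  grant_permission(st, "clinician", "*", "*", c("read", "write"))
  for (src in list(...)) load_workflow(st, src)
  st
}

# A three-activity linear workflow small enough to reason about by hand.
linear_wf <- function(id = "lin") {
  workflow_def(id, "Linear", list(
    activity_def("a", "A", list(attribute_def("x", "integer", min = 0, max = 9))),
    activity_def("b", "B", list(attribute_def("y", "text"))),
    activity_def("c", "C", list(attribute_def("z", "real", min = 0, max = 1)))
  ), list(c("a", "b"), c("b", "c")))
}

# Independent state oracle: recomputes every activity's state from nothing
# but the execution set and the raw transition list.
oracle_status <- function(wf, executed) {
  ids <- names(wf$activities)
  state <- vapply(ids, function(id) {
    if (id %in% executed) return("executed")
    preds <- wf$transitions$from[wf$transitions$to == id]
    if (length(preds) == 0L || any(preds %in% executed)) "available" else "locked"
  }, character(1))
  data.frame(activity_id = ids, state = unname(state), stringsAsFactors = FALSE)
}

executed_ids <- function(store, case_id) {
  case <- store$cases[[as.character(case_id)]]
  unique(vapply(case$executions, `[[`, character(1), "activity_id"))
}

# Independent completed-years oracle: count anniversaries of `from` that
# have occurred on or before `to`, by explicit anniversary construction.
oracle_years_between <- function(to, from) {
  if (to < from) return(-oracle_years_between(from, to))
  y0 <- as.integer(format(from, "%Y"))
  md <- format(from, "-%m-%d")
  k <- 0L
  repeat {
    anniv <- as.Date(paste0(y0 + k + 1L, md))
    if (is.na(anniv) || anniv > to) break
    k <- k + 1L
  }
  k
}

# Draw a valid submission for an activity (delegates to the generator's
# value drawing, which is seeded by the caller).
valid_submission <- function(wf, activity_id, registries) {
  draw_submission(wf$activities[[activity_id]], registries, 0)$raw
}

random_string <- function(max_len = 12L) {
  pool <- c(letters, LETTERS, 0:9, "-", ".", "+", " ", "/", ";", "'", "é")
  n <- sample.int(max_len + 1L, 1L) - 1L
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

fuzz_attribute_set <- function() {
  list(
    integer = attribute_def("f", "integer", min = -5, max = 120),
    real = attribute_def("f", "real", min = 0, max = 10),
    text = attribute_def("f", "text", required = TRUE),
    date = attribute_def("f", "date"),
    choice = attribute_def("f", "choice", choices = c("present", "absent")),
    register = attribute_def("f", "register", registry = "lookup"),
    table = attribute_def("f", "table",
                          columns = c(who = "text", amount = "integer",
                                      when = "date"))
  )
}

fuzz_registries <- list(lookup = registry_def("lookup",
                                              c("Itraconazole", "Fluconazole")))

# Run validate_value over n random raw strings for every kind; returns the
# number of calls that raised instead of returning a value/errors.
fuzz_validate <- function(n, seed) {
  set.seed(seed)
  attrs <- fuzz_attribute_set()
  crashes <- 0L
  for (i in seq_len(n)) {
    raw <- random_string()
    for (at in attrs) {
      res <- tryCatch(validate_value(at, raw, fuzz_registries),
                      error = function(e) e)
      if (inherits(res, "error")) crashes <- crashes + 1L
      # a table attribute must also survive structured row input
      if (at$kind == "table" && i %% 10 == 0) {
        row <- list(c(who = random_string(), amount = random_string(),
                      when = random_string()))
        res2 <- tryCatch(validate_value(at, row, fuzz_registries),
                         error = function(e) e)
        if (inherits(res2, "error")) crashes <- crashes + 1L
      }
    }
  }
  crashes
}
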