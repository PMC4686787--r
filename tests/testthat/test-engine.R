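test_that("case identifiers are generated sequentially and uniquely", {
  st <- make_store(linear_wf())
  c1 <- create_case(st, "lin", user = "doc")
  c2 <- create_case(st, "lin", user = "doc")
  c3 <- create_case(st, "lin", user = "doc")
  expect_identical(c(c1$case_id, c2$case_id, c3$case_id), c(1L, 2L, 3L))
  expect_length(unique(names(st$cases)), 3)
  expect_error(create_case(st, "nope", user = "doc"),
               class = "flux_unknown_workflow")
})

test_that("availability follows the start/predecessor rule", {
  st <- make_store(linear_wf())
  case <- create_case(st, "lin", user = "doc")
  expect_identical(status(st, 1)$state, c("available", "locked", "locked"))
  execute_activity(st, 1, "a", list(x = "3"), user = "doc")
  expect_identical(status(st, 1)$state, c("executed", "available", "locked"))
  execute_activity(st, 1, "b", list(y = "hi"), user = "doc")
  expect_identical(status(st, 1)$state, c("executed", "executed", "available"))
})

test_that("branches leave the choice of path to the user (OR semantics)", {
  wf <- workflow_def("br", "Branch", list(
    activity_def("a", "A"), activity_def("b", "B"),
    activity_def("c", "C"), activity_def("d", "D")
  ), list(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "d")))
  st <- make_store(wf)
  create_case(st, "br", user = "doc")
  execute_activity(st, 1, "a", list(), user = "doc")
  stt <- status(st, 1)
  expect_identical(stt$state[stt$activity_id %in% c("b", "c")],
                   c("available", "available"))
  # one branch suffices for the join to open
  execute_activity(st, 1, "c", list(), user = "doc")
  stt <- status(st, 1)
  expect_identical(stt$state[stt$activity_id == "d"], "available")
})

test_that("locked activities cannot be executed and leave no trace", {
  st <- make_store(linear_wf())
  create_case(st, "lin", user = "doc")
  n_audit <- length(st$audit)
  expect_error(execute_activity(st, 1, "c", list(z = "0.5"), user = "doc"),
               class = "flux_activity_locked")
  expect_length(st$cases[["1"]]$executions, 0)
  expect_length(st$audit, n_audit)
})

test_that("validation failures store nothing and carry every error", {
  st <- make_store(linear_wf())
  create_case(st, "lin", user = "doc")
  err <- tryCatch(
    execute_activity(st, 1, "a", list(x = "99", bogus = "1"), user = "doc"),
    error = function(e) e)
  expect_s3_class(err, "flux_validation_error")
  expect_setequal(err$errors$code, c("out-of-range", "unknown-attribute"))
  expect_length(st$cases[["1"]]$executions, 0)
  # computed attributes cannot be supplied by hand
  st2 <- make_store(flux_fixture("ald"))
  create_case(st2, "ald", user = "doc")
  err <- tryCatch(
    execute_activity(st2, 1, "diagnosis_information",
                     list(patient_initials = "J", birth_date = "1980-01-01",
                          age_at_first_symptom = "7"),
                     user = "doc"),
    error = function(e) e)
  expect_true("unknown-attribute" %in% err$errors$code)
})

test_that("re-execution is versioned and history stays retrievable", {
  st <- make_store(linear_wf())
  create_case(st, "lin", user = "doc")
  e1 <- execute_activity(st, 1, "a", list(x = "3"), user = "doc")
  e2 <- execute_activity(st, 1, "a", list(x = "7"), user = "doc")
  expect_identical(c(e1$version, e2$version), c(1L, 2L))
  expect_identical(latest_values(st, 1, "a")$x, 7L)
  versions <- vapply(st$cases[["1"]]$executions, `[[`, integer(1), "version")
  expect_identical(versions, c(1L, 2L))
  expect_identical(st$cases[["1"]]$executions[[1]]$values$x, 3L)
  expect_error(latest_values(st, 1, "b"), class = "flux_never_executed")
})

test_that("computed attributes evaluate over ancestors with local shadowing", {
  wf <- workflow_def("cmp", "Computed", list(
    activity_def("intake", "Intake", list(
      attribute_def("birth_date", "date", required = TRUE),
      attribute_def("weight", "real", min = 0, max = 500))),
    activity_def("visit", "Visit", list(
      attribute_def("visit_date", "date", required = TRUE),
      attribute_def("weight", "real", min = 0, max = 500),
      attribute_def("age", "computed",
                    formula = "years_between(visit_date, birth_date)"),
      attribute_def("double_weight", "computed", formula = "weight * 2")))
  ), list(c("intake", "visit")))
  st <- make_store(wf)
  create_case(st, "cmp", user = "doc")
  execute_activity(st, 1, "intake",
                   list(birth_date = "1980-06-01", weight = "70"),
                   user = "doc")
  ex <- execute_activity(st, 1, "visit",
                         list(visit_date = "2010-06-01", weight = "80"),
                         user = "doc")
  expect_identical(ex$values$age, 30L)
  expect_identical(ex$values$double_weight, 160) # local weight shadows intake
  # recomputing from stored inputs reproduces the stored value exactly
  ctx <- c(latest_values(st, 1, "intake"), latest_values(st, 1, "visit"))
  f <- wf$activities$visit$attributes$age$formula
  expect_identical(evaluate_formula(f, ctx), ex$values$age)
})

test_that("suggestions follow executed sources, rule order and availability", {
  st <- make_store(flux_fixture("ald"))
  create_case(st, "ald", user = "doc")
  expect_identical(suggest_next(st, 1), character()) # nothing executed
  execute_activity(st, 1, "diagnosis_information",
                   list(patient_initials = "J.S.", birth_date = "1980-06-01"),
                   user = "doc")
  execute_activity(st, 1, "treatment", list(treatment = "Dietary therapy"),
                   user = "doc")
  execute_activity(st, 1, "symptoms", list(symptom = "Fatigue"), user = "doc")
  execute_activity(st, 1, "clinical_evolution",
                   list(visit_date = "2011-05-01", vlcfa_level = "2.4"),
                   user = "doc")
  expect_identical(suggest_next(st, 1),
                   c("mri_encephalon", "adrenal_function_test"))
  # an executed activity is filtered from the suggestions
  execute_activity(st, 1, "mri_encephalon",
                   list(loes_score = "5", result = "abnormal"), user = "doc")
  expect_identical(suggest_next(st, 1), "adrenal_function_test")
  # a false condition suggests nothing
  execute_activity(st, 1, "adrenal_function_test",
                   list(cortisol_basal = "20", acth = "40"), user = "doc")
  expect_identical(suggest_next(st, 1), character())
})

test_that("engine availability matches the brute-force oracle on random runs", {
  set.seed(99)
  for (trial in 1:50) {
    wf <- random_workflow(1000 + trial, n_activities = 2 + (trial %% 11))
    st <- make_store(wf)
    create_case(st, wf$workflow_id, user = "doc")
    for (step in 1:8) {
      stt <- status(st, 1)
      open <- stt$activity_id[stt$state != "locked"]
      if (!length(open)) break
      aid <- sample(open, 1)
      raw <- valid_submission(wf, aid, st$registries[[wf$workflow_id]])
      execute_activity(st, 1, aid, raw, user = "doc")
      expect_identical(status(st, 1), oracle_status(wf, executed_ids(st, 1)),
                       info = sprintf("trial %d step %d", trial, step))
    }
  }
})

test_that("the executed set grows monotonically and stored values re-validate", {
  set.seed(123)
  wf <- random_workflow(77, n_activities = 8)
  st <- make_store(wf)
  create_case(st, wf$workflow_id, user = "doc")
  prev_done <- character()
  for (step in 1:12) {
    stt <- status(st, 1)
    open <- stt$activity_id[stt$state != "locked"]
    aid <- sample(open, 1)
    raw <- valid_submission(wf, aid, st$registries[[wf$workflow_id]])
    # mix in failing submissions; they must not disturb the store
    if (step %% 3 == 0) {
      try(execute_activity(st, 1, aid, c(raw, list(nonsense = "1")),
                           user = "doc"), silent = TRUE)
    }
    execute_activity(st, 1, aid, raw, user = "doc")
    done <- executed_ids(st, 1)
    expect_true(all(prev_done %in% done))
    prev_done <- done
  }
  # every stored value re-validates against its definition
  regs <- st$registries[[wf$workflow_id]]
  for (ex in st$cases[["1"]]$executions) {
    acts <- wf$activities[[ex$activity_id]]$attributes
    for (nm in names(ex$values)) {
      at <- acts[[nm]]
      if (at$kind == "computed") next
      rendered <- if (at$kind == "table") {
        df <- ex$values[[nm]]
        lapply(seq_len(nrow(df)), function(i) {
          vapply(names(df), function(cn) render_scalar(df[[cn]][i]),
                 character(1))
        })
      } else {
        render_scalar(ex$values[[nm]])
      }
      res <- validate_value(at, rendered, regs)
      expect_true(res$ok, info = nm)
      expect_equal(res$value, ex$values[[nm]], info = nm)
    }
  }
})
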