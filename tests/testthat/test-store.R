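test_that("extensible registries accept appends; others refuse", {
  st <- make_store(flux_fixture("ald"))
  reg <- append_registry_entry(st, "ald", "treatments", "Gene therapy", "doc")
  expect_true("Gene therapy" %in% reg$entries)
  n <- length(reg$entries)
  # idempotent on duplicates, but the attempt is audited
  n_audit <- length(st$audit)
  reg <- append_registry_entry(st, "ald", "treatments", "Gene therapy", "doc")
  expect_length(reg$entries, n)
  expect_length(st$audit, n_audit + 1)
  expect_true(isTRUE(st$audit[[length(st$audit)]]$detail$noop))
  # the appended entry is immediately valid for register attributes
  create_case(st, "ald", user = "doc")
  execute_activity(st, 1, "diagnosis_information",
                   list(patient_initials = "A", birth_date = "2000-01-01"),
                   user = "doc")
  ex <- execute_activity(st, 1, "treatment", list(treatment = "Gene therapy"),
                         user = "doc")
  expect_identical(ex$values$treatment, "Gene therapy")
})

test_that("non-extensible registries and unknown registries refuse appends", {
  st <- make_store(flux_fixture("nmo"))
  expect_error(append_registry_entry(st, "nmo", "doctors", "Dr. New", "doc"),
               class = "flux_registry_not_extensible")
  expect_error(append_registry_entry(st, "nmo", "ghost", "x", "doc"),
               class = "flux_unknown_registry")
  # the refusals were audited as denied
  denied <- Filter(function(e) e$outcome == "denied", st$audit)
  expect_length(denied, 2)
})

test_that("permissions default to deny and separate read from write", {
  st <- flux_store(clock = fixed_clock())
  load_workflow(st, linear_wf())
  # empty permission table: every check denies
  expect_false(check_permission(st, "nobody", "lin", "a", "read"))
  add_user(st, "reader", role = "analyst")
  add_user(st, "writer", role = "clinician")
  expect_false(check_permission(st, "reader", "lin", "a", "read"))
  grant_permission(st, "analyst", "lin", "*", "read")
  grant_permission(st, "clinician", "lin", "b", c("read", "write"))
  # wildcard covers every activity for the granted right only
  expect_true(all(vapply(c("a", "b", "c"), function(a)
    check_permission(st, "reader", "lin", a, "read"), logical(1))))
  expect_false(check_permission(st, "reader", "lin", "a", "write"))
  # exact-activity write does not bleed to other activities
  expect_true(check_permission(st, "writer", "lin", "b", "write"))
  expect_false(check_permission(st, "writer", "lin", "a", "write"))
  # engine enforcement: read-only users cannot execute but can retrieve
  create_case_denied <- tryCatch(create_case(st, "lin", user = "reader"),
                                 error = function(e) e)
  expect_s3_class(create_case_denied, "flux_permission_denied")
  create_case(st, "lin", user = "writer") # has write on b
  expect_error(execute_activity(st, 1, "a", list(x = "1"), user = "reader"),
               class = "flux_permission_denied")
})

test_that("every successful mutation appends exactly one audit entry", {
  st <- flux_store(clock = fixed_clock())
  load_workflow(st, linear_wf())          # configuration, not a mutation
  n0 <- length(st$audit)
  expect_identical(n0, 0L)
  add_user(st, "doc", role = "clinician")            # +1
  grant_permission(st, "clinician", "*", "*", c("read", "write")) # +1
  create_case(st, "lin", user = "doc")               # +1
  execute_activity(st, 1, "a", list(x = "5"), user = "doc") # +1
  expect_length(st$audit, 4)
  # failed validation appends nothing
  try(execute_activity(st, 1, "a", list(x = "99"), user = "doc"), silent = TRUE)
  expect_length(st$audit, 4)
  # seqs are 1..n with no gaps
  expect_identical(vapply(st$audit, `[[`, integer(1), "seq"), 1:4)
})

test_that("the audit log filters by case, user and action in seq order", {
  st <- make_store(linear_wf())
  create_case(st, "lin", user = "doc")
  execute_activity(st, 1, "a", list(x = "5"), user = "doc")
  execute_activity(st, 1, "b", list(y = "t"), user = "doc")
  log <- audit_log(st)
  expect_identical(log$seq, seq_len(nrow(log)))
  expect_identical(sum(log$action == "execute-activity"), 2L)
  by_case <- audit_log(st, case_id = 1)
  expect_true(all(grepl("case_id=1", by_case$subject)))
  expect_identical(nrow(audit_log(st, action = "create-case")), 1L)
  expect_identical(nrow(audit_log(st, user = "ghost")), 0L)
  # an empty store has an empty log
  expect_identical(nrow(audit_log(flux_store())), 0L)
  # permission-gated access
  add_user(st, "outsider", role = "none")
  expect_error(audit_log(st, caller = "outsider"),
               class = "flux_permission_denied")
  expect_gt(nrow(audit_log(st, caller = "doc")), 0)
})

test_that("the hash chain detects any tampering", {
  st <- make_store(linear_wf())
  create_case(st, "lin", user = "doc")
  execute_activity(st, 1, "a", list(x = "5"), user = "doc")
  expect_true(verify_audit_chain(st))
  tampered <- make_store(linear_wf())
  create_case(tampered, "lin", user = "doc")
  execute_activity(tampered, 1, "a", list(x = "5"), user = "doc")
  tampered$audit[[3]]$user <- "mallory"
  expect_false(verify_audit_chain(tampered))
  # deleting an entry breaks the chain too
  st$audit <- st$audit[-3]
  expect_false(verify_audit_chain(st))
})

test_that("snapshot and restore reproduce the store; truncation is refused", {
  st <- make_store(flux_fixture("nmo"))
  generate_cases(st, "nmo", n_cases = 5, seed = 3, passes = 4)
  path <- withr::local_tempfile(fileext = ".json")
  snapshot(st, path)
  st2 <- restore_snapshot(path)
  expect_identical(names(st2$cases), names(st$cases))
  expect_equal(st2$cases, st$cases)
  expect_equal(st2$users, st$users)
  expect_equal(st2$permissions, st$permissions)
  expect_equal(st2$registries, st$registries)
  expect_length(st2$audit, length(st$audit))
  expect_true(verify_audit_chain(st2))
  # the restored store exports byte-identically
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  export_cases(st, "nmo", "csv-long", f1, user = "simulator")
  export_cases(st2, "nmo", "csv-long", f2, user = "simulator")
  expect_identical(readLines(f1), readLines(f2))
  # empty store round-trips
  p0 <- withr::local_tempfile(fileext = ".json")
  snapshot(flux_store(), p0)
  st0 <- restore_snapshot(p0)
  expect_length(st0$cases, 0)
  # a truncated archive is refused outright
  full <- readChar(path, file.size(path))
  trunc_path <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(full, 1, nchar(full) %/% 2), trunc_path)
  expect_error(restore_snapshot(trunc_path), class = "flux_snapshot_integrity")
})

test_that("replaying the audit trail from empty reproduces all latest values", {
  st <- make_store(flux_fixture("ald"))
  generate_cases(st, "ald", n_cases = 6, seed = 9, passes = 4,
                 invalid_fraction = 0.15)
  append_registry_entry(st, "ald", "symptoms", "Numbness", "doc")
  re <- replay_audit(st)
  expect_identical(names(re$cases), names(st$cases))
  for (cid in names(st$cases)) {
    for (aid in executed_ids(st, cid)) {
      expect_equal(latest_values(re, cid, aid), latest_values(st, cid, aid),
                   info = paste(cid, aid))
    }
  }
  expect_identical(re$registries$ald$symptoms$entries,
                   st$registries$ald$symptoms$entries)
})
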