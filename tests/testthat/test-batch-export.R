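write_batch <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("case_id,activity,attribute,row_index,column,value", lines), f)
  f
}

test_that("a batch file with valid groups equals the same manual executions", {
  st <- make_store(linear_wf())
  create_case(st, "lin", user = "doc")
  create_case(st, "lin", user = "doc")
  f <- write_batch(c("1,a,x,0,,3", "2,a,x,0,,7"))
  summ <- batch_execute(st, "lin", f, user = "doc")
  expect_identical(summ$status, c("ok", "ok"))
  # equivalent manual path
  st2 <- make_store(linear_wf())
  create_case(st2, "lin", user = "doc")
  create_case(st2, "lin", user = "doc")
  execute_activity(st2, 1, "a", list(x = "3"), user = "doc")
  execute_activity(st2, 2, "a", list(x = "7"), user = "doc")
  expect_equal(latest_values(st, 1, "a"), latest_values(st2, 1, "a"))
  expect_equal(latest_values(st, 2, "a"), latest_values(st2, 2, "a"))
})

test_that("groups are independent: one failure does not block the rest", {
  st <- make_store(linear_wf())
  create_case(st, "lin", user = "doc")
  create_case(st, "lin", user = "doc")
  f <- write_batch(c("1,a,x,0,,3", "2,a,x,0,,99")) # 99 out of range
  summ <- batch_execute(st, "lin", f, user = "doc")
  expect_identical(summ$status, c("ok", "error"))
  expect_match(summ$message[2], "out-of-range")
  expect_length(st$cases[["1"]]$executions, 1)
  expect_length(st$cases[["2"]]$executions, 0)
})

test_that("an empty batch file does nothing; malformed rows are reported", {
  st <- make_store(linear_wf())
  f <- write_batch(character())
  summ <- batch_execute(st, "lin", f, user = "doc")
  expect_identical(nrow(summ), 0L)
  f <- write_batch(c("one,a,x,0,,3"))
  summ <- batch_execute(st, "lin", f, user = "doc")
  expect_identical(summ$status, "error")
  expect_match(summ$message, "line 2")
  # a batch-level audit entry exists even for empty runs
  expect_true(any(vapply(st$audit, function(e) e$action == "batch-execute",
                         logical(1))))
})

test_that("batch rows can populate repeating tables and create dense new cases", {
  st <- make_store(flux_fixture("nmo"))
  f <- write_batch(c(
    '1,identification,name,0,,"Doe, Jane"',
    "1,identification,birth_date,0,,1980-06-01",
    "1,identification,first_evaluation_date,0,,2010-01-05",
    "1,clinical_history,summary,0,,stable",
    "1,family_history,relatives,1,relative,mother",
    "1,family_history,relatives,1,condition,NMO",
    "1,family_history,relatives,1,onset_year,1999",
    "1,family_history,relatives,2,relative,uncle",
    "1,family_history,relatives,2,condition,none",
    "1,family_history,relatives,2,onset_year,"))
  summ <- batch_execute(st, "nmo", f, user = "doc")
  expect_identical(summ$status, rep("ok", 3))
  tab <- latest_values(st, 1, "family_history")$relatives
  expect_equal(nrow(tab), 2)
  expect_identical(tab$relative, c("mother", "uncle"))
  expect_identical(latest_values(st, 1, "identification")$name, "Doe, Jane")
  # a sparse new case id is refused as a group error
  f2 <- write_batch(c("9,identification,name,0,,X"))
  summ2 <- batch_execute(st, "nmo", f2, user = "doc")
  expect_identical(summ2$status, "error")
  expect_match(summ2$message, "cannot be created")
})

test_that("long export counts one row per scalar value or table cell", {
  st <- make_store(flux_fixture("nmo"))
  create_case(st, "nmo", user = "doc")
  execute_activity(st, 1, "identification",
                   list(name = "J", birth_date = "1980-06-01",
                        first_evaluation_date = "2010-01-05", age = "35"),
                   user = "doc")
  execute_activity(st, 1, "clinical_history", list(summary = "s"), user = "doc")
  execute_activity(st, 1, "family_history", list(relatives = list(
    c(relative = "mother", condition = "NMO", onset_year = "1999"),
    c(relative = "aunt", condition = "none", onset_year = "2001"))),
    user = "doc")
  f <- withr::local_tempfile()
  tab <- export_cases(st, "nmo", "csv-long", f, user = "doc")
  # 4 + 1 scalars, plus 2 rows x 3 columns of table cells
  expect_identical(nrow(tab), 4L + 1L + 6L)
  expect_identical(readLines(f)[1],
                   "case_id,activity,version,attribute,row_index,column,value")
  expect_identical(length(readLines(f)), nrow(tab) + 1L)
})

test_that("wide export qualifies columns and excludes repeating tables", {
  st <- make_store(linear_wf())
  create_case(st, "lin", user = "doc")
  execute_activity(st, 1, "a", list(x = "5"), user = "doc")
  execute_activity(st, 1, "b", list(y = "hello, world"), user = "doc")
  f <- withr::local_tempfile()
  tab <- export_cases(st, "lin", "csv-wide", f, user = "doc")
  expect_identical(names(tab),
                   c("case_id", "activity", "version", "a.x", "b.y", "c.z"))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$a.x, c("5", ""))
  # quoting survives a read back
  back <- utils::read.csv(f, check.names = FALSE, colClasses = "character")
  expect_identical(back$`b.y`, c("", "hello, world"))
  # tables never appear among wide columns
  st2 <- make_store(flux_fixture("nmo"))
  f2 <- withr::local_tempfile()
  tab2 <- export_cases(st2, "nmo", "csv-wide", f2, user = "doc")
  expect_false(any(grepl("relatives", names(tab2))))
})

test_that("ARFF export parses with an independent reader, nominals in order", {
  st <- make_store(flux_fixture("ald"))
  generate_cases(st, "ald", n_cases = 4, seed = 21, passes = 4)
  f <- withr::local_tempfile(fileext = ".arff")
  export_cases(st, "ald", "arff", f, user = "doc")
  hdr <- readLines(f)
  # nominal domains are declared in choice/registry order
  expect_match(grep("symptoms.severity", hdr, value = TRUE),
               "{mild,moderate,severe}", fixed = TRUE)
  expect_match(grep("^@attribute treatment.treatment ", hdr, value = TRUE),
               "{\"Lorenzo's oil\",'Corticosteroid replacement',", fixed = TRUE)
  expect_true(any(grepl("date \"yyyy-MM-dd\"", hdr, fixed = TRUE)))
  # an independent ARFF reader accepts the file and types the columns
  arff <- foreign::read.arff(f)
  expect_true(nrow(arff) > 0)
  expect_true(all(c("case_id", "activity", "version") %in% names(arff)))
  expect_true(is.numeric(arff$`clinical_evolution.vlcfa_level`))
  sev <- arff$`symptoms.severity`
  expect_true(all(sev[!is.na(sev)] %in% c("mild", "moderate", "severe")))
  treat <- as.character(arff$`treatment.treatment`)
  expect_true(all(treat[!is.na(treat)] %in%
                    st$registries$ald$treatments$entries))
})

test_that("csv-long export re-imports into a fresh store losslessly", {
  st <- make_store(flux_fixture("ald"))
  generate_cases(st, "ald", n_cases = 5, seed = 13, passes = 4)
  f1 <- withr::local_tempfile()
  export_cases(st, "ald", "csv-long", f1, user = "doc")
  st2 <- make_store(flux_fixture("ald"))
  summ <- batch_execute(st2, "ald", f1, user = "doc")
  expect_true(all(summ$status == "ok"))
  f2 <- withr::local_tempfile()
  export_cases(st2, "ald", "csv-long", f2, user = "doc")
  strip_version <- function(l) sub("^(([^,]*,){2})[^,]*", "\\11", l)
  expect_identical(strip_version(readLines(f2)), strip_version(readLines(f1)))
})

test_that("export requires read permission on every activity", {
  st <- flux_store(clock = fixed_clock())
  load_workflow(st, linear_wf())
  add_user(st, "writer", role = "w")
  grant_permission(st, "w", "lin", "*", "write")
  f <- withr::local_tempfile()
  expect_error(export_cases(st, "lin", "csv-long", f, user = "writer"),
               class = "flux_permission_denied")
  denied <- st$audit[[length(st$audit)]]
  expect_identical(denied$outcome, "denied")
})

test_that("case reports are deterministic and ordered by workflow", {
  st <- make_store(flux_fixture("nmo"))
  create_case(st, "nmo", user = "doc")
  rep0 <- case_report(st, 1)
  expect_match(rep0, "Case 1")
  expect_false(grepl("by doc", rep0)) # fresh case: header, no sections
  execute_activity(st, 1, "identification",
                   list(name = "J", birth_date = "1980-06-01",
                        first_evaluation_date = "2010-01-05"), user = "doc")
  execute_activity(st, 1, "clinical_history", list(summary = "s"), user = "doc")
  rep1 <- case_report(st, 1)
  expect_lt(regexpr("Identification", rep1),
            regexpr("Clinical History", rep1))
  # hints are guidance, not data: they never appear
  expect_false(grepl("Full patient name", rep1))
  expect_identical(rep1, case_report(st, 1))
  expect_error(case_report(st, 99), class = "flux_unknown_case")
})
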