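minimal_doc <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<Package Id="mini" Name="Minimal" xmlns="http://www.wfmc.org/2008/XPDL2.2">',
    '<WorkflowProcesses><WorkflowProcess Id="p" Name="P">',
    '<Activities><Activity Id="only" Name="Only"/></Activities>',
    '<Transitions/>',
    '</WorkflowProcess></WorkflowProcesses></Package>')
}

test_that("packaged fixtures parse with their documented structure", {
  nmo <- parse_workflow(flux_fixture("nmo"))
  expect_length(nmo$activities, 16)
  ald <- parse_workflow(flux_fixture("ald"))
  expect_length(ald$activities, 9)
  # document order is preserved
  expect_identical(names(nmo$activities)[1:3],
                   c("identification", "clinical_history", "family_history"))
  expect_identical(names(ald$activities)[1], "diagnosis_information")
  # attribute order within an activity follows the document
  expect_identical(names(nmo$activities$identification$attributes)[1:2],
                   c("name", "birth_date"))
})

test_that("a minimal one-activity document parses", {
  wf <- parse_workflow(minimal_doc())
  expect_length(wf$activities, 1)
  expect_equal(nrow(wf$transitions), 0)
})

test_that("structural violations raise structured parse errors", {
  bad_tr <- sub("<Transitions/>",
                '<Transitions><Transition Id="t" From="only" To="ghost"/></Transitions>',
                minimal_doc())
  err <- tryCatch(parse_workflow(bad_tr), error = function(e) e)
  expect_s3_class(err, "flux_parse_error")
  expect_true("unknown-transition-endpoint" %in% err$issues$code)
  expect_match(grep("unknown-transition", conditionMessage(err), value = TRUE),
               "ghost")

  expect_error(parse_workflow("<Package Id='x'"), class = "flux_parse_error")

  bad_kind <- sub("/>",
                  '><ExtendedAttributes><ExtendedAttribute Name="FLUX_FIELD" Value="NAME=x;KIND=percentage"/></ExtendedAttributes></Activity>',
                  sub('<Activity Id="only" Name="Only"/>',
                      '<Activity Id="only" Name="Only"/>', minimal_doc()))
  bad_kind <- sub('<Activity Id="only" Name="Only"/>',
                  paste0('<Activity Id="only" Name="Only"><ExtendedAttributes>',
                         '<ExtendedAttribute Name="FLUX_FIELD" Value="NAME=x;KIND=percentage"/>',
                         '</ExtendedAttributes></Activity>'), minimal_doc())
  err <- tryCatch(parse_workflow(bad_kind), error = function(e) e)
  expect_true("unknown-kind" %in% err$issues$code)
})

test_that("the linter reports issues as data and agrees with the parser", {
  for (f in c("nmo", "pcm", "ald")) {
    issues <- lint_workflow(flux_fixture(f))
    expect_equal(sum(issues$severity == "error"), 0, info = f)
  }
  # activities only reachable through a cycle are flagged, as a warning
  doc <- workflow_def("w", "W", list(
    activity_def("a", "A"), activity_def("b", "B"), activity_def("c", "C")
  ), list(c("b", "c"), c("c", "b")))
  issues <- lint_workflow(serialize_workflow(doc))
  expect_true(any(issues$code == "unreachable-activity" &
                    issues$severity == "warning"))
  expect_no_error(parse_workflow(serialize_workflow(doc)))

  # computed attribute referencing an undefined name is an error
  bad <- workflow_def("w", "W", list(
    activity_def("a", "A", list(
      attribute_def("calc", "computed", formula = "nothing * 2")))
  ))
  issues <- lint_workflow(serialize_workflow(bad))
  expect_true(any(issues$code == "unknown-formula-symbol" &
                    issues$severity == "error"))
  expect_error(parse_workflow(serialize_workflow(bad)),
               class = "flux_parse_error")
})

test_that("linter soundness: rejected documents always carry an error issue", {
  variants <- list(
    "not xml at all <",
    sub('Id="mini"', "", minimal_doc()),                       # no workflow id
    sub("<Activities>.*</Activities>", "<Activities/>", minimal_doc()),
    sub('To="b"', 'To="a"',
        sub("<Transitions/>",
            '<Transitions><Transition From="only" To="only"/></Transitions>',
            minimal_doc()))                                    # self loop
  )
  for (v in variants) {
    rejected <- inherits(tryCatch(parse_workflow(v), error = function(e) e),
                         "flux_parse_error")
    issues <- lint_workflow(v)
    expect_true(rejected, info = substr(v, 1, 40))
    expect_gt(sum(issues$severity == "error"), 0)
  }
})

test_that("parse then serialize is the identity on fixtures and random workflows", {
  for (f in c("nmo", "pcm", "ald")) {
    wf <- parse_workflow(flux_fixture(f))
    expect_equal(parse_workflow(serialize_workflow(wf)), wf, info = f)
  }
  for (seed in 1:25) {
    wf <- random_workflow(seed, n_activities = 2 + (seed %% 9))
    expect_equal(parse_workflow(serialize_workflow(wf)), wf,
                 info = paste("seed", seed))
  }
  # empty-transition workflow round-trips
  wf <- workflow_def("solo", "Solo", list(activity_def("a", "A")))
  expect_equal(parse_workflow(serialize_workflow(wf)), wf)
  # table column order survives
  wf <- workflow_def("tab", "Tab", list(activity_def("a", "A", list(
    attribute_def("t", "table",
                  columns = c(z_last = "text", a_first = "integer",
                              mid = "date"))))))
  back <- parse_workflow(serialize_workflow(wf))
  expect_identical(names(back$activities$a$attributes$t$columns),
                   c("z_last", "a_first", "mid"))
})

test_that("field records with unknown keys lint as warnings but still parse", {
  doc <- sub('<Activity Id="only" Name="Only"/>',
             paste0('<Activity Id="only" Name="Only"><ExtendedAttributes>',
                    '<ExtendedAttribute Name="FLUX_FIELD" ',
                    'Value="NAME=x;KIND=integer;COLOUR=red"/>',
                    '</ExtendedAttributes></Activity>'),
             minimal_doc())
  issues <- lint_workflow(doc)
  expect_true(any(issues$code == "unknown-field-key" &
                    issues$severity == "warning"))
  wf <- parse_workflow(doc)
  expect_identical(wf$activities$only$attributes$x$kind, "integer")
})
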