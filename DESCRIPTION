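Package: fluxcase
Title: Workflow-Defined Electronic Health Record Engine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale electronic health record (EHR) engine whose entire
    data model is declared in a workflow definition file rather than in code.
    A disease protocol is an XPDL-subset document describing activities,
    transitions, typed attributes (integers, reals, dates, choices, registry
    lookups, repeating tables and computed fields), registries and suggestion
    rules. The package parses, lints and serializes these workflows, runs the
    per-patient activity state machine with full validation, keeps a
    hash-chained append-only audit trail with role-based permissions, executes
    batch value files, exports analysis-ready tables (long/wide CSV and ARFF)
    and ships three example disease protocols plus a seeded synthetic case
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    foreign,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
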