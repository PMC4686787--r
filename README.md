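# fluxcase

A workflow-defined electronic health record (EHR) engine for rare and
complex diseases, in R.

Rare diseases seldom justify a bespoke EHR, and the generic alternatives
fail in opposite ways: rigid systems hard-code a fixed form set, while
free-text systems produce notes that cannot be compared or analyzed.
fluxcase takes a third route, borrowed from workflow-based laboratory
information management systems (LIMS): **the entire clinical data model
lives in a workflow definition file**. A disease protocol is a directed
graph of *activities* (consultation, exam, diagnosis, ...), each carrying
typed *attributes* — integers and reals with inclusive ranges, ISO dates,
fixed choice lists, registry-backed lookups that refuse misspellings,
repeating tables (one row per family member, say), and computed fields
derived by formula from earlier answers. Supporting a new disease, or a new
question in an old one, means editing the workflow file. The engine never
changes.

The package provides, for a workflow file in an XPDL 2.x structural subset:

* **Parsing, linting and serialization** (`parse_workflow()`,
  `lint_workflow()`, `serialize_workflow()`), with structural invariants
  enforced at load time;
* **A per-patient activity state machine** — every activity is `executed`,
  `available` or `locked`; an activity unlocks when any predecessor has been
  executed, so alternative diagnostic paths stay open and the clinician
  chooses (`create_case()`, `status()`, `execute_activity()`,
  `suggest_next()`);
* **Total validation** — any submission either stores typed values or
  returns the complete list of structured errors, never partial state;
* **An audited store** — append-only SHA-256 hash-chained audit trail,
  role-based read/write permissions with default deny, snapshot/restore,
  and full store reconstruction by replaying the trail (`audit_log()`,
  `verify_audit_chain()`, `snapshot()`, `replay_audit()`);
* **Batch execution and export** — long/wide CSV and ARFF for downstream
  statistics and data-mining tools, plus a deterministic per-case text
  report (`batch_execute()`, `export_cases()`, `case_report()`);
* **Three packaged protocols** — neuromyelitis optica (`@nmo`, 16
  activities), paracoccidioidomycosis (`@pcm`, with a 35-condition and a
  29-disease-history battery) and adrenoleukodystrophy (`@ald`, 9
  activities with extensible registries and suggestion rules) — and a
  seeded synthetic-case generator (`generate_cases()`).

## Worked example

```r
library(fluxcase)

st <- flux_store(clock = fixed_clock())   # deterministic clock for the demo
load_workflow(st, flux_fixture("ald"))
add_user(st, "asouza", "A. Souza", role = "clinician")
grant_permission(st, "clinician", "ald", "*", c("read", "write"))

case <- create_case(st, "ald", user = "asouza")
execute_activity(st, case$case_id, "diagnosis_information",
  list(patient_initials = "J.S.", birth_date = "1980-06-01",
       first_symptom_date = "2010-06-01",
       genotype = "ABCD1 c.1415_1416delAG"),
  user = "asouza")
#> <flux_execution> diagnosis_information v1 (2024-01-01T08:04:00Z, by asouza)
#>   patient_initials: J.S.
#>   birth_date: 1980-06-01
#>   genotype: ABCD1 c.1415_1416delAG
#>   first_symptom_date: 2010-06-01
#>   age_at_first_symptom: 30
```

`age_at_first_symptom` was not entered: it is a computed attribute,
evaluated from the formula
`years_between(first_symptom_date, birth_date)` declared in the workflow
file (completed years, truncated — the clinical age convention). After
recording the treatment, symptoms and a clinical-evolution visit with an
elevated very-long-chain fatty acid level:

```r
execute_activity(st, 1, "treatment", list(treatment = "Dietary therapy"),
                 user = "asouza")
execute_activity(st, 1, "symptoms", list(symptom = "Fatigue",
                 severity = "moderate"), user = "asouza")
execute_activity(st, 1, "clinical_evolution",
  list(visit_date = "2011-05-01", vlcfa_level = "2.4"), user = "asouza")

suggest_next(st, 1)
#> [1] "mri_encephalon"        "adrenal_function_test"

head(status(st, 1), 6)
#>             activity_id     state
#> 1 diagnosis_information  executed
#> 2             treatment  executed
#> 3              symptoms  executed
#> 4    clinical_evolution  executed
#> 5        mri_encephalon available
#> 6 adrenal_function_test available
```

The two suggestions come from a rule in the workflow file
(`vlcfa_level > 1.5`), filtered to activities that are currently
available. Every mutation so far is in the audit trail
(`audit_log(st)`), hash-chained (`verify_audit_chain(st)` is `TRUE`),
and the whole store can be exported for analysis:

```r
export_cases(st, "ald", "csv-long", "ald-cases.csv", user = "asouza")
export_cases(st, "ald", "arff", "ald-cases.arff", user = "asouza")
```

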