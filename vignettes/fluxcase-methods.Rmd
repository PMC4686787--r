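---
title: "fluxcase: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluxcase: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcase)
```

## The model

fluxcase treats an electronic health record system as an *interpreted
workflow*. A disease protocol is a directed graph: nodes are activities (a
consultation, an exam, a diagnosis step), each carrying an ordered schema of
typed attributes; edges are transitions constraining the order in which
activities may be performed for a patient case. Everything the system knows
about a disease — fields, types, ranges, vocabularies, derived quantities,
even which follow-up to suggest — is data in the workflow file. The engine
is generic and never changes per disease; this is the property the whole
design serves, and the property the test suite asserts operationally (a new
attribute added to a workflow file is live, validated and exported with no
package change).

### The workflow dialect

Workflow files use the structural skeleton of XPDL 2.x — `Package` >
`WorkflowProcesses` > `WorkflowProcess` with `Activities` and
`Transitions` — and ignore all layout and graphics elements. XPDL editors
disagree on how to encode domain schemas, so fluxcase defines its own
editor-agnostic encoding on `ExtendedAttribute` elements: one
`FLUX_FIELD` record per attribute (a semicolon-separated `KEY=value`
record with keys `NAME`, `KIND`, `REQUIRED`, `MIN`, `MAX`, `CHOICES`,
`REGISTRY`, `FORMULA`, `COLUMNS`, `EXAMPLE`, `HINT`), and package-level
`FLUX_REGISTRY` / `FLUX_SUGGEST` records. This is a defined stand-in, not
a reconstruction of any particular editor's vocabulary; unknown keys lint
as warnings so files from richer dialects degrade gracefully. Everything
is UTF-8 and case-sensitive, and `;` and `,` are reserved as record and
list delimiters (the linter rejects values that would be ambiguous).

The linter and the parser share one analysis: a document parses if and
only if it has no error-severity lint issue. Warnings (unreachable
activities, shadowed attribute names, multi-predecessor joins, unknown
record keys) never block loading.

### The state machine

For a patient case, each activity is in exactly one of three states:

* **executed** — at least one execution exists;
* **available** — not executed, and the activity either has no incoming
  transition (a start activity) or at least one predecessor is executed;
* **locked** — otherwise.

Two decisions here were genuinely open:

* **OR-joins.** An activity with several predecessors becomes available
  when *any* of them is executed. Branches in clinical protocols model
  alternative strategies — two diagnostic routes, either of which
  justifies the next step — and an AND-join would deadlock whichever
  route was not taken. The linter flags every multi-predecessor activity
  so workflow authors know which semantics they are getting.
* **Re-execution.** Executing an already-executed activity is allowed and
  produces a new version (1, 2, ...), never an overwrite. This one
  mechanism covers both corrections and longitudinal re-entry (a battery
  repeated at every consultation); earlier versions stay retrievable, and
  the audit trail keeps the full history either way.

### The type system

Eight attribute kinds: `integer`, `real` (bounds, where declared, are
*inclusive* — the natural reading of a clinical range), `text`, `date`
(ISO 8601 `YYYY-MM-DD` only; unambiguous and sortable; impossible
calendar dates like `2020-02-30` are rejected, not normalized), `choice`,
`register`, `table` (repeating rows over scalar columns; no nesting),
and `computed`.

Validation is **total** and **complete**: any finite text input yields
either a typed value or structured errors — never an exception — and all
independently violated constraints are reported, not just the first. The
empty string for a non-required attribute means *absent* and stores no
value; for a required attribute it is a `missing-required` error.

Registry matching is exact and case-sensitive. The registry kind exists to
*prevent* misspelled vocabulary from entering the record, so near misses
(edit distance ≤ 2) are suggested in the error message but never silently
accepted. Extensible registries accept audited appends at run time, so a
novel treatment can become part of the allowed vocabulary without touching
the workflow file; non-extensible registries refuse.

### Formulas

Computed attributes and suggestion conditions use a closed expression
language, deliberately not R: numbers, attribute names, `+ - * /` with
standard precedence and left associativity, parentheses, unary minus,
`years_between(a, b)`, string literals, and a single comparison
(`== != < <= > >=`) at lowest precedence. The evaluator is a tree walk
over this grammar and nothing else — there is no route from a workflow
file to host-language evaluation, which the suite asserts by feeding the
parser hostile inputs. Comparisons were added to the arithmetic core
because suggestion rules need boolean conditions; a single non-chainable
comparison is the smallest sufficient extension.

`years_between` counts completed calendar years truncated toward zero
(the clinical age convention), and is tested against an independent
anniversary-counting oracle. Division by zero, non-numeric operands and
unbound names raise classed evaluation errors naming the offending
symbol; they are never folded into values.

Computed attributes evaluate over the union of the activity's own values
and the latest values of its *ancestor* activities (those from which it is
reachable); on a name collision the local value shadows the ancestor, and
the linter warns at parse time so the shadowing is never a surprise. If a
referenced input is absent (an optional field left empty), the computed
value is simply absent too — failing the whole submission because an
optional input is missing would make optional fields effectively
required. Any other evaluation failure rejects the submission.

## The audited store

Every mutating operation appends exactly one audit entry; validation
failures append none; permission denials append one entry with
`outcome = "denied"`, because an access-control system that does not
record refusals is not accountable. Entries carry a SHA-256 hash over
their content plus the previous entry's hash, making the trail
tamper-evident: edits, deletions and reorderings all break the chain.

Execution entries record the submitted raw values, which makes the trail a
*complete* history: `replay_audit()` rebuilds a store from nothing but the
trail, and the suite checks that every latest value in the replayed store
equals the live one. Snapshots are single self-contained JSON documents
(workflows re-serialized to XPDL, live registries, all execution versions,
users, permissions, the trail); restore is all-or-nothing and re-verifies
the hash chain. JSON was chosen over a binary archive because the store
must be inspectable and diffable at desk scale.

Permissions follow default deny: a right exists only if a permission row
matches the user's role, the workflow, the activity (exactly or via the
`"*"` wildcard) and includes the right; `write` governs executing and case
creation, `read` governs retrieval and export. User and permission
management is administrative — driven by the deployment's configuration
file and audited, but not itself permission-gated, since with an empty
table nobody could bootstrap. No passwords are implemented: identity is
asserted by configuration/CLI flag, and authentication proper is a
deployment concern outside the package's testable core.

Timestamps come from an injectable clock (`fixed_clock()` in all tests
and examples), so stores, reports and exports are reproducible to the
byte.

## Batch execution and export

The batch format is a long CSV (`case_id,activity,attribute,row_index,
column,value`; RFC 4180): one row per scalar value, one per table cell.
A flat long format handles scalars and repeating tables uniformly, which a
wide upload format cannot. Groups — one `(case, activity)` submission
each — are independent: a failing group never blocks the others. Rows
naming computed attributes are skipped (derived values are never
submitted), and case ids absent from the store are created provided they
extend it densely (`max+1, max+2, ...`); both rules exist so that a
long-CSV *export* is itself a valid batch file, and the suite checks the
export → fresh store → re-import → export cycle for byte identity
(modulo version counters, which restart).

Exports come in three dialects: `csv-long` (lossless), `csv-wide` (one
row per case–activity–version; activity-qualified columns; repeating
tables excluded rather than lossily flattened), and ARFF for data-mining
tools (NUMERIC for numeric and computed kinds, `date "yyyy-MM-dd"`,
nominal enumerations in declared order for choices and registries, STRING
otherwise, `?` for missing). The ARFF writer is checked against an
independent reader (`foreign::read.arff`) in the suite. By default only
latest versions are exported — analysis wants current state — with
`all_versions = TRUE` for history.

## Packaged protocols and synthetic data

Three protocols ship as `.xpdl` files: the 16-activity neuromyelitis
optica workflow (identification with demographics and a registry-backed
attending physician, a repeating family-history table, a computed
age-at-onset spanning activities, branching optic-neuritis/myelitis
assessment paths), the paracoccidioidomycosis workflow (identification by
SAME hospital number; a first-consultation battery of 35 present/absent
conditions and 29 yes/no disease-history questions with free-text
overflow fields; three organ-system exams; a concluding
hypothesis/exams/prescriptions activity), and the 9-activity
adrenoleukodystrophy workflow (extensible treatment and symptom
registries, suggestion rules driven by fatty-acid and cortisol levels).
Activity and attribute names beyond those on public record — and all
numbered condition/disease labels — are reconstructions, marked as such
in the files: they exercise structure and types, never medical content.

The synthetic generator (`generate_cases()`) fills a store with seeded
cases: per pass, each available activity executes with probability
`completion` (default 0.8 — most of a protocol gets done at each
encounter, not all), drawing integers and reals uniformly within declared
bounds (0–100 when unbounded), dates uniformly in 1950–2020 (a plausible
span of birth and event dates), choices and registry entries uniformly,
tables with 0–4 rows, and text from a fixed word list. With
`invalid_fraction > 0` individual values are deliberately made
out-of-domain and the generator *asserts* the engine rejects the
submission; kinds that accept any text are invalidated by an unknown
extra attribute instead, so `invalid_fraction = 1` provably stores
nothing. The generator restores the caller's RNG state, and equal seeds
yield byte-identical exports.

What passing tests on synthetic data do **not** show: the values carry no
clinical realism — no correlated symptoms, no plausible trajectories, no
real vocabularies beyond the fixture registries. They demonstrate that the
machinery (typing, state, audit, round trips) is correct, not that any
medical content is.

## Problem sizes and numerical choices

The property suites run at sizes chosen to exercise structure while
keeping the default test run brisk: the state-machine oracle comparison
uses 500 seeded random workflows of up to 12 activities with random
execution sequences (the acceptance script re-runs 200 under its own
seed); serialization round trips cover the three fixtures plus 200 random
workflows; validation fuzzing feeds 10^4 random strings per attribute
kind; audit replay and chain checks run on a 50-case synthetic store.
Real-number parsing accepts `.` as the only decimal separator
(locale-independence); exported reals render with up to 15 significant
digits so that re-validation reproduces the stored double exactly.
Suggestion rules evaluate in declaration order, and suggestions are
de-duplicated preserving first occurrence, then filtered to currently
available activities — determinism over cleverness.

## Known limitations

* One process per workflow file; XPDL pools, lanes, deadlines and
  sub-flows are out of scope, as is any graphical editor.
* The store is single-writer, desk-scale: operations are atomic per case,
  but there is no concurrent multi-session web front end.
* Registry entries may not contain `;` or `,` (the record delimiters).
* Wide/ARFF exports drop repeating tables by design; use the long dialect
  when tables matter.
* No units conversion, reference ranges, or free-text analysis: fields
  the workflow does not declare, the system does not know.
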