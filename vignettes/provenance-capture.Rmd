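---
title: "Capturing and chaining the provenance of simulation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capturing and chaining the provenance of simulation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simprov)
```

## The provenance model

`simprov` stores the history of a simulation study as one directed acyclic
graph in the PROV-DM style. Three node kinds carry the story:

* **entity versions** — immutable snapshots of study products. A product's
  identity is the pair *(entity type, canonical file path)*; every edit
  appends the next version `v(k+1)` with a `REVISION_OF` edge to `v(k)`.
  Paths are normalized lexically (separator unification, `.`/`..`
  collapse), never resolved against a filesystem, so the builder can run
  far from the modeler's machine. Eleven entity types cover the
  conceptual model (research question, requirement, assumption,
  qualitative model, data, reference), the simulation model and
  experiment, simulation data, and postprocessing (script, visualization).
  "Research objective" is accepted as a parse-time alias of the research
  question — the two names coexist in study-reporting vocabularies and we
  found no workable distinction between them.
* **activities** — the modeler's actions, eight types from specifying each
  conceptual resource through executing experiments and analyzing data.
* **agents** — the software bearing responsibility for activities, keyed by
  *(name, version)* so a tool reported a hundred times is one node.

Edges are typed (`USED`, `GENERATED_BY`, `ASSOCIATED_WITH`, `REVISION_OF`)
with fixed endpoint kinds, and every insertion is cycle-checked, so
acyclicity is an invariant rather than a hope. Node ids are deterministic
functions of the event stream (`activity:<event_id>`,
`entity:<type>:<path>:v<k>`, `agent:<name>:<version>`): rebuilding a graph
from the same events reproduces identical ids, which makes exports
diffable and replay a byte-stable operation. We chose readable ids over
opaque hashes deliberately — they carry the same determinism guarantee and
make debugging and DOT renderings legible.

Timestamps are carried on activities but never used for ordering:
insertion order is authoritative. Capturers emit events in the order the
actions happened; trusting wall clocks across machines would make version
numbering dependent on clock skew.

## Provenance patterns

A pattern declares, per activity type, which used and generated entity
types are valid, with `[min, max]` cardinalities, which attributes each
entity must carry (default: non-empty `name` and `path`; a
`specification` may be blank), and whether an agent is required (default:
yes, with a `name`). Patterns are YAML and user-replaceable; the shipped
`patterns/default.yaml` covers all eight activities.

Only the experiment-specification pattern is fully prescribed by the
provenance model we implement (a simulation model is always used; an
existing experiment, an assumption, and/or a requirement optionally; a
simulation experiment is always generated). The other seven are
reconstructed from the entity taxonomy and the worked example graphs and
marked as such in the file. Two reconstruction choices deserve note:

* **Executing an experiment requires both the experiment and the model.**
  One could argue the experiment alone suffices (it references its model),
  but the worked examples consistently show both used, and requiring both
  keeps the executed model version explicit in the graph.
* **Analyzing simulation data must generate a visualization** (data output
  is optional). Analysis can in principle produce only transformed data,
  but every pattern must require *some* generated entity — an activity
  that provably produced nothing is indistinguishable from a capturer
  bug — and the visualization is the common case. Data-only analyses can
  be accommodated with a user pattern file.
* A "visualizing data" action maps onto the analyzing-data activity; we do
  not introduce a ninth type for it.

Cardinality defaults err permissive: `max` is unbounded unless a pattern
says otherwise, because real studies compare multiple models in one
activity; singular phrasing in a pattern description is not read as
`max = 1`. Entity types *not mentioned* in any constraint of a pattern are
violations in strict mode (the default): silently dropping them would hide
capturer bugs. A `permissive = TRUE` flag downgrades this to a warning for
exploratory ingestion of foreign streams.

```{r patterns}
p <- default_patterns()
match_activity(p, "SpecifyingSimulationExperiment",
               used = list(list(entity_type = "SimulationModel",
                                name = "m1", path = "models/m1.mlr")),
               generated = list(list(entity_type = "SimulationExperiment",
                                     name = "e1", path = "experiments/e1.py")),
               agent = list(name = "vscode"))
```

## The builder

`ingest_event()` is atomic at event granularity: a valid event contributes
its activity, entity versions, agent, and edges; an invalid event
contributes exactly nothing to the graph and one verbatim record to the
error log. Partial insertion would break the accounting invariant we test
throughout: *activities in graph + error-log records = events processed*.
Duplicate event ids are rejected without state change, so capturers may
deliver at-least-once.

Chaining resolves every used descriptor to the **latest version** of its
identity. A used product never seen before is bootstrapped as version 1
without a generating activity: conceptual files exist before any capturer
watched them, and rejecting them would make starting a study impossible.
Generated descriptors create version `k+1` of an existing identity (with
its `REVISION_OF` edge) or version 1 of a new one. File content is stored
as an attribute up to `getOption("simprov.content_limit", 1 MiB)`; larger
payloads keep only their hash.

Two manual completion operations mirror what automatic capture cannot
infer: `add_manual_dependency()` (e.g. linking a copied-and-adapted model
to its source; flagged `origin = "manual"` in all exports and styled
distinctly in DOT) and `fill_attribute()` (supplying attributes the
capturer missed; `name`/`path` must stay non-empty). `revalidate()`
re-audits a stored graph against the patterns, so hand edits that break a
pattern are detectable after the fact.

## The capturer SDK

`capture_session()` is a reference implementation of both capture methods:

* **File tracking** (the editor-plugin contract): `register_entity()`
  creates a typed, tracked file and emits its `specifying_*` event;
  `detect_edit()` emits a new-version event **iff the content hash
  changed** — hash-based detection on save keeps the SDK deterministic and
  testable without OS file watchers (a watcher is thin optional glue, not
  part of the contract). Edit events re-declare the used entities chosen
  at registration, so patterns with required inputs stay satisfied across
  edits.
* **Execution wrapping** (the utility-library contract):
  `wrap_execution()` runs the modeler's callable, fingerprints the
  declared output file, and emits the executing (or analyzing) event. A
  failing run still emits its event, flagged `failed` with an empty output
  descriptor — failed iterations are part of the study's history, not
  noise. Environment metadata lands in `extras` and is never required by
  patterns, keeping patterns tool-agnostic.

`infer_entity_type()` applies a file-naming convention
(`model_*`, `requirement_*`, …; shipped as editable YAML) and returns `NA`
rather than guessing: no entity type is universally identifiable from file
names alone, so ambiguity is pushed back to the modeler explicitly.

## Reduction views

**Chain aggregation** collapses maximal same-type activity chains into one
aggregate each. Two same-type activities are chained when they generate
consecutive versions of one identity (with no other-type activity
generating an intermediate version) or when one directly uses what the
other generated. This definition is our formalization of
"sequences of the same activity" — the abstraction rule is not fully
specified by its sources — and it reproduces the expected phase structure:
a ten-iteration edit-specify-execute-analyze refinement (40 activities)
collapses to one aggregate per activity type with member counts summing
to 40. Inside an aggregate, intermediate entity versions are elided from
the *view* (the final version survives; the underlying graph is
untouched — views are non-destructive), and edges are remapped to the
survivors, preserving reachability among surviving nodes in the
member-union (quotient) sense that aggregation implies. Aggregation is
idempotent.

**Transitive reduction** removes every edge implied by a longer path —
the unique minimal edge set of a DAG with the same reachability.
`REVISION_OF` edges are exempt and kept verbatim: the statement "v2
revises v1" is semantic content, not a redundant shortcut, even when a
longer path happens to connect the two versions. They still count toward
the reachability that other edges are tested against.

## Serialization

PROV-JSON export writes the standard `entity`/`activity`/`agent` and
`used`/`wasGeneratedBy`/`wasAssociatedWith` sections; study types become
`prov:type` values under the `simprov:` prefix, versions ride on
`simprov:version` plus a `simprov:revisionOf` relation section, and manual
edges carry `simprov:origin`. Attribute keys are emitted in sorted order
and relations in insertion order, making export deterministic:
`import_prov_json()` then `export_prov_json()` is byte-identical, which
the tests exercise over 100 generated graphs. Import is strict by default
(unknown types are errors) with a permissive mode that imports foreign
entities untyped with a warning.

## The synthetic study generator

`generate_stream()` emulates the event stream of a three-phase study:
conceptual specification (references, research question, assumptions,
requirements), iterative refinement (model edit, experiment edit,
execution, analysis per iteration — four activities each), and adaptation
(model copy, execution, comparative analysis). Streams are
seed-deterministic; file contents are tiny text blobs keyed by the seed,
standing in for real model code. With `invalid_fraction > 0` a seeded
subset of events is corrupted and listed in a manifest. Corruptions are
drawn *only* from violation classes the pattern engine detects (required
used entity removed, required attribute blanked, unknown activity type),
so the expected error-log content is exactly computable — that is what
makes the conservation and atomicity properties testable to equality
rather than approximately.

What the generator does **not** emulate: real editing cadence and
timestamps (the clock is one synthetic minute per event), concurrent
multi-tool capture, large or binary file contents, renamed or moved files
(a rename is a new identity, see limitations), and any actual simulation
dynamics. Passing tests therefore demonstrate the bookkeeping contracts —
validation, chaining, versioning, reduction, serialization — not that any
particular editor integration captures every real-world action.

Test and acceptance problem sizes (mini-studies of 1–3 refinement
iterations across several seeds, 200 random DAGs of up to 25 nodes for
the reduction oracle, 100 graphs for round-trip stability, a
ten-iteration phase for aggregation) were chosen so each property is
exercised across distinct shapes while the whole suite stays quick to run
routinely.

## Limitations

* **Identity is path-bound.** Renaming or moving a file starts a new
  identity; the link to the old history must be added manually, exactly as
  for a copied-and-adapted model. Content-based identity was rejected
  because products legitimately share content (empty templates).
* **Patterns are local to one activity.** Cross-activity rules ("a model
  must be validated before prediction") are out of scope.
* **No persistence layer.** State lives in memory and in PROV-JSON files;
  the REST service is single-session and unauthenticated by design.
* **Aggregation merges activities only**; repeated entities between
  iterations are elided from the view rather than summarized into
  aggregate entities.
* The error log keeps rejected events verbatim, but re-submission after
  fixing requires a fresh event id; the builder does not mutate logged
  events back into the graph.
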