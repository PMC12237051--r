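# simprov

Provenance capture and graph building for simulation studies.

## The problem

A simulation study in systems biology is not a linear pipeline: models are
refined over dozens of edit–run–analyze iterations, experiments are adapted,
assumptions and requirements are written down early and shape decisions much
later. When only the final model and figures are published, that process —
*which* references informed *which* assumptions, *which* model version
produced *which* data — is lost, and with it much of the study's
reproducibility. Reconstructing such a history by hand after the fact takes
hours and is error-prone.

`simprov` records this history as it happens. Lightweight **provenance
capturers** (an editor-plugin-style file tracker and an execution-wrapping
helper, both included as a reference SDK) observe the modeler's actions and
emit JSON **events**. A central **provenance builder** validates every event
against a declarative **provenance pattern** for its activity type and
chains the valid ones into a single, growing provenance graph. Invalid
events are never half-applied: they land verbatim in an error log for
inspection.

## The model

The graph follows the W3C PROV-DM core — *entities*, *activities*, and
*agents* connected by `used` (entity ← activity), `wasGeneratedBy`
(activity ← entity), and `wasAssociatedWith` (agent ← activity) relations,
forming a directed acyclic graph — extended with simulation-study types:

* **Entities** (study products): research question, requirement, assumption,
  qualitative model, data, reference, simulation model, simulation
  experiment, simulation data, script, visualization.
* **Activities** (modeler actions, eight types): specifying each
  conceptual-model resource, specifying the simulation model and experiment,
  executing an experiment, analyzing simulation data.
* **Agents**: the software systems bearing responsibility for activities
  (editors, simulators, runtimes).

Every edit of a product creates a new immutable **entity version**
(`v1, v2, …`, linked by revision edges); new dependencies always attach to
the latest version. Each activity type has a YAML-declared **pattern**
stating its required and optional used/generated entity types with
cardinalities and required attributes — e.g. specifying a simulation
experiment *always* uses a simulation model and *always* generates a
simulation experiment; assumptions and requirements are optional.

Two reduction views make long histories readable: **chain aggregation**
collapses maximal runs of same-type activities (linked through the entity
versions they successively generate) into one aggregate per run, exposing
the study's phases; **transitive reduction** removes every edge implied by a
longer path (revision edges are kept verbatim). Graphs export to
**PROV-JSON** (round-trippable, byte-stable) and **Graphviz DOT**.

## Worked example

The canonical two-experiment study: two experiment executions under a
Tellurium agent, then one analysis under a Python agent.

```r
library(simprov)

b <- ingest_stream(prov_builder(), fig2_stream())
graph_counts(b$graph)
#>        entities      activities          agents           edges            used
#>               8               3               2              13               7
#>    generated_by associated_with     revision_of
#>               3               3               0
```

Eight entity versions (two models, two experiments, two simulation data
sets, one script, one visualization), three activities, two agents; 13
typed edges — 7 `used`, 3 `wasGeneratedBy`, 3 `wasAssociatedWith`. The
script `S` was never generated inside the study, so it enters as a
bootstrapped version 1 on first use.

Versioning and validation:

```r
p <- default_patterns()
m <- match_activity(p, "SpecifyingSimulationExperiment",
                    used = list(), # forgot the model
                    generated = list(list(entity_type = "SimulationExperiment",
                                          name = "e1", path = "e1.py")),
                    agent = list(name = "vscode"))
m
#> <prov_match: invalid, 1 violation(s)>
#>   [missing-entity] requires at least 1 SimulationModel as used, found 0
```

An event failing such a check is rejected whole and logged; the graph never
changes. See the vignette (`vignettes/provenance-capture.Rmd`) for the
capturer SDK, the reductions, and the synthetic study generator.

A thin CLI wraps the same functions
(`inst/cli/simprov ingest|errors|export|reduce|fixtures|serve`), and
`prov_serve()` exposes the builder as the REST service capturers POST
events to.

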