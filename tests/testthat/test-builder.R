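test_that("parse_event handles minimal, full, and malformed inputs", {
  ev <- parse_event('{"event_id":"x1","event_type":"specifying_reference",
    "agent":{"name":"vscode"},
    "generated":[{"entity_type":"Reference","name":"r","path":"refs/r.md"}]}')
  expect_s3_class(ev, "prov_event")
  expect_length(ev$generated, 1L)
  expect_identical(ev$generated[[1]]$entity_type, "Reference")

  full <- parse_event('{"event_id":"x2","event_type":"executing_simulation_experiment",
    "timestamp":"2026-01-01T10:00:00Z","agent":{"name":"mlrules","version":"3.0"},
    "used":[{"entity_type":"SimulationModel","name":"m","path":"m.mlr"},
            {"entity_type":"SimulationExperiment","name":"e","path":"e.py"}],
    "generated":[{"entity_type":"SimulationData","name":"sd","path":"sd.csv"}],
    "run_id":42}')
  expect_length(full$used, 2L)
  expect_equal(full$extras$run_id, 42)

  expect_error(parse_event('{"event_id":"x3", "event_ty'),
               class = "simprov_malformed_json")
  expect_error(parse_event('{"event_id":"x4","generated":[]}'),
               class = "simprov_missing_field")
  expect_error(parse_event('{"event_id":"x5","event_type":"specifying_reference"}'),
               class = "simprov_missing_field")
})

test_that("ingestion is atomic: valid events chain, invalid ones go to the log", {
  b <- small_graph()
  n0 <- graph_counts(b$graph)

  # valid experiment event: one activity, one new entity version, three edges
  b2 <- ingest_event(b, prov_event(
    "ing-1", "specifying_simulation_experiment", test_agent(),
    used = list(ed("SimulationModel", "m1", "models/m1.mlr")),
    generated = list(ed("SimulationExperiment", "e2", "experiments/e2.py"))
  ))
  n2 <- graph_counts(b2$graph)
  expect_equal(n2[["activities"]], n0[["activities"]] + 1L)
  expect_equal(n2[["entities"]], n0[["entities"]] + 1L)
  expect_equal(nrow(error_log(b2)), 0L)

  # the same event without its required model: graph untouched, log grows
  b3 <- ingest_event(b, prov_event(
    "ing-2", "specifying_simulation_experiment", test_agent(),
    used = list(),
    generated = list(ed("SimulationExperiment", "e2", "experiments/e2.py"))
  ))
  expect_identical(canonical_graph(b3$graph), canonical_graph(b$graph))
  log <- error_log(b3)
  expect_equal(nrow(log), 1L)
  expect_match(log$codes, "missing-entity")
  # the rejected event is stored verbatim
  expect_identical(b3$error_log[[1]]$event$event_id, "ing-2")

  # replay of a processed id: error, no state change
  expect_error(ingest_event(b2, prov_event(
    "ing-1", "specifying_simulation_experiment", test_agent(),
    generated = list(ed("SimulationExperiment"))
  )), class = "simprov_duplicate_event")
})

test_that("conservation holds: activities plus rejects equals events processed", {
  ev <- generate_stream(ministudy_script(refine = 2L, seed = 4L, invalid_fraction = 0.3))
  b <- ingest_stream(prov_builder(), ev)
  expect_equal(
    graph_counts(b$graph)[["activities"]] + nrow(error_log(b)),
    length(ev)
  )
  expect_length(b$processed_event_ids, length(ev))
  expect_identical(b$processed_event_ids,
                   vapply(ev, function(e) e$event_id, ""))
})

test_that("chaining versions: edits create revisions, uses attach to the latest", {
  b <- prov_builder()
  for (i in 1:2) {
    b <- ingest_event(b, prov_event(
      sprintf("ch-%d", i), "specifying_simulation_model", test_agent(),
      generated = list(ed("SimulationModel", "m1", "models/m1.mlr",
                          content = paste0("rules v", i)))
    ))
  }
  g <- b$graph
  v2 <- "entity:simulation_model:models/m1.mlr:v2"
  v1 <- "entity:simulation_model:models/m1.mlr:v1"
  expect_true(any(g$edges$kind == "REVISION_OF" & g$edges$from == v2 & g$edges$to == v1))
  # the second activity generated v2, not v1
  gb <- g$edges[g$edges$kind == "GENERATED_BY", ]
  expect_identical(gb$from[gb$to == "activity:ch-2"], v2)

  # third edit, then an execution: USED targets version 3
  b <- ingest_event(b, prov_event(
    "ch-3", "specifying_simulation_model", test_agent(),
    generated = list(ed("SimulationModel", "m1", "models/m1.mlr", content = "rules v3"))
  ))
  b <- ingest_event(b, prov_event(
    "ch-4", "specifying_simulation_experiment", test_agent(),
    used = list(ed("SimulationModel", "m1", "models/m1.mlr")),
    generated = list(ed("SimulationExperiment", "e1", "experiments/e1.py"))
  ))
  b <- ingest_event(b, prov_event(
    "ch-5", "executing_simulation_experiment", list(name = "mlrules", version = "3.0"),
    used = list(ed("SimulationExperiment", "e1", "experiments/e1.py"),
                ed("SimulationModel", "m1", "models/m1.mlr")),
    generated = list(ed("SimulationData", "sd", "output/sd.csv"))
  ))
  used <- b$graph$edges[b$graph$edges$kind == "USED" &
                          b$graph$edges$from == "activity:ch-5", ]
  expect_true("entity:simulation_model:models/m1.mlr:v3" %in% used$to)
  expect_false(v1 %in% used$to)
})

test_that("a used descriptor with no prior version bootstraps version 1", {
  b <- ingest_event(prov_builder(), prov_event(
    "bs-1", "specifying_research_question", test_agent(),
    used = list(ed("Reference", "paper", "refs/reference_p.md")),
    generated = list(ed("ResearchQuestion", "q", "concept/question_q.md"))
  ))
  ref <- resolve_latest(b$graph, entity_identity("Reference", "refs/reference_p.md"))
  expect_identical(ref$version, 1L)
  # externally produced: no generating activity
  gb <- b$graph$edges[b$graph$edges$kind == "GENERATED_BY", ]
  expect_false(ref$node_id %in% gb$from)
})

test_that("manual dependencies pass cycle checks and are flagged", {
  # adapted-model scenario: the copy's specifying activity manually linked
  # to the source model's latest version
  b <- prov_builder()
  b <- ingest_event(b, prov_event(
    "md-1", "specifying_simulation_model", test_agent(),
    generated = list(ed("SimulationModel", "orig", "models/model_orig.mlr"))
  ))
  b <- ingest_event(b, prov_event(
    "md-2", "specifying_simulation_model", test_agent(),
    generated = list(ed("SimulationModel", "adapted", "models/model_adapted.mlr"))
  ))
  orig_v1 <- "entity:simulation_model:models/model_orig.mlr:v1"
  b2 <- add_manual_dependency(b, "activity:md-2", orig_v1)
  e <- b2$graph$edges
  manual <- e[e$origin == "manual", ]
  expect_equal(nrow(manual), 1L)
  expect_identical(manual$kind, "USED")
  # reachability from the adapted model's activity to the original version
  M <- closure_matrix(b2$graph$nodes$node_id, e$from, e$to)
  expect_true(M["activity:md-2", orig_v1])
  # the flag survives export
  expect_match(export_prov_json(b2$graph), '"simprov:origin": "manual"', fixed = TRUE)

  # closing a cycle is rejected, state unchanged
  adapted_v1 <- "entity:simulation_model:models/model_adapted.mlr:v1"
  expect_error(add_manual_dependency(b2, "activity:md-2", adapted_v1),
               class = "simprov_cycle")
  # duplicating an automatic edge is a warning no-op
  expect_warning(b3 <- add_manual_dependency(b2, "activity:md-2", orig_v1),
                 class = "simprov_duplicate_edge")
  expect_equal(nrow(b3$graph$edges), nrow(b2$graph$edges))
})

test_that("fill_attribute repairs revalidation violations but keeps name/path non-empty", {
  b <- small_graph()
  exp1 <- "entity:simulation_experiment:experiments/e1.py:v1"
  b2 <- fill_attribute(b, exp1, "specification", "scan lipoplex dose 1..10")
  i <- match(exp1, b2$graph$nodes$node_id)
  expect_identical(b2$graph$nodes$attributes[[i]]$specification,
                   "scan lipoplex dose 1..10")

  # blanked path -> violation -> filled -> violation disappears
  broken <- b
  broken$graph <- simprov:::set_node_attribute(broken$graph, exp1, "path", "")
  expect_gt(nrow(revalidate(broken$graph)), 0L)
  fixed <- fill_attribute(broken, exp1, "path", "experiments/e1.py")
  expect_equal(nrow(revalidate(fixed$graph)), 0L)

  expect_error(fill_attribute(b, exp1, "name", ""), class = "simprov_invalid_value")
  expect_error(fill_attribute(b, "entity:ghost:v1", "name", "x"),
               class = "simprov_unknown_node")
})

test_that("replay determinism: same stream twice gives byte-identical exports", {
  ev <- generate_stream(ministudy_script(refine = 2L, seed = 12L))
  j1 <- export_prov_json(ingest_stream(prov_builder(), ev)$graph)
  j2 <- export_prov_json(ingest_stream(prov_builder(), ev)$graph)
  expect_identical(j1, j2)
})

test_that("JSONL event logs round-trip for offline ingestion", {
  ev <- generate_stream(study_script(list(list(kind = "refine", iterations = 2L)), seed = 6L))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events_jsonl(ev, path)
  back <- read_events_jsonl(path)
  expect_length(back, length(ev))
  g1 <- ingest_stream(prov_builder(), ev)$graph
  g2 <- ingest_stream(prov_builder(), back)$graph
  expect_graph_equal(g1, g2)
})
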