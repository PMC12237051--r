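test_that("PROV-JSON export has the expected sections and record counts", {
  empty <- export_prov_json(prov_graph())
  doc <- jsonlite::fromJSON(empty, simplifyVector = FALSE)
  expect_true(!is.null(doc$prefix$simprov))
  for (sec in c("entity", "activity", "agent", "used", "wasGeneratedBy",
                "wasAssociatedWith")) {
    expect_length(doc[[sec]], 0L)
  }

  g <- ingest_stream(prov_builder(), fig2_stream())$graph
  doc <- jsonlite::fromJSON(export_prov_json(g), simplifyVector = FALSE)
  expect_length(doc$entity, 8L)
  expect_length(doc$activity, 3L)
  expect_length(doc$agent, 2L)
  expect_length(doc$used, 7L)
  expect_length(doc$wasGeneratedBy, 3L)
  expect_length(doc$wasAssociatedWith, 3L)
})

test_that("PROV-JSON round-trips isomorphically and re-exports byte-identically", {
  g <- ingest_stream(prov_builder(), fig2_stream())$graph
  j <- export_prov_json(g)
  g2 <- import_prov_json(j)
  expect_graph_equal(g, g2)
  expect_identical(export_prov_json(g2), j)

  # versioned graph: REVISION_OF edges survive the round trip
  ev <- generate_stream(ministudy_script(refine = 2L, seed = 21L))
  gv <- ingest_stream(prov_builder(), ev)$graph
  jv <- export_prov_json(gv)
  gv2 <- import_prov_json(jv)
  expect_graph_equal(gv, gv2)
  expect_identical(export_prov_json(gv2), jv)
})

test_that("import rejects undeclared namespaces and unknown types in strict mode", {
  expect_error(import_prov_json('{"prefix":{"prov":"x"},"entity":{}}'),
               class = "simprov_malformed_document")
  expect_error(import_prov_json("not json at all {"),
               class = "simprov_malformed_document")
  foreign <- paste0(
    '{"prefix":{"simprov":"ns"},',
    '"entity":{"e1":{"prov:type":"simprov:WetLabProtocol",',
    '"simprov:version":1,"simprov:name":"p","simprov:path":"p.txt"}},',
    '"activity":{},"agent":{},"used":{},"wasGeneratedBy":{},"wasAssociatedWith":{}}'
  )
  expect_error(import_prov_json(foreign), class = "simprov_unknown_type")
  expect_warning(g <- import_prov_json(foreign, strict = FALSE),
                 class = "simprov_unknown_type")
  expect_equal(sum(g$nodes$kind == "entity"), 1L)
  expect_true(is.na(g$nodes$entity_type[1]))
})

test_that("DOT export lists every node and edge with PROV shapes", {
  g <- ingest_stream(prov_builder(), fig2_stream())$graph
  dot <- export_dot(g)
  lines <- strsplit(dot, "\n")[[1]]
  expect_equal(sum(grepl("shape=", lines)), 13L)
  expect_equal(sum(grepl(" -> ", lines)), 13L)
  expect_equal(sum(grepl("shape=ellipse", lines)), 8L)
  expect_equal(sum(grepl("shape=box", lines)), 3L)
  expect_equal(sum(grepl("shape=house", lines)), 2L)
  expect_match(export_dot(prov_graph()), "digraph provenance \\{")

  # manual dependency styled distinctly
  b <- small_graph()
  b <- ingest_event(b, prov_event(
    "dot-1", "specifying_simulation_model", test_agent(),
    generated = list(ed("SimulationModel", "m2", "models/m2.mlr"))
  ))
  b <- add_manual_dependency(b, "activity:dot-1",
                             "entity:simulation_model:models/m1.mlr:v1")
  expect_match(export_dot(b$graph), 'label="manual", style=dashed, color=forestgreen')
})

test_that("transitive reduction removes exactly the redundant edges", {
  # canonical shortcut
  keep <- transitive_reduction_mask(c("a", "b", "a"), c("b", "c", "c"))
  expect_identical(keep, c(TRUE, TRUE, FALSE))
  # already-minimal graphs unchanged
  expect_identical(transitive_reduction_mask(c("a", "a"), c("b", "c")), c(TRUE, TRUE))
  expect_identical(transitive_reduction_mask(character(0), character(0)), logical(0))
  expect_error(transitive_reduction_mask(c("a", "b"), c("b", "a")),
               class = "simprov_cycle")

  # seeded random DAGs against the brute-force deletion oracle
  for (seed in 1:60) {
    d <- random_dag(seed)
    if (length(d$from) == 0L) next
    keep <- transitive_reduction_mask(d$from, d$to, nodes = d$nodes)
    expect_identical(keep, brute_force_reduction(d$nodes, d$from, d$to),
                     info = paste("seed", seed))
    # reachability is preserved exactly
    expect_identical(
      closure_matrix(d$nodes, d$from[keep], d$to[keep]),
      closure_matrix(d$nodes, d$from, d$to),
      info = paste("seed", seed)
    )
  }
})

test_that("transitive_reduce on provenance graphs keeps REVISION_OF verbatim", {
  ev <- generate_stream(ministudy_script(refine = 3L, seed = 31L))
  g <- ingest_stream(prov_builder(), ev)$graph
  r <- transitive_reduce(g)
  expect_s3_class(r, "prov_reduced")
  expect_identical(r$nodes$node_id, g$nodes$node_id)
  expect_equal(
    sum(r$edges$kind == "REVISION_OF"),
    sum(g$edges$kind == "REVISION_OF")
  )
  expect_lte(nrow(r$edges), nrow(g$edges))
  expect_identical(
    closure_matrix(g$nodes$node_id, r$edges$from, r$edges$to),
    closure_matrix(g$nodes$node_id, g$edges$from, g$edges$to)
  )
})

test_that("chain aggregation collapses edit runs and is idempotent", {
  # ten consecutive edits of one model file -> one aggregate of count 10
  b <- prov_builder()
  for (i in 1:10) {
    b <- ingest_event(b, prov_event(
      sprintf("agg-%02d", i), "specifying_simulation_model", test_agent(),
      generated = list(ed("SimulationModel", "m1", "models/m1.mlr",
                          content = paste0("v", i)))
    ))
  }
  r <- aggregate_chains(b$graph)
  ai <- aggregate_info(r)
  expect_equal(nrow(ai), 1L)
  expect_equal(ai$count, 10L)
  expect_identical(ai$activity_type, "SpecifyingSimulationModel")
  # only the final version survives in the view; the aggregate generates it
  ents <- r$nodes[r$nodes$kind == "entity", ]
  expect_equal(nrow(ents), 1L)
  expect_equal(ents$version, 10L)
  gb <- r$edges[r$edges$kind == "GENERATED_BY", ]
  expect_identical(gb$from, ents$node_id)
  expect_identical(gb$to, ai$aggregate_id)

  # no repeated chains -> output isomorphic to input (fixpoint)
  g2 <- ingest_stream(prov_builder(), fig2_stream())$graph
  r2 <- aggregate_chains(g2)
  expect_graph_equal(g2, r2)

  # idempotence
  r3 <- aggregate_chains(r)
  expect_graph_equal(r, r3)
})

test_that("aggregation keeps the phase structure and quotient reachability", {
  ev <- generate_stream(ministudy_script(refine = 4L, seed = 41L))
  g <- ingest_stream(prov_builder(), ev)$graph
  r <- aggregate_chains(g)
  ai <- aggregate_info(r)
  # refine-phase aggregates exist per repeated activity type
  expect_true(all(c("SpecifyingSimulationModel", "ExecutingSimulationExperiment",
                    "AnalyzingSimulationData") %in% ai$activity_type))
  # members are never invented
  expect_true(all(unlist(ai$member_activity_ids) %in% g$nodes$node_id))
  expect_equal(sum(ai$count) + sum(!startsWith(r$nodes$node_id, "aggregate:") &
                                     r$nodes$kind == "activity"),
               sum(g$nodes$kind == "activity"))

  # reachability among surviving nodes equals the quotient of the original
  node_map <- attr(r, "node_map")
  Mo <- closure_matrix(g$nodes$node_id, g$edges$from, g$edges$to)
  Mr <- closure_matrix(r$nodes$node_id, r$edges$from, r$edges$to)
  members <- function(id) names(node_map)[node_map == id]
  ids <- r$nodes$node_id
  for (u in ids) {
    for (v in ids) {
      if (u == v) next
      want <- any(Mo[members(u), members(v)])
      expect_identical(unname(Mr[u, v]), want,
                       info = sprintf("%s -> %s", u, v))
    }
  }
})
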