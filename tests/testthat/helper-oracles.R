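# Independent oracles and small builders shared across tests. These stay
# deliberately dumb: reachability by Warshall closure in base R, transitive
# reduction by one-at-a-time edge deletion, truth tables coded by hand.

# Boolean reachability closure (no igraph): M[u, v] TRUE iff v reachable
# from u by a non-empty path.
closure_matrix <- function(nodes, from, to) {
  n <- length(nodes)
  M <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (length(from) > 0L) M[cbind(match(from, nodes), match(to, nodes))] <- TRUE
  for (k in seq_len(n)) {
    M <- M | outer(M[, k], M[k, ], "&")
  }
  M
}

# Brute-force transitive reduction: an edge is redundant iff its target is
# still reachable from its source after deleting that one edge.
brute_force_reduction <- function(nodes, from, to) {
  keep <- logical(length(from))
  for (i in seq_along(from)) {
    M <- closure_matrix(nodes, from[-i], to[-i])
    keep[i] <- !M[from[i], to[i]]
  }
  keep
}

# Random DAG by construction: edges only run from lower to higher index.
random_dag <- function(seed, max_nodes = 25L, p = 0.25) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1L)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pick <- runif(nrow(pairs)) < p
  list(
    nodes = nodes,
    from = nodes[pairs[pick, "row"]],
    to = nodes[pairs[pick, "col"]]
  )
}

# Canonical form for graph comparison: nodes sorted by id with attribute
# maps key-sorted, edges sorted by (kind, from, to, origin).
canonical_graph <- function(g) {
  nodes <- g$nodes[order(g$nodes$node_id), ]
  nodes$attributes <- lapply(nodes$attributes, function(a) {
    if (length(a) == 0L) return(list())
    lapply(a[order(names(a))], as.character)
  })
  edges <- g$edges[order(g$edges$kind, g$edges$from, g$edges$to, g$edges$origin), ]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

expect_graph_equal <- function(a, b) {
  expect_equal(canonical_graph(a), canonical_graph(b))
}

# entity descriptor shorthand
ed <- function(entity_type, name = paste0(tolower(entity_type), "1"),
               path = paste0("files/", tolower(entity_type), ".txt"), ...) {
  c(list(entity_type = entity_type, name = name, path = path), list(...))
}

test_agent <- function() list(name = "vscode", version = "1.90")

# a small valid graph: one model version used by one experiment-specifying
# activity generating an experiment
small_graph <- function() {
  b <- prov_builder()
  b <- ingest_event(b, prov_event(
    "sg-1", "specifying_simulation_model", test_agent(),
    generated = list(ed("SimulationModel", "m1", "models/m1.mlr")),
    timestamp = "2026-01-01T09:00:00Z"
  ))
  b <- ingest_event(b, prov_event(
    "sg-2", "specifying_simulation_experiment", test_agent(),
    used = list(ed("SimulationModel", "m1", "models/m1.mlr")),
    generated = list(ed("SimulationExperiment", "e1", "experiments/e1.py")),
    timestamp = "2026-01-01T09:01:00Z"
  ))
  b
}

ministudy_script <- function(refine = 3L, seed = 1L, invalid_fraction = 0) {
  study_script(
    list(
      list(kind = "conceptual", iterations = 1L),
      list(kind = "refine", iterations = refine),
      list(kind = "adapt", iterations = 1L)
    ),
    seed = seed, invalid_fraction = invalid_fraction
  )
}
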