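#' Create an empty provenance graph
#'
#' The single growing acyclic provenance graph of a simulation study.
#' Nodes are entity versions, activities, and agents; edges are the four
#' typed dependencies: \code{USED} (activity to entity version),
#' \code{GENERATED_BY} (entity version to activity), \code{ASSOCIATED_WITH}
#' (activity to agent), and \code{REVISION_OF} (entity version k+1 to
#' version k of the same identity).
#'
#' @return A \code{prov_graph} object.
#' @export
#' @examples
#' g <- prov_graph()
#' graph_counts(g)
prov_graph <- function() {
  structure(
    list(
      nodes = empty_nodes(),
      edges = empty_edges(),
      insertion_order = character(0)
    ),
    class = "prov_graph"
  )
}

empty_nodes <- function() {
  tibble::tibble(
    node_id = character(0),
    kind = character(0),          # "entity" | "activity" | "agent"
    entity_type = character(0),
    path = character(0),
    version = integer(0),
    activity_type = character(0),
    timestamp = character(0),
    source_event_id = character(0),
    agent_name = character(0),
    agent_version = character(0),
    attributes = list()
  )
}

empty_edges <- function() {
  tibble::tibble(
    kind = character(0),          # USED | GENERATED_BY | ASSOCIATED_WITH | REVISION_OF
    from = character(0),
    to = character(0),
    origin = character(0)         # "auto" | "manual"
  )
}

edge_kinds <- function() c("USED", "GENERATED_BY", "ASSOCIATED_WITH", "REVISION_OF")

# legal (source kind, target kind) per edge kind
.edge_typing <- list(
  USED = c("activity", "entity"),
  GENERATED_BY = c("entity", "activity"),
  ASSOCIATED_WITH = c("activity", "agent"),
  REVISION_OF = c("entity", "entity")
)

#' @export
print.prov_graph <- function(x, ...) {
  n <- graph_counts(x)
  cat(sprintf(
    "<prov_graph: %d entity version(s), %d activity(ies), %d agent(s), %d edge(s)>\n",
    n[["entities"]], n[["activities"]], n[["agents"]], n[["edges"]]
  ))
  invisible(x)
}

#' Node and edge counts of a provenance graph
#'
#' @param graph A \code{prov_graph}.
#' @return Named integer vector: entities, activities, agents, and edge
#'   counts overall and per kind.
#' @export
graph_counts <- function(graph) {
  stopifnot(inherits(graph, "prov_graph"))
  kinds <- graph$nodes$kind
  ek <- graph$edges$kind
  c(
    entities = sum(kinds == "entity"),
    activities = sum(kinds == "activity"),
    agents = sum(kinds == "agent"),
    edges = nrow(graph$edges),
    used = sum(ek == "USED"),
    generated_by = sum(ek == "GENERATED_BY"),
    associated_with = sum(ek == "ASSOCIATED_WITH"),
    revision_of = sum(ek == "REVISION_OF")
  )
}

#' Graph nodes or edges as a tibble
#'
#' @param x A \code{prov_graph}.
#' @param what \code{"nodes"} or \code{"edges"}.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.prov_graph <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  x[[what]]
}

node_row <- function(graph, node_id) {
  i <- match(node_id, graph$nodes$node_id)
  if (is.na(i)) NULL else graph$nodes[i, ]
}

has_node <- function(graph, node_id) node_id %in% graph$nodes$node_id

node_kind <- function(graph, node_id) {
  i <- match(node_id, graph$nodes$node_id)
  if (is.na(i)) NA_character_ else graph$nodes$kind[i]
}

add_node_rows <- function(graph, rows) {
  graph$nodes <- dplyr::bind_rows(graph$nodes, rows)
  graph
}

#' Resolve the latest version of an entity identity
#'
#' When a new activity references a product already in the graph, its
#' dependency attaches to the latest version of that product. Returns the
#' entity-version row with maximal version number for the identity, or
#' \code{NULL} when no version exists (absence is a value, not an error).
#'
#' @param graph A \code{prov_graph}.
#' @param identity An \code{\link{entity_identity}}.
#' @return One-row tibble (the latest version's node row) or \code{NULL}.
#' @export
resolve_latest <- function(graph, identity) {
  stopifnot(inherits(graph, "prov_graph"), inherits(identity, "entity_identity"))
  hit <- graph$nodes[
    graph$nodes$kind == "entity" &
      graph$nodes$entity_type == identity$entity_type &
      graph$nodes$path == identity$path, ,
    drop = FALSE
  ]
  if (nrow(hit) == 0L) return(NULL)
  hit[which.max(hit$version), ]
}

# igraph over the dependency edges (all kinds), used for cycle checks and
# reachability. Isolated nodes are included so vertex ids resolve.
as_igraph <- function(graph, edges = graph$edges) {
  igraph::graph_from_data_frame(
    d = data.frame(from = edges$from, to = edges$to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$node_id, stringsAsFactors = FALSE)
  )
}

graph_is_acyclic <- function(graph) {
  if (nrow(graph$edges) == 0L) return(TRUE)
  igraph::is_dag(as_igraph(graph))
}

# TRUE iff `to` is reachable from `from` along directed edges.
is_reachable <- function(graph, from, to) {
  if (from == to) return(TRUE)
  if (nrow(graph$edges) == 0L) return(FALSE)
  ig <- as_igraph(graph)
  to %in% names(igraph::subcomponent(ig, from, mode = "out"))
}

#' Add a typed dependency edge with cycle and typing checks
#'
#' The graph invariant is acyclicity: an edge is added only if no directed
#' cycle results, and edge endpoints must respect the kind typing
#' (\code{USED}: activity to entity; \code{GENERATED_BY}: entity to activity;
#' \code{ASSOCIATED_WITH}: activity to agent; \code{REVISION_OF}: entity to
#' entity of the same identity). On rejection the input graph is returned
#' unchanged by R's copy semantics; the error is classed.
#'
#' @param graph A \code{prov_graph}.
#' @param kind Edge kind.
#' @param from,to Endpoint node ids (must exist).
#' @param origin \code{"auto"} or \code{"manual"}.
#' @return The graph with the edge added.
#' @export
add_edge_checked <- function(graph, kind, from, to, origin = "auto") {
  stopifnot(inherits(graph, "prov_graph"))
  if (!kind %in% edge_kinds()) {
    stop_simprov("typing", sprintf("unknown edge kind '%s'", kind))
  }
  if (!has_node(graph, from)) stop_simprov("unknown_node", sprintf("no node '%s'", from))
  if (!has_node(graph, to)) stop_simprov("unknown_node", sprintf("no node '%s'", to))
  want <- .edge_typing[[kind]]
  got <- c(node_kind(graph, from), node_kind(graph, to))
  if (!identical(want, got)) {
    stop_simprov("typing", sprintf(
      "%s edge must run %s -> %s, got %s -> %s", kind, want[1], want[2], got[1], got[2]
    ))
  }
  if (kind == "REVISION_OF") {
    a <- node_row(graph, from)
    b <- node_row(graph, to)
    if (a$entity_type != b$entity_type || a$path != b$path) {
      stop_simprov("typing", "REVISION_OF must link versions of the same identity")
    }
  }
  dup <- graph$edges$kind == kind & graph$edges$from == from & graph$edges$to == to
  if (any(dup)) {
    warn_simprov("duplicate_edge", sprintf("edge %s %s -> %s already present", kind, from, to))
    return(graph)
  }
  # adding from -> to closes a cycle iff `from` is already reachable from `to`
  if (is_reachable(graph, to, from)) {
    stop_simprov("cycle", sprintf("edge %s -> %s would create a cycle", from, to))
  }
  graph$edges <- dplyr::bind_rows(
    graph$edges,
    tibble::tibble(kind = kind, from = from, to = to, origin = origin)
  )
  graph
}

# Structural validity: acyclicity, edge typing, gapless version chains with
# REVISION_OF paths, single generating activity per version.
#' Check structural invariants of a provenance graph
#'
#' @param graph A \code{prov_graph}.
#' @return Character vector of violation messages; empty when valid.
#' @export
check_graph_invariants <- function(graph) {
  out <- character(0)
  if (!graph_is_acyclic(graph)) out <- c(out, "graph contains a directed cycle")
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    want <- .edge_typing[[e$kind]]
    got <- c(node_kind(graph, e$from), node_kind(graph, e$to))
    if (!identical(want, got)) {
      out <- c(out, sprintf("edge %d (%s) has illegal endpoint kinds", i, e$kind))
    }
  }
  ents <- graph$nodes[graph$nodes$kind == "entity", ]
  if (nrow(ents) > 0L) {
    keys <- split(seq_len(nrow(ents)), identity_key(ents$entity_type, ents$path))
    for (k in names(keys)) {
      vs <- sort(ents$version[keys[[k]]])
      if (!identical(vs, seq_len(length(vs)))) {
        out <- c(out, sprintf("identity %s has version gap: %s", k, paste(vs, collapse = ",")))
      }
    }
    rev <- graph$edges[graph$edges$kind == "REVISION_OF", ]
    for (i in keys) {
      rows <- ents[i, ]
      for (j in seq_len(nrow(rows))) {
        if (rows$version[j] > 1L) {
          prev <- entity_node_id(rows$entity_type[j], rows$path[j], rows$version[j] - 1L)
          ok <- any(rev$from == rows$node_id[j] & rev$to == prev)
          if (!ok) out <- c(out, sprintf("%s lacks REVISION_OF to its predecessor", rows$node_id[j]))
        }
      }
    }
  }
  gb <- graph$edges[graph$edges$kind == "GENERATED_BY", ]
  if (nrow(gb) > 0L) {
    n_gen <- table(gb$from)
    multi <- names(n_gen)[n_gen > 1L]
    for (m in multi) out <- c(out, sprintf("%s has %d generating activities", m, n_gen[[m]]))
  }
  out
}

# Incident structure of one activity, in the shape match_activity() expects.
activity_neighbourhood <- function(graph, activity_id) {
  e <- graph$edges
  used_ids <- e$to[e$kind == "USED" & e$from == activity_id]
  gen_ids <- e$from[e$kind == "GENERATED_BY" & e$to == activity_id]
  agent_ids <- e$to[e$kind == "ASSOCIATED_WITH" & e$from == activity_id]
  descr <- function(id) {
    r <- node_row(graph, id)
    attrs <- r$attributes[[1]]
    c(list(entity_type = r$entity_type), as.list(attrs))
  }
  agent <- NULL
  if (length(agent_ids) > 0L) {
    r <- node_row(graph, agent_ids[[1]])
    agent <- list(name = r$agent_name, version = r$agent_version)
  }
  list(
    used = lapply(used_ids, descr),
    generated = lapply(gen_ids, descr),
    agent = agent
  )
}

#' Revalidate a stored graph against a pattern set
#'
#' Audits that every activity node, with its incident \code{USED},
#' \code{GENERATED_BY}, and \code{ASSOCIATED_WITH} edges and the attributes
#' of the touched entity versions, still matches its provenance pattern.
#' A freshly built graph revalidates cleanly by construction; hand edits
#' (deleted edges, blanked attributes) surface here.
#'
#' @param graph A \code{prov_graph}.
#' @param patterns A \code{pattern_set} (default: the shipped patterns).
#' @return Tibble of violations (activity node id, code, detail); zero rows
#'   when the graph is valid.
#' @export
revalidate <- function(graph, patterns = default_patterns()) {
  stopifnot(inherits(graph, "prov_graph"))
  acts <- graph$nodes[graph$nodes$kind == "activity", ]
  out <- list()
  for (i in seq_len(nrow(acts))) {
    nb <- activity_neighbourhood(graph, acts$node_id[i])
    m <- match_activity(patterns, acts$activity_type[i], nb$used, nb$generated, nb$agent)
    if (!m$valid) {
      out[[length(out) + 1L]] <- tibble::tibble(
        activity_id = acts$node_id[i],
        code = vapply(m$violations, `[[`, "", "code"),
        detail = vapply(m$violations, `[[`, "", "detail")
      )
    }
  }
  if (length(out) == 0L) {
    tibble::tibble(activity_id = character(0), code = character(0), detail = character(0))
  } else {
    dplyr::bind_rows(out)
  }
}

# internal: set one attribute on a node (no validation; callers check)
set_node_attribute <- function(graph, node_id, key, value) {
  i <- match(node_id, graph$nodes$node_id)
  attrs <- graph$nodes$attributes[[i]]
  attrs[[key]] <- value
  graph$nodes$attributes[[i]] <- attrs
  graph
}
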