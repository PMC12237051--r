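SIMPROV_NS <- "https://simprov.example.org/ns#"
PROV_NS <- "http://www.w3.org/ns/prov#"

named_or_empty <- function(x) {
  if (length(x) == 0L) structure(list(), names = character(0)) else x
}

sorted_attrs <- function(attrs, prefix = "simprov:") {
  if (length(attrs) == 0L) return(list())
  attrs <- attrs[order(names(attrs))]
  stats::setNames(lapply(attrs, as.character), paste0(prefix, names(attrs)))
}

#' Export a provenance graph as PROV-JSON
#'
#' Standard PROV-JSON document with \code{entity}, \code{activity},
#' \code{agent}, \code{used}, \code{wasGeneratedBy}, and
#' \code{wasAssociatedWith} sections. The simulation-study types are encoded
#' as \code{prov:type} values under the \code{simprov:} namespace; entity
#' versioning is carried by \code{simprov:version} plus a custom
#' \code{simprov:revisionOf} relation section; manually added dependencies
#' carry \code{simprov:origin = "manual"}. Key ordering is deterministic, so
#' rebuilding a graph from the same event stream re-exports byte-identically.
#'
#' @param graph A \code{prov_graph}.
#' @return PROV-JSON text.
#' @export
export_prov_json <- function(graph) {
  stopifnot(inherits(graph, "prov_graph"))
  nodes <- graph$nodes
  ent <- nodes[nodes$kind == "entity", ]
  act <- nodes[nodes$kind == "activity", ]
  agn <- nodes[nodes$kind == "agent", ]

  entities <- stats::setNames(lapply(seq_len(nrow(ent)), function(i) {
    c(
      list(
        "prov:type" = paste0("simprov:", ent$entity_type[i]),
        "simprov:version" = ent$version[i]
      ),
      sorted_attrs(ent$attributes[[i]])
    )
  }), ent$node_id)

  activities <- stats::setNames(lapply(seq_len(nrow(act)), function(i) {
    out <- list(
      "prov:type" = paste0("simprov:", act$activity_type[i]),
      "prov:startTime" = act$timestamp[i] %|na|% "",
      "simprov:event_id" = act$source_event_id[i] %|na|% ""
    )
    c(out, sorted_attrs(act$attributes[[i]]))
  }), act$node_id)

  agents <- stats::setNames(lapply(seq_len(nrow(agn)), function(i) {
    out <- list(
      "prov:type" = "prov:SoftwareAgent",
      "simprov:name" = agn$agent_name[i]
    )
    if (!is.na(agn$agent_version[i])) out[["simprov:version"]] <- agn$agent_version[i]
    out
  }), agn$node_id)

  rel_record <- function(e, keys) {
    out <- stats::setNames(list(e$from, e$to), keys)
    if (identical(e$origin, "manual")) out[["simprov:origin"]] <- "manual"
    out
  }
  rel_section <- function(kind, keys, tag) {
    rows <- graph$edges[graph$edges$kind == kind, ]
    if (nrow(rows) == 0L) return(named_or_empty(list()))
    stats::setNames(
      lapply(seq_len(nrow(rows)), function(i) rel_record(rows[i, ], keys)),
      paste0("_:", tag, seq_len(nrow(rows)))
    )
  }

  doc <- list(
    prefix = list(prov = PROV_NS, simprov = SIMPROV_NS),
    entity = named_or_empty(entities),
    activity = named_or_empty(activities),
    agent = named_or_empty(agents),
    used = rel_section("USED", c("prov:activity", "prov:entity"), "u"),
    wasGeneratedBy = rel_section("GENERATED_BY", c("prov:entity", "prov:activity"), "g"),
    wasAssociatedWith = rel_section("ASSOCIATED_WITH", c("prov:activity", "prov:agent"), "a"),
    "simprov:revisionOf" = rel_section("REVISION_OF", c("simprov:newer", "simprov:older"), "r")
  )
  paste0(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)), "\n")
}

`%|na|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

strip_ns <- function(x) sub("^simprov:", "", x)

#' Import a provenance graph from PROV-JSON
#'
#' Reconstructs the typed graph from a document written by
#' \code{\link{export_prov_json}}. The document must declare the
#' \code{simprov} namespace. In strict mode (default) an entity whose
#' \code{prov:type} is outside the enumeration is an error; in permissive
#' mode it is imported as an untyped entity with a warning, and foreign
#' attribute statements are preserved.
#'
#' @param text PROV-JSON text.
#' @param strict Reject unknown entity types.
#' @return A \code{prov_graph}.
#' @export
import_prov_json <- function(text, strict = TRUE) {
  doc <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) stop_simprov("malformed_document", conditionMessage(e))
  )
  if (!is.list(doc) || is.null(doc$prefix) || is.null(doc$prefix$simprov)) {
    stop_simprov("malformed_document", "document does not declare the simprov namespace")
  }
  g <- prov_graph()

  for (id in names(doc$entity %||% list())) {
    rec <- doc$entity[[id]]
    raw_type <- strip_ns(as.character(rec[["prov:type"]] %||% ""))
    et <- tryCatch(parse_entity_type(raw_type), error = function(e) NA_character_)
    if (is.na(et)) {
      if (strict) {
        stop_simprov("unknown_type", sprintf("entity '%s' has unknown type '%s'", id, raw_type))
      }
      warn_simprov("unknown_type", sprintf("importing '%s' as untyped entity", id))
      et <- NA_character_
    }
    akeys <- setdiff(names(rec), c("prov:type", "simprov:version"))
    attrs <- stats::setNames(
      lapply(rec[akeys], as.character),
      sub("^simprov:", "", akeys)
    )
    g <- add_node_rows(g, tibble::tibble(
      node_id = id, kind = "entity",
      entity_type = et,
      path = as.character(attrs$path %||% ""),
      version = as.integer(rec[["simprov:version"]] %||% 1L),
      activity_type = NA_character_, timestamp = NA_character_,
      source_event_id = NA_character_,
      agent_name = NA_character_, agent_version = NA_character_,
      attributes = list(attrs)
    ))
  }

  for (id in names(doc$activity %||% list())) {
    rec <- doc$activity[[id]]
    at <- parse_activity_type(strip_ns(as.character(rec[["prov:type"]] %||% "")))
    akeys <- setdiff(names(rec), c("prov:type", "prov:startTime", "simprov:event_id"))
    attrs <- stats::setNames(lapply(rec[akeys], as.character), sub("^simprov:", "", akeys))
    g <- add_node_rows(g, tibble::tibble(
      node_id = id, kind = "activity",
      entity_type = NA_character_, path = NA_character_, version = NA_integer_,
      activity_type = at,
      timestamp = as.character(rec[["prov:startTime"]] %||% ""),
      source_event_id = as.character(rec[["simprov:event_id"]] %||% ""),
      agent_name = NA_character_, agent_version = NA_character_,
      attributes = list(attrs)
    ))
    g$insertion_order <- c(g$insertion_order, id)
  }

  for (id in names(doc$agent %||% list())) {
    rec <- doc$agent[[id]]
    g <- add_node_rows(g, tibble::tibble(
      node_id = id, kind = "agent",
      entity_type = NA_character_, path = NA_character_, version = NA_integer_,
      activity_type = NA_character_, timestamp = NA_character_,
      source_event_id = NA_character_,
      agent_name = as.character(rec[["simprov:name"]] %||% ""),
      agent_version = if (is.null(rec[["simprov:version"]])) NA_character_ else
        as.character(rec[["simprov:version"]]),
      attributes = list(list())
    ))
  }

  import_rel <- function(g, section, kind, keys) {
    for (rec in doc[[section]] %||% list()) {
      origin <- if (identical(rec[["simprov:origin"]], "manual")) "manual" else "auto"
      g <- add_edge_checked(g, kind, as.character(rec[[keys[1]]]),
                            as.character(rec[[keys[2]]]), origin = origin)
    }
    g
  }
  g <- import_rel(g, "used", "USED", c("prov:activity", "prov:entity"))
  g <- import_rel(g, "wasGeneratedBy", "GENERATED_BY", c("prov:entity", "prov:activity"))
  g <- import_rel(g, "wasAssociatedWith", "ASSOCIATED_WITH", c("prov:activity", "prov:agent"))
  g <- import_rel(g, "simprov:revisionOf", "REVISION_OF", c("simprov:newer", "simprov:older"))
  g
}

# DOT --------------------------------------------------------------------

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a provenance graph as Graphviz DOT
#'
#' Node shapes follow the PROV drawing convention: entities as ellipses,
#' activities as rectangles, agents as house shapes. Manually added
#' dependencies are styled distinctly (dashed, green). Ordering follows the
#' graph's node and edge tables, so output is deterministic.
#'
#' @param graph A \code{prov_graph}.
#' @return DOT source text.
#' @export
export_dot <- function(graph) {
  stopifnot(inherits(graph, "prov_graph"))
  n <- graph$nodes
  lines <- c("digraph provenance {", "  rankdir=BT;")
  for (i in seq_len(nrow(n))) {
    label <- switch(n$kind[i],
      entity = sprintf("%s\\n%s v%d",
                       n$entity_type[i] %|na|% "Entity",
                       (n$attributes[[i]]$name %||% n$path[i]) %|na|% "",
                       n$version[i]),
      activity = n$activity_type[i],
      agent = if (!is.na(n$agent_version[i])) {
        sprintf("%s %s", n$agent_name[i], n$agent_version[i])
      } else {
        n$agent_name[i]
      }
    )
    shape <- switch(n$kind[i], entity = "ellipse", activity = "box", agent = "house")
    lines <- c(lines, sprintf("  %s [shape=%s, label=%s];",
                              dot_quote(n$node_id[i]), shape, dot_quote(label)))
  }
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    style <- if (identical(e$origin[i], "manual")) {
      ' [label="manual", style=dashed, color=forestgreen]'
    } else if (e$kind[i] == "REVISION_OF") {
      ' [style=dotted]'
    } else {
      ""
    }
    lines <- c(lines, sprintf("  %s -> %s%s;",
                              dot_quote(e$from[i]), dot_quote(e$to[i]), style))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

# Transitive reduction ---------------------------------------------------

#' Transitive reduction of an edge list
#'
#' Low-level reduction over a plain directed acyclic edge list: returns the
#' logical keep-mask of edges belonging to the unique transitive reduction
#' (an edge u -> v is redundant iff some other successor of u reaches v).
#'
#' @param from,to Character vectors of endpoint ids (parallel).
#' @param nodes Optional vector of all node ids (for isolated nodes).
#' @return Logical vector, TRUE for edges kept.
#' @export
transitive_reduction_mask <- function(from, to, nodes = NULL) {
  stopifnot(length(from) == length(to))
  if (length(from) == 0L) return(logical(0))
  nodes <- unique(c(nodes, from, to))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(ig)) stop_simprov("cycle", "transitive reduction requires a DAG")
  d <- igraph::distances(ig, mode = "out")
  reach <- is.finite(d)
  succ <- split(to, from)
  keep <- logical(length(from))
  for (i in seq_along(from)) {
    ws <- setdiff(succ[[from[i]]], to[i])
    keep[i] <- !any(reach[ws, to[i]])
  }
  keep
}

#' Transitive reduction of a provenance graph
#'
#' Removes every dependency edge whose endpoints stay connected through a
#' longer path, yielding the unique minimal edge set with the same
#' reachability relation. \code{REVISION_OF} edges are exempt: version
#' chains are semantic, not redundancy, and are kept verbatim (they still
#' contribute to the reachability other edges are tested against).
#'
#' @param graph A \code{prov_graph}.
#' @return A reduced \code{prov_graph} (class \code{prov_reduced}); the
#'   number of removed edges is in attribute \code{"removed_edges"}.
#' @export
transitive_reduce <- function(graph) {
  stopifnot(inherits(graph, "prov_graph"))
  e <- graph$edges
  keep <- transitive_reduction_mask(e$from, e$to, nodes = graph$nodes$node_id)
  keep <- keep | e$kind == "REVISION_OF"
  out <- graph
  out$edges <- e[keep, ]
  class(out) <- unique(c("prov_reduced", class(graph)))
  attr(out, "removed_edges") <- sum(!keep)
  out
}

# Chain aggregation ------------------------------------------------------

# Link relation between same-type activities: a and b are chain-linked iff
# they generate consecutive versions of the same identity (with only
# same-type activities generating the versions in between -- which the
# consecutive-pair formulation enforces transitively), or b directly uses a
# version generated by a.
chain_links <- function(graph) {
  acts <- graph$nodes[graph$nodes$kind == "activity", ]
  if (nrow(acts) == 0L) return(NULL)
  type_of <- stats::setNames(acts$activity_type, acts$node_id)
  e <- graph$edges
  gb <- e[e$kind == "GENERATED_BY", ]         # entity -> activity
  gen_by <- stats::setNames(gb$to, gb$from)   # entity id -> generating activity
  links <- list()
  add_link <- function(a, b) {
    if (!is.na(type_of[a]) && identical(type_of[[a]], type_of[[b]]) && a != b) {
      links[[length(links) + 1L]] <<- c(a, b)
    }
  }
  # consecutive generators of one identity
  ents <- graph$nodes[graph$nodes$kind == "entity", ]
  if (nrow(ents) > 0L) {
    for (rows in split(seq_len(nrow(ents)), identity_key(ents$entity_type, ents$path))) {
      rows <- rows[order(ents$version[rows])]
      ids <- ents$node_id[rows]
      gens <- unname(gen_by[ids])
      for (i in seq_len(length(gens) - 1L)) {
        a <- gens[i]; b <- gens[i + 1L]
        if (!is.na(a) && !is.na(b)) add_link(a, b)
      }
    }
  }
  # generated-then-used
  used <- e[e$kind == "USED", ]
  for (i in seq_len(nrow(used))) {
    a <- gen_by[used$to[i]]
    if (!is.na(a)) add_link(unname(a), used$from[i])
  }
  links
}

#' Aggregate chains of same-type activities
#'
#' Collapses maximal chains of activities of the same type -- linked
#' through the entity versions they successively generate (revision chains)
#' or through generated-then-used entities, with no activity of another type
#' interleaved on the linking path -- into one aggregate activity each. The
#' aggregate inherits the union of the members' external \code{USED} edges,
#' the final generated version of each touched identity (intermediate
#' versions are elided from the view; the underlying graph is untouched),
#' and all member agents. This turns a long edit-run-analyze iteration log
#' into a coarse per-phase overview.
#'
#' @param graph A \code{prov_graph}.
#' @return A reduced \code{prov_graph} (class \code{prov_reduced});
#'   aggregate membership is available via \code{\link{aggregate_info}}.
#' @export
aggregate_chains <- function(graph) {
  stopifnot(inherits(graph, "prov_graph"))
  links <- chain_links(graph)
  acts <- graph$nodes$node_id[graph$nodes$kind == "activity"]
  ig <- igraph::graph_from_data_frame(
    d = if (length(links) == 0L) {
      data.frame(from = character(0), to = character(0))
    } else {
      as.data.frame(do.call(rbind, links), stringsAsFactors = FALSE) |>
        stats::setNames(c("from", "to"))
    },
    directed = FALSE,
    vertices = data.frame(name = acts, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(ig)
  groups <- split(names(comp$membership), comp$membership)
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  # order members by insertion; aggregate id from the first member
  groups <- lapply(groups, function(g) g[order(match(g, graph$insertion_order))])

  node_map <- stats::setNames(graph$nodes$node_id, graph$nodes$node_id)
  agg_rows <- list()
  for (g in groups) {
    first <- g[[1]]
    agg_id <- paste0("aggregate:", first)
    node_map[g] <- agg_id
    frow <- node_row(graph, first)
    # elide intermediate member-generated versions per identity
    e <- graph$edges
    gb <- e[e$kind == "GENERATED_BY" & e$to %in% g, ]
    gen_versions <- graph$nodes[match(gb$from, graph$nodes$node_id), ]
    if (nrow(gen_versions) > 0L) {
      for (rows in split(seq_len(nrow(gen_versions)),
                         identity_key(gen_versions$entity_type, gen_versions$path))) {
        ids <- gen_versions$node_id[rows]
        final <- ids[which.max(gen_versions$version[rows])]
        node_map[setdiff(ids, final)] <- final
      }
    }
    agg_rows[[agg_id]] <- tibble::tibble(
      node_id = agg_id, kind = "activity",
      entity_type = NA_character_, path = NA_character_, version = NA_integer_,
      activity_type = frow$activity_type, timestamp = frow$timestamp,
      source_event_id = NA_character_,
      agent_name = NA_character_, agent_version = NA_character_,
      attributes = list(list(
        member_activity_ids = g,
        count = length(g)
      ))
    )
  }
  if (length(agg_rows) == 0L) {
    out <- graph
    class(out) <- unique(c("prov_reduced", class(graph)))
    return(out)
  }

  # rebuild nodes: first member occurrence becomes the aggregate; other
  # mapped-away nodes drop
  new_nodes <- list()
  seen <- character(0)
  for (i in seq_len(nrow(graph$nodes))) {
    id <- graph$nodes$node_id[i]
    mapped <- node_map[[id]]
    if (mapped %in% seen) next
    seen <- c(seen, mapped)
    if (mapped == id) {
      new_nodes[[length(new_nodes) + 1L]] <- graph$nodes[i, ]
    } else if (startsWith(mapped, "aggregate:")) {
      new_nodes[[length(new_nodes) + 1L]] <- agg_rows[[mapped]]
    } else {
      new_nodes[[length(new_nodes) + 1L]] <- graph$nodes[graph$nodes$node_id == mapped, ]
    }
  }
  out <- graph
  out$nodes <- dplyr::bind_rows(new_nodes)
  e <- graph$edges
  e$from <- unname(node_map[e$from])
  e$to <- unname(node_map[e$to])
  e <- e[e$from != e$to, ]
  e <- e[!duplicated(e[, c("kind", "from", "to")]), ]
  out$edges <- e
  io <- unname(node_map[graph$insertion_order])
  out$insertion_order <- io[!duplicated(io)]
  class(out) <- unique(c("prov_reduced", class(graph)))
  attr(out, "node_map") <- node_map
  out
}

#' Aggregate metadata of a reduced graph
#'
#' @param graph A \code{prov_reduced} from \code{\link{aggregate_chains}}.
#' @return Tibble with one row per aggregate activity: id, type, member
#'   count, and member activity ids (list column). Non-aggregated graphs
#'   yield zero rows.
#' @export
aggregate_info <- function(graph) {
  stopifnot(inherits(graph, "prov_graph"))
  idx <- which(startsWith(graph$nodes$node_id, "aggregate:"))
  tibble::tibble(
    aggregate_id = graph$nodes$node_id[idx],
    activity_type = graph$nodes$activity_type[idx],
    count = vapply(graph$nodes$attributes[idx], function(a) as.integer(a$count), 0L),
    member_activity_ids = lapply(graph$nodes$attributes[idx], `[[`, "member_activity_ids")
  )
}
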