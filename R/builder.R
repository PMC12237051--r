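#' Parse a provenance event from JSON
#'
#' One captured modeler action, serialized as key-value JSON. Recognised
#' top-level keys are \code{event_id}, \code{event_type} (snake_case
#' activity type, e.g. \code{"executing_simulation_experiment"}),
#' \code{timestamp}, \code{agent} (\code{{name, version}}), \code{used} and
#' \code{generated} (lists of entity descriptors with at least
#' \code{entity_type}, \code{name}, \code{path}); any other keys are
#' preserved in \code{extras}.
#'
#' @param json_text JSON source text.
#' @return A \code{prov_event}.
#' @export
parse_event <- function(json_text) {
  parsed <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) stop_simprov("malformed_json", paste("malformed JSON:", conditionMessage(e)))
  )
  if (!is.list(parsed) || is.null(names(parsed))) {
    stop_simprov("malformed_json", "event must be a JSON object")
  }
  event_from_list(parsed)
}

event_from_list <- function(parsed) {
  for (key in c("event_id", "event_type")) {
    if (is.null(parsed[[key]]) || !nzchar(as.character(parsed[[key]]))) {
      stop_simprov("missing_field", sprintf("event lacks required field '%s'", key))
    }
  }
  if (is.null(parsed$generated)) {
    stop_simprov("missing_field", "event lacks required field 'generated'")
  }
  std <- c("event_id", "event_type", "timestamp", "agent", "used", "generated")
  extras <- parsed[setdiff(names(parsed), std)]
  structure(
    list(
      event_id = as.character(parsed$event_id),
      event_type = as.character(parsed$event_type),
      timestamp = as.character(parsed$timestamp %||% ""),
      agent = parsed$agent,
      used = lapply(parsed$used %||% list(), as.list),
      generated = lapply(parsed$generated %||% list(), as.list),
      extras = extras
    ),
    class = "prov_event"
  )
}

#' Construct a provenance event in code
#'
#' Convenience constructor used by the capturer SDK and the fixture
#' generators; produces the same structure as \code{\link{parse_event}}.
#'
#' @param event_id Unique id (capturers use UUIDs; any unique string works).
#' @param event_type snake_case activity type.
#' @param agent Named list with \code{name} and optional \code{version}.
#' @param used,generated Lists of entity descriptors.
#' @param timestamp ISO-8601 instant.
#' @param extras Open key-value list.
#' @return A \code{prov_event}.
#' @export
prov_event <- function(event_id, event_type, agent, used = list(),
                       generated = list(), timestamp = "", extras = list()) {
  structure(
    list(
      event_id = event_id, event_type = event_type, timestamp = timestamp,
      agent = agent, used = used, generated = generated, extras = extras
    ),
    class = "prov_event"
  )
}

#' @export
print.prov_event <- function(x, ...) {
  cat(sprintf(
    "<prov_event %s: %s, %d used, %d generated>\n",
    x$event_id, x$event_type, length(x$used), length(x$generated)
  ))
  invisible(x)
}

event_to_list <- function(event) {
  out <- list(
    event_id = event$event_id,
    event_type = event$event_type,
    timestamp = event$timestamp,
    agent = event$agent,
    used = event$used,
    generated = event$generated
  )
  c(out, event$extras)
}

#' Serialize an event to JSON
#'
#' @param event A \code{prov_event}.
#' @return JSON text (single line).
#' @export
event_to_json <- function(event) {
  as.character(jsonlite::toJSON(event_to_list(event), auto_unbox = TRUE, null = "null"))
}

#' Read / write JSONL event logs
#'
#' Offline ingestion uses JSON-Lines files: one event object per line.
#'
#' @param path File path.
#' @return \code{read_events_jsonl}: list of \code{prov_event}.
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_event)
}

#' @rdname read_events_jsonl
#' @param events List of \code{prov_event}.
#' @export
write_events_jsonl <- function(events, path) {
  writeLines(vapply(events, event_to_json, ""), path)
  invisible(path)
}

# Builder state ----------------------------------------------------------

#' Create a provenance builder
#'
#' The builder accepts events, validates each against the pattern set, and
#' chains valid activities into the single provenance graph; rejected events
#' are kept verbatim in an error log for inspection.
#'
#' @param patterns A \code{pattern_set}; defaults to the shipped patterns.
#' @return A \code{prov_builder} state object.
#' @export
#' @examples
#' b <- prov_builder()
#' b <- ingest_stream(b, fig2_stream())
#' graph_counts(b$graph)
prov_builder <- function(patterns = default_patterns()) {
  structure(
    list(
      graph = prov_graph(),
      patterns = patterns,
      error_log = list(),
      processed_event_ids = character(0)
    ),
    class = "prov_builder"
  )
}

#' @export
print.prov_builder <- function(x, ...) {
  cat(sprintf(
    "<prov_builder: %d event(s) processed, %d rejected>\n",
    length(x$processed_event_ids), length(x$error_log)
  ))
  print(x$graph)
  invisible(x)
}

#' Ingest one event
#'
#' Validates the event's activity against its provenance pattern; when valid
#' the activity with its entities, agent, and dependencies is chained into
#' the graph, otherwise the whole event is discarded (the graph is left
#' untouched) and an error-log record is appended. Either way the event id
#' is marked processed; replaying an already-processed id is an error and
#' changes nothing, making at-least-once delivery safe.
#'
#' @param state A \code{prov_builder}.
#' @param event A \code{prov_event}.
#' @return The updated \code{prov_builder}.
#' @export
ingest_event <- function(state, event) {
  stopifnot(inherits(state, "prov_builder"), inherits(event, "prov_event"))
  if (event$event_id %in% state$processed_event_ids) {
    stop_simprov("duplicate_event", sprintf("event '%s' already processed", event$event_id))
  }
  m <- match_activity(
    state$patterns, event$event_type,
    used = event$used, generated = event$generated, agent = event$agent
  )
  if (m$valid) {
    res <- tryCatch(chain(state$graph, event), simprov_error = function(e) e)
    if (inherits(res, "condition")) {
      m <- match_result(list(violation("cycle", conditionMessage(res))))
    } else {
      state$graph <- res
    }
  }
  if (!m$valid) {
    state$error_log[[length(state$error_log) + 1L]] <- list(
      event = event,
      violations = m$violations,
      received_at = event$timestamp
    )
  }
  state$processed_event_ids <- c(state$processed_event_ids, event$event_id)
  state
}

#' Ingest a stream of events in order
#'
#' @param state A \code{prov_builder}.
#' @param events List of \code{prov_event} (processed strictly in order).
#' @param quiet Suppress per-event outcome messages.
#' @return The updated \code{prov_builder}.
#' @export
ingest_stream <- function(state, events, quiet = TRUE) {
  for (ev in events) {
    before <- length(state$error_log)
    state <- ingest_event(state, ev)
    if (!quiet) {
      outcome <- if (length(state$error_log) > before) "rejected" else "accepted"
      message(sprintf("event %s (%s): %s", ev$event_id, ev$event_type, outcome))
    }
  }
  state
}

#' Error log as a tibble
#'
#' @param state A \code{prov_builder}.
#' @return Tibble with one row per rejected event: event id, type, and the
#'   concatenated violation codes and details.
#' @export
error_log <- function(state) {
  stopifnot(inherits(state, "prov_builder"))
  if (length(state$error_log) == 0L) {
    return(tibble::tibble(
      event_id = character(0), event_type = character(0),
      codes = character(0), details = character(0)
    ))
  }
  tibble::tibble(
    event_id = vapply(state$error_log, function(r) r$event$event_id, ""),
    event_type = vapply(state$error_log, function(r) r$event$event_type, ""),
    codes = vapply(state$error_log, function(r) {
      paste(vapply(r$violations, `[[`, "", "code"), collapse = ";")
    }, ""),
    details = vapply(state$error_log, function(r) {
      paste(vapply(r$violations, `[[`, "", "detail"), collapse = "; ")
    }, "")
  )
}

# Chaining ---------------------------------------------------------------

# Attribute map of a descriptor: everything except entity_type, with content
# capped at the configured size (hash fallback keeps large payloads out of
# the graph).
descriptor_attributes <- function(d) {
  attrs <- d[setdiff(names(d), "entity_type")]
  attrs <- attrs[!vapply(attrs, is.null, logical(1))]
  attrs <- lapply(attrs, as.character)
  limit <- getOption("simprov.content_limit", 1048576L)
  if (!is.null(attrs$content) && nchar(attrs$content, type = "bytes") > limit) {
    attrs$content_hash <- attrs$content_hash %||% hash_content(attrs$content)
    attrs$content <- NULL
  }
  attrs
}

new_entity_row <- function(entity_type, path, version, attrs) {
  tibble::tibble(
    node_id = entity_node_id(entity_type, path, version),
    kind = "entity",
    entity_type = entity_type,
    path = path,
    version = as.integer(version),
    activity_type = NA_character_,
    timestamp = NA_character_,
    source_event_id = NA_character_,
    agent_name = NA_character_,
    agent_version = NA_character_,
    attributes = list(attrs)
  )
}

#' Chain a validated event into the graph
#'
#' Inserts the event's activity node (an activity is always new), resolves
#' each used descriptor to the latest version of its identity (creating
#' version 1 for products that exist outside the graph, e.g. hand-written
#' conceptual files), creates the next version for each generated descriptor
#' whose identity already exists (linked to its predecessor by a
#' \code{REVISION_OF} edge), resolves or creates the agent, and wires the
#' \code{USED}/\code{GENERATED_BY}/\code{ASSOCIATED_WITH} edges. Acyclicity
#' is preserved by construction and checked on every edge.
#'
#' @param graph A \code{prov_graph}.
#' @param event A \code{prov_event} already validated against its pattern.
#' @return The extended graph.
#' @export
chain <- function(graph, event) {
  stopifnot(inherits(graph, "prov_graph"), inherits(event, "prov_event"))
  at <- parse_activity_type(event$event_type)
  aid <- activity_node_id(event$event_id)
  if (has_node(graph, aid)) {
    stop_simprov("duplicate_event", sprintf("activity for event '%s' already in graph", event$event_id))
  }
  graph <- add_node_rows(graph, tibble::tibble(
    node_id = aid, kind = "activity",
    entity_type = NA_character_, path = NA_character_, version = NA_integer_,
    activity_type = at, timestamp = event$timestamp,
    source_event_id = event$event_id,
    agent_name = NA_character_, agent_version = NA_character_,
    attributes = list(as_extras_attrs(event$extras))
  ))
  graph$insertion_order <- c(graph$insertion_order, aid)

  # used: attach to latest version; bootstrap version 1 when absent
  for (d in event$used) {
    et <- parse_entity_type(d$entity_type)
    p <- canonical_path(d$path)
    latest <- resolve_latest(graph, entity_identity(et, p))
    if (is.null(latest)) {
      attrs <- descriptor_attributes(d)
      attrs$path <- p
      graph <- add_node_rows(graph, new_entity_row(et, p, 1L, attrs))
      target <- entity_node_id(et, p, 1L)
    } else {
      target <- latest$node_id
    }
    graph <- add_edge_checked(graph, "USED", aid, target)
  }

  # generated: next version of an existing identity, else version 1
  for (d in event$generated) {
    et <- parse_entity_type(d$entity_type)
    p <- canonical_path(d$path)
    latest <- resolve_latest(graph, entity_identity(et, p))
    v <- if (is.null(latest)) 1L else latest$version + 1L
    attrs <- descriptor_attributes(d)
    attrs$path <- p
    graph <- add_node_rows(graph, new_entity_row(et, p, v, attrs))
    nid <- entity_node_id(et, p, v)
    if (v > 1L) {
      graph <- add_edge_checked(graph, "REVISION_OF", nid, latest$node_id)
    }
    graph <- add_edge_checked(graph, "GENERATED_BY", nid, aid)
  }

  # agent: resolved-or-created on (name, version)
  if (!is.null(event$agent)) {
    aname <- as.character(event$agent$name)
    aver <- if (is.null(event$agent$version)) NA_character_ else as.character(event$agent$version)
    gid <- agent_node_id(aname, if (is.na(aver)) NULL else aver)
    if (!has_node(graph, gid)) {
      graph <- add_node_rows(graph, tibble::tibble(
        node_id = gid, kind = "agent",
        entity_type = NA_character_, path = NA_character_, version = NA_integer_,
        activity_type = NA_character_, timestamp = NA_character_,
        source_event_id = NA_character_,
        agent_name = aname, agent_version = aver,
        attributes = list(list())
      ))
    }
    graph <- add_edge_checked(graph, "ASSOCIATED_WITH", aid, gid)
  }
  graph
}

as_extras_attrs <- function(extras) {
  if (length(extras) == 0L) return(list())
  flat <- extras[vapply(extras, function(x) is.atomic(x) && length(x) == 1L, logical(1))]
  lapply(flat, as.character)
}

# Manual completion edits ------------------------------------------------

#' Add a manual dependency
#'
#' Some relations cannot be inferred from events (e.g. a copied-and-adapted
#' model's link to its source); the modeler adds them by hand. The edge
#' passes the same cycle and typing checks as automatic edges and is flagged
#' with origin \code{"manual"} in exports. Duplicating an existing edge is a
#' warning no-op.
#'
#' @param state A \code{prov_builder}.
#' @param activity_id Activity node id (edge source).
#' @param entity_node_id Entity-version node id (edge target).
#' @param kind Edge kind; only \code{"USED"} is supported.
#' @return Updated \code{prov_builder}.
#' @export
add_manual_dependency <- function(state, activity_id, entity_node_id, kind = "USED") {
  stopifnot(inherits(state, "prov_builder"))
  kind <- match.arg(kind, "USED")
  state$graph <- add_edge_checked(state$graph, kind, activity_id, entity_node_id,
                                  origin = "manual")
  state
}

#' Fill a missing node attribute
#'
#' Attributes the capturer could not extract (a blank specification, say)
#' can be supplied after the fact. Required attributes (\code{name},
#' \code{path}) must stay non-empty.
#'
#' @param state A \code{prov_builder}.
#' @param node_id Node id.
#' @param key Attribute key.
#' @param value Attribute value (character scalar).
#' @return Updated \code{prov_builder}.
#' @export
fill_attribute <- function(state, node_id, key, value) {
  stopifnot(inherits(state, "prov_builder"), is.character(key), length(key) == 1L)
  if (!has_node(state$graph, node_id)) {
    stop_simprov("unknown_node", sprintf("no node '%s'", node_id))
  }
  value <- as.character(value)
  if (key %in% c("name", "path") && !nzchar(value)) {
    stop_simprov("invalid_value", sprintf("required attribute '%s' must be non-empty", key))
  }
  state$graph <- set_node_attribute(state$graph, node_id, key, value)
  state
}
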