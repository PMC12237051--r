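#' Open a capture session
#'
#' A capture session is the reference provenance capturer: it mirrors the
#' contract of an editor plugin (create typed entity files, detect edits by
#' content hash, emit \code{specifying_*} events) and of an
#' execution-wrapping utility library (run an experiment, collect its
#' output, emit an \code{executing_*}/\code{analyzing_*} event). Every
#' emitted event carries the session agent; events are collected in the
#' session and, when \code{sink} is a file path, appended to that JSONL file.
#'
#' @param agent_name Name of the software agent (e.g. the editor or runtime).
#' @param agent_version Optional agent version string.
#' @param sink Optional path of a JSONL file to append events to.
#' @return A \code{capture_session} (mutable).
#' @export
#' @examples
#' s <- capture_session("vscode", "1.90")
#' register_entity(s, "assumption_uniform.md", "Assumption", "uniform distribution")
#' length(session_events(s))
capture_session <- function(agent_name, agent_version = NULL, sink = NULL) {
  env <- new.env(parent = emptyenv())
  env$agent <- list(name = agent_name, version = agent_version)
  env$sink <- sink
  env$tracked <- list()   # path -> list(identity, last_content_hash, used_ids)
  env$events <- list()
  env$counter <- 0L
  structure(env, class = "capture_session")
}

#' @export
print.capture_session <- function(x, ...) {
  cat(sprintf(
    "<capture_session %s: %d tracked file(s), %d event(s)>\n",
    x$agent$name, length(x$tracked), length(x$events)
  ))
  invisible(x)
}

#' Events emitted so far in a session
#'
#' @param session A \code{capture_session}.
#' @return List of \code{prov_event} in emission order.
#' @export
session_events <- function(session) session$events

next_event_id <- function(session) {
  session$counter <- session$counter + 1L
  sprintf("%s-%04d", session$agent$name, session$counter)
}

emit <- function(session, event) {
  session$events[[length(session$events) + 1L]] <- event
  if (!is.null(session$sink)) {
    cat(event_to_json(event), "\n", sep = "", file = session$sink, append = TRUE)
  }
  event
}

identity_descriptor <- function(id) {
  list(entity_type = id$entity_type, name = id$name %||% basename(id$path), path = id$path)
}

#' Register a new typed entity file
#'
#' The editor-plugin contract: the modeler creates a file of an explicit
#' entity type (the command palette's role), optionally selecting existing
#' conceptual-model entities it is based on. Emits a
#' \code{specifying_<entity>} event generating version 1 and starts tracking
#' the file for edits.
#'
#' @param session A \code{capture_session}.
#' @param path File path (canonicalized; identity key with the type).
#' @param entity_type Entity type label.
#' @param name Human-readable name; defaults to the file name.
#' @param used List of \code{\link{entity_identity}} the new product is
#'   based on.
#' @param content Initial file content (hashed for edit detection).
#' @return The emitted \code{prov_event}, invisibly.
#' @export
register_entity <- function(session, path, entity_type, name = basename(path),
                            used = list(), content = "") {
  stopifnot(inherits(session, "capture_session"))
  et <- parse_entity_type(entity_type)
  p <- canonical_path(path)
  if (!is.null(session$tracked[[p]])) {
    stop_simprov("duplicate_registration", sprintf("path '%s' is already tracked", p))
  }
  session$tracked[[p]] <- list(
    identity = entity_identity(et, p, name),
    last_content_hash = hash_content(content),
    used_ids = used
  )
  event <- prov_event(
    event_id = next_event_id(session),
    event_type = paste0("specifying_", camel_to_snake(et)),
    agent = session$agent,
    used = lapply(used, identity_descriptor),
    generated = list(list(
      entity_type = et, name = name, path = p,
      content = content, content_hash = hash_content(content)
    )),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  invisible(emit(session, event))
}

#' Detect an edit of a tracked file
#'
#' An edit event is emitted iff the content hash changed: re-saving
#' identical content produces no spurious version. The event re-declares the
#' used entities chosen at registration (patterns that require them stay
#' satisfied) and carries the new content plus the previous hash in extras.
#'
#' @param session A \code{capture_session}.
#' @param path A tracked path.
#' @param new_content The saved content.
#' @return The emitted \code{prov_event}, or \code{NULL} when unchanged.
#' @export
detect_edit <- function(session, path, new_content) {
  stopifnot(inherits(session, "capture_session"))
  p <- canonical_path(path)
  tf <- session$tracked[[p]]
  if (is.null(tf)) stop_simprov("unknown_file", sprintf("path '%s' is not tracked", p))
  h <- hash_content(new_content)
  if (identical(h, tf$last_content_hash)) return(NULL)
  old_hash <- tf$last_content_hash
  session$tracked[[p]]$last_content_hash <- h
  id <- tf$identity
  event <- prov_event(
    event_id = next_event_id(session),
    event_type = paste0("specifying_", camel_to_snake(id$entity_type)),
    agent = session$agent,
    used = lapply(tf$used_ids, identity_descriptor),
    generated = list(list(
      entity_type = id$entity_type, name = id$name %||% basename(p), path = p,
      content = new_content, content_hash = h
    )),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    extras = list(previous_content_hash = old_hash)
  )
  invisible(emit(session, event))
}

#' Wrap an experiment (or analysis) execution
#'
#' The utility-library contract: the modeler's run function does the actual
#' work; the wrapper collects the experiment and model paths, runs it,
#' fingerprints the declared output file, and emits an
#' \code{executing_simulation_experiment} (or
#' \code{analyzing_simulation_data}) event. A failing run still emits the
#' event, flagged failed, with an empty output descriptor -- the failed
#' iteration stays visible in the provenance graph.
#'
#' @param session A \code{capture_session}.
#' @param experiment_path Path of the experiment (or analysis script) file.
#' @param model_path Path of the simulation model the run uses (for
#'   analysis runs: the simulation-data input path).
#' @param output_path Path the run writes its output to.
#' @param run_callable Zero-argument function performing the run.
#' @param activity \code{"executing_simulation_experiment"} or
#'   \code{"analyzing_simulation_data"}.
#' @param used_extra Additional entity descriptors to declare as used.
#' @return List with \code{result} (the callable's value, or the condition
#'   on failure), \code{failed}, and \code{event}.
#' @export
wrap_execution <- function(session, experiment_path, model_path, output_path,
                           run_callable,
                           activity = "executing_simulation_experiment",
                           used_extra = list()) {
  stopifnot(inherits(session, "capture_session"), is.function(run_callable))
  used_types <- if (identical(activity, "executing_simulation_experiment")) {
    c("SimulationExperiment", "SimulationModel")
  } else {
    c("Script", "SimulationData")
  }
  out_type <- if (identical(activity, "executing_simulation_experiment")) {
    "SimulationData"
  } else {
    "Visualization"
  }
  res <- tryCatch(run_callable(), error = function(e) e)
  failed <- inherits(res, "error")
  out_path <- canonical_path(output_path)
  output <- list(entity_type = out_type, name = basename(out_path), path = out_path)
  if (!failed && file.exists(output_path)) {
    content <- paste(readLines(output_path, warn = FALSE), collapse = "\n")
    output$content_hash <- hash_content(content)
  } else {
    output$content <- ""          # empty output file of a failed run
    output$content_hash <- hash_content("")
  }
  extras <- list(
    failed = failed,
    r_version = as.character(getRversion())
  )
  if (failed) extras$error <- conditionMessage(res)
  event <- prov_event(
    event_id = next_event_id(session),
    event_type = activity,
    agent = session$agent,
    used = c(
      list(
        list(entity_type = used_types[1], name = basename(experiment_path),
             path = canonical_path(experiment_path)),
        list(entity_type = used_types[2], name = basename(model_path),
             path = canonical_path(model_path))
      ),
      used_extra
    ),
    generated = list(output),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    extras = extras
  )
  emit(session, event)
  list(result = res, failed = failed, event = event)
}

#' Infer an entity type from a file name
#'
#' Applies the naming convention shipped with the package
#' (\code{extdata/naming_conventions.yaml}): a file named
#' \code{<prefix>_*.<ext>} maps to the entity type of the prefix
#' (\code{model_} to SimulationModel, \code{requirement_} to Requirement,
#' ...). No entity type can be identified universally from file names, so
#' an unmatched name returns \code{NA} rather than a guess; the modeler
#' then makes the type explicit.
#'
#' @param path File path.
#' @param conventions Named character vector prefix -> entity type;
#'   defaults to the shipped table.
#' @return Entity type label or \code{NA_character_}.
#' @export
#' @examples
#' infer_entity_type("model_lipoplex.mlr")
#' infer_entity_type("notes.txt")
infer_entity_type <- function(path, conventions = default_conventions()) {
  base <- basename(canonical_path(path))
  prefix <- sub("_.*$", "", base)
  if (prefix == base) return(NA_character_)   # no underscore: no convention
  unname(conventions[prefix]) %|na|% NA_character_
}

#' Shipped naming-convention table
#'
#' @return Named character vector mapping file-name prefixes to entity types.
#' @export
default_conventions <- function() {
  f <- system.file("extdata", "naming_conventions.yaml", package = "simprov")
  tab <- yaml::read_yaml(f)$prefixes
  vapply(tab, function(x) parse_entity_type(x), "")
}
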