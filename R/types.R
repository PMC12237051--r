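#' Entity types of a simulation study
#'
#' The closed set of study products tracked by the provenance model: the
#' conceptual-model resources (research question, requirements, assumptions,
#' qualitative model, data, references), the simulation model and experiment,
#' the simulation data an execution produces, and the postprocessing products
#' (scripts, visualizations).
#'
#' @return Character vector of the eleven entity type labels.
#' @export
#' @examples
#' entity_types()
entity_types <- function() {
  c(
    "ResearchQuestion", "Requirement", "Assumption", "QualitativeModel",
    "Data", "Reference", "SimulationModel", "SimulationExperiment",
    "SimulationData", "Script", "Visualization"
  )
}

#' Activity types of a simulation study
#'
#' The eight modeler activities the provenance patterns cover: specifying
#' each conceptual-model resource, specifying the simulation model and
#' experiment, executing an experiment, and analyzing simulation data.
#'
#' @return Character vector of the eight activity type labels.
#' @export
activity_types <- function() {
  c(
    "SpecifyingReference", "SpecifyingResearchQuestion",
    "SpecifyingRequirement", "SpecifyingAssumption",
    "SpecifyingSimulationModel", "SpecifyingSimulationExperiment",
    "ExecutingSimulationExperiment", "AnalyzingSimulationData"
  )
}

# Aliases accepted at parse time. "Research objective" appears as a synonym
# for the research question in study-reporting vocabularies.
.entity_aliases <- c(
  "ResearchObjective" = "ResearchQuestion",
  "research objective" = "ResearchQuestion",
  "research question" = "ResearchQuestion"
)

#' Parse an entity type label
#'
#' Accepts the canonical CamelCase labels, their snake_case forms, and the
#' "research objective" alias for \code{ResearchQuestion}. Unknown labels are
#' rejected: the enumeration is closed.
#'
#' @param x Character scalar label.
#' @return The canonical entity type label.
#' @export
parse_entity_type <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% entity_types()) return(x)
  if (x %in% names(.entity_aliases)) return(unname(.entity_aliases[[x]]))
  # snake_case form, e.g. "simulation_model"
  camel <- snake_to_camel(x)
  if (camel %in% entity_types()) return(camel)
  stop_simprov("unknown_label", sprintf("unknown entity type '%s'", x))
}

#' Parse an activity type label
#'
#' Accepts canonical CamelCase or the snake_case event-type form
#' (e.g. \code{"executing_simulation_experiment"}).
#'
#' @param x Character scalar label.
#' @return The canonical activity type label.
#' @export
parse_activity_type <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% activity_types()) return(x)
  camel <- snake_to_camel(x)
  if (camel %in% activity_types()) return(camel)
  stop_simprov("unknown_label", sprintf("unknown activity type '%s'", x))
}

#' Event-type name of an activity type
#'
#' Events name activities in snake_case (\code{specifying_simulation_model});
#' this maps the canonical label to that wire form.
#'
#' @param activity_type Canonical activity type label.
#' @return snake_case event type string.
#' @export
activity_event_type <- function(activity_type) {
  camel_to_snake(parse_activity_type(activity_type))
}

snake_to_camel <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)[[1]]
  paste0(toupper(substring(parts, 1, 1)), substring(parts, 2), collapse = "")
}

camel_to_snake <- function(x) {
  tolower(gsub("(?<=[a-z])(?=[A-Z])", "_", x, perl = TRUE))
}

#' Canonicalize a file path for entity identity
#'
#' Entity identity is keyed on \code{(entity_type, path)}; paths are
#' normalized lexically (separators unified, \code{.} segments dropped,
#' \code{..} segments collapsed where possible) but never resolved against a
#' filesystem, and case is preserved.
#'
#' @param path Character scalar path.
#' @return Canonical path string.
#' @export
#' @examples
#' canonical_path("models\\.\\sub\\..\\m1.mlr")
canonical_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, !is.na(path))
  p <- gsub("\\", "/", path, fixed = TRUE)
  absolute <- startsWith(p, "/")
  segs <- strsplit(p, "/", fixed = TRUE)[[1]]
  out <- character(0)
  for (s in segs) {
    if (s == "" || s == ".") next
    if (s == "..") {
      if (length(out) > 0L && out[length(out)] != "..") {
        out <- out[-length(out)]
      } else if (!absolute) {
        out <- c(out, "..")
      }
      next
    }
    out <- c(out, s)
  }
  res <- paste0(if (absolute) "/" else "", paste(out, collapse = "/"))
  if (res == "") "." else res
}

#' Entity identity
#'
#' The identity key of an evolving study product: its entity type plus its
#' canonical file path. All versions of one product share one identity.
#'
#' @param entity_type Entity type label (any parseable form).
#' @param path File path; canonicalized.
#' @param name Optional human-readable name.
#' @return An \code{entity_identity} object.
#' @export
entity_identity <- function(entity_type, path, name = NULL) {
  structure(
    list(
      entity_type = parse_entity_type(entity_type),
      path = canonical_path(path),
      name = name
    ),
    class = "entity_identity"
  )
}

#' @export
format.entity_identity <- function(x, ...) {
  sprintf("<%s %s>", x$entity_type, x$path)
}

#' @export
print.entity_identity <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

identity_key <- function(entity_type, path) {
  paste0(entity_type, ":", path)
}

# Deterministic node ids: rebuilding a graph from the same event stream must
# reproduce the same ids so exports are diffable.
entity_node_id <- function(entity_type, path, version) {
  sprintf("entity:%s:%s:v%d", camel_to_snake(entity_type), path, as.integer(version))
}

activity_node_id <- function(event_id) {
  paste0("activity:", event_id)
}

agent_node_id <- function(name, version = NULL) {
  if (is.null(version) || is.na(version) || !nzchar(version)) {
    paste0("agent:", name)
  } else {
    paste0("agent:", name, ":", version)
  }
}

#' Hash text content
#'
#' Stable content hash used for edit detection and simulation-data
#' fingerprints (xxhash128 of the serialized string; stable across sessions
#' and platforms).
#'
#' @param content Character scalar.
#' @return Hash string.
#' @export
hash_content <- function(content) {
  stopifnot(is.character(content), length(content) == 1L)
  rlang::hash(content)
}

# Classed conditions -----------------------------------------------------

stop_simprov <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("simprov_", class), "simprov_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

warn_simprov <- function(class, message) {
  warning(structure(
    class = c(paste0("simprov_", class), "simprov_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
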