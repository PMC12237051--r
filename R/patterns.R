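#' Load provenance patterns from YAML
#'
#' A provenance pattern declares, for one activity type, which used and
#' generated entity types are valid (with min/max cardinalities), which
#' attributes each must carry, and whether an agent is required. The YAML
#' dialect is: a top-level \code{patterns:} list; each item has
#' \code{activity}, \code{uses:}/\code{generates:} lists of
#' \code{{entity, min, max, required_attributes, optional_attributes}}, and
#' optionally \code{agent: {required, required_attributes}}.
#'
#' Defaults applied per constraint: \code{min} 0, \code{max} unbounded,
#' \code{required_attributes} \code{[name, path]}; the agent defaults to
#' required with \code{required_attributes} \code{[name]}.
#'
#' @param yaml_text YAML source text (character scalar), or \code{NULL} to
#'   read from \code{file}.
#' @param file Path to a YAML file (used when \code{yaml_text} is NULL).
#' @return A \code{pattern_set}: named list of \code{prov_pattern} objects
#'   keyed by activity type.
#' @export
#' @examples
#' p <- default_patterns()
#' names(p$patterns)
load_patterns <- function(yaml_text = NULL, file = NULL) {
  if (is.null(yaml_text)) {
    stopifnot(!is.null(file))
    yaml_text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(
    yaml::yaml.load(yaml_text),
    error = function(e) stop_simprov("parse", paste("malformed YAML:", conditionMessage(e)))
  )
  if (!is.list(doc) || is.null(doc$patterns)) {
    stop_simprov("schema", "pattern file must have a top-level 'patterns:' list")
  }
  pats <- list()
  for (item in doc$patterns) {
    at <- tryCatch(parse_activity_type(item$activity %||% ""), error = function(e) {
      stop_simprov("schema", conditionMessage(e))
    })
    if (at %in% names(pats)) {
      stop_simprov("schema", sprintf("duplicate pattern for activity '%s'", at))
    }
    uses <- lapply(item$uses %||% list(), parse_constraint, role = "used")
    gens <- lapply(item$generates %||% list(), parse_constraint, role = "generated")
    if (!any(vapply(gens, function(g) g$min_count >= 1L, logical(1)))) {
      stop_simprov("schema", sprintf(
        "pattern for %s must require at least one generated entity", at
      ))
    }
    ag <- item$agent %||% list()
    pats[[at]] <- structure(
      list(
        activity_type = at,
        used_constraints = uses,
        generated_constraints = gens,
        agent_required = isTRUE(ag$required %||% TRUE),
        agent_required_attributes = as.character(ag$required_attributes %||% "name")
      ),
      class = "prov_pattern"
    )
  }
  structure(list(patterns = pats), class = "pattern_set")
}

parse_constraint <- function(x, role) {
  et <- tryCatch(parse_entity_type(x$entity %||% ""), error = function(e) {
    stop_simprov("schema", conditionMessage(e))
  })
  min_count <- as.integer(x$min %||% 0L)
  max_raw <- x$max %||% "unbounded"
  max_count <- if (identical(max_raw, "unbounded")) Inf else as.numeric(max_raw)
  if (min_count < 0L) stop_simprov("schema", "min must be non-negative")
  if (max_count < 1) stop_simprov("schema", "max must be positive")
  if (min_count > max_count) {
    stop_simprov("schema", sprintf("min > max for entity %s", et))
  }
  req <- as.character(x$required_attributes %||% c("name", "path"))
  opt <- as.character(x$optional_attributes %||% character(0))
  if (length(intersect(req, opt)) > 0L) {
    stop_simprov("schema", sprintf(
      "attributes both required and optional for %s: %s",
      et, paste(intersect(req, opt), collapse = ", ")
    ))
  }
  structure(
    list(
      entity_type = et, role = role, min_count = min_count, max_count = max_count,
      required_attributes = req, optional_attributes = opt
    ),
    class = "entity_constraint"
  )
}

#' The shipped default pattern set
#'
#' Loads \code{patterns/default.yaml} from the installed package: one
#' pattern per activity type for all eight activities.
#'
#' @return A \code{pattern_set}.
#' @export
default_patterns <- function() {
  load_patterns(file = system.file("patterns", "default.yaml", package = "simprov"))
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set: %d pattern(s)>\n", length(x$patterns)))
  for (p in x$patterns) {
    cat(sprintf(
      "  %s: uses %s -> generates %s\n", p$activity_type,
      fmt_constraints(p$used_constraints), fmt_constraints(p$generated_constraints)
    ))
  }
  invisible(x)
}

fmt_constraints <- function(cs) {
  if (length(cs) == 0L) return("-")
  paste(vapply(cs, function(c) {
    paste0(c$entity_type, if (c$min_count >= 1L) "" else "?")
  }, ""), collapse = ", ")
}

violation <- function(code, detail) list(code = code, detail = detail)

#' Match one activity against its provenance pattern
#'
#' Decides whether an activity, given its used and generated entity
#' descriptors and its agent, is valid: per entity type and role the count
#' must fall within the constraint's \code{[min, max]}; entity types not
#' mentioned in any constraint are violations (strict mode) or warnings
#' (\code{permissive}); every present entity and the agent must carry all
#' required attributes non-empty; an agent must be present when the pattern
#' requires one.
#'
#' A pure function: identical inputs yield identical results.
#'
#' @param patterns A \code{pattern_set}.
#' @param activity_type Activity type label (any parseable form).
#' @param used,generated Lists of entity descriptors; each descriptor is a
#'   named list with at least \code{entity_type}, plus attribute keys
#'   (\code{name}, \code{path}, ...).
#' @param agent Named list with \code{name} (and optional \code{version}),
#'   or \code{NULL}.
#' @param permissive Downgrade unknown-entity violations to warnings.
#' @return A \code{prov_match}: list with \code{valid} (logical) and
#'   \code{violations} (list of \code{{code, detail}}). \code{valid} is TRUE
#'   iff no violations.
#' @export
match_activity <- function(patterns, activity_type, used = list(),
                           generated = list(), agent = NULL,
                           permissive = FALSE) {
  stopifnot(inherits(patterns, "pattern_set"))
  at <- tryCatch(parse_activity_type(activity_type), error = function(e) NULL)
  if (is.null(at) || !at %in% names(patterns$patterns)) {
    return(match_result(list(violation(
      "unknown-activity", sprintf("no pattern for activity type '%s'", activity_type)
    ))))
  }
  pat <- patterns$patterns[[at]]
  v <- list()
  v <- c(v, check_role(pat$used_constraints, used, "used", permissive))
  v <- c(v, check_role(pat$generated_constraints, generated, "generated", permissive))
  if (pat$agent_required && is.null(agent)) {
    v <- c(v, list(violation("missing-agent", sprintf("%s requires an agent", at))))
  }
  if (!is.null(agent)) {
    for (key in pat$agent_required_attributes) {
      val <- agent[[key]]
      if (is.null(val) || !nzchar(as.character(val))) {
        v <- c(v, list(violation(
          "missing-attribute", sprintf("agent is missing required attribute '%s'", key)
        )))
      }
    }
  }
  match_result(v)
}

match_result <- function(violations) {
  structure(
    list(valid = length(violations) == 0L, violations = violations),
    class = "prov_match"
  )
}

#' @export
print.prov_match <- function(x, ...) {
  if (x$valid) {
    cat("<prov_match: valid>\n")
  } else {
    cat(sprintf("<prov_match: invalid, %d violation(s)>\n", length(x$violations)))
    for (v in x$violations) cat(sprintf("  [%s] %s\n", v$code, v$detail))
  }
  invisible(x)
}

check_role <- function(constraints, descriptors, role, permissive) {
  v <- list()
  types <- vapply(descriptors, function(d) {
    tryCatch(parse_entity_type(d$entity_type %||% ""), error = function(e) NA_character_)
  }, "")
  known <- vapply(constraints, `[[`, "", "entity_type")
  for (i in seq_along(descriptors)) {
    if (is.na(types[i])) {
      v <- c(v, list(violation(
        "unknown-entity",
        sprintf("%s descriptor %d has unknown entity type '%s'",
                role, i, descriptors[[i]]$entity_type %||% "")
      )))
    } else if (!types[i] %in% known) {
      msg <- sprintf("entity type %s is not allowed as %s here", types[i], role)
      if (permissive) {
        warn_simprov("unknown_entity", msg)
      } else {
        v <- c(v, list(violation("unknown-entity", msg)))
      }
    }
  }
  for (cst in constraints) {
    idx <- which(!is.na(types) & types == cst$entity_type)
    n <- length(idx)
    if (n < cst$min_count) {
      v <- c(v, list(violation(
        "missing-entity",
        sprintf("requires at least %d %s as %s, found %d",
                cst$min_count, cst$entity_type, role, n)
      )))
    }
    if (n > cst$max_count) {
      v <- c(v, list(violation(
        "excess-entity",
        sprintf("at most %s %s %s entities allowed, found %d",
                format(cst$max_count), cst$entity_type, role, n)
      )))
    }
    for (i in idx) {
      d <- descriptors[[i]]
      for (key in cst$required_attributes) {
        val <- d[[key]]
        if (is.null(val) || !nzchar(as.character(val))) {
          v <- c(v, list(violation(
            "missing-attribute",
            sprintf("%s %s is missing required attribute '%s'",
                    cst$entity_type, d$name %||% sprintf("(%s #%d)", role, i), key)
          )))
        }
      }
    }
  }
  v
}
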