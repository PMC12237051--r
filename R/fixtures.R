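#' Define a synthetic study script
#'
#' A study script drives the deterministic event-stream generator. It
#' mirrors the three-phase shape of a typical modeling-and-simulation
#' study: specification of the conceptual model, iterative refinement
#' (edit model, edit experiment, execute, analyze), and adaptation of the
#' model with a comparative analysis.
#'
#' @param phases List of \code{list(kind, iterations)} with kind one of
#'   \code{"conceptual"}, \code{"refine"}, \code{"adapt"}.
#' @param seed Integer seed; same script and seed give a byte-identical
#'   stream.
#' @param invalid_fraction Proportion of events to corrupt (in [0, 1]).
#' @return A \code{study_script}.
#' @export
#' @examples
#' s <- study_script(list(
#'   list(kind = "conceptual", iterations = 1),
#'   list(kind = "refine", iterations = 3)
#' ), seed = 7)
study_script <- function(phases, seed = 1L, invalid_fraction = 0) {
  stopifnot(is.list(phases), invalid_fraction >= 0, invalid_fraction <= 1)
  for (p in phases) {
    stopifnot(p$kind %in% c("conceptual", "refine", "adapt"), p$iterations >= 0)
  }
  structure(
    list(phases = phases, seed = as.integer(seed), invalid_fraction = invalid_fraction),
    class = "study_script"
  )
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic clock: one minute per event, fixed origin
stream_timestamp <- function(n) {
  sprintf("2026-01-01T%02d:%02d:00Z", 9L + (n %/% 60L), n %% 60L)
}

#' Generate a synthetic event stream
#'
#' Emits the event stream a capturer would produce for the scripted study:
#' the conceptual phase specifies references, the research question,
#' assumptions, and requirements; each refine iteration edits the model and
#' the experiment, executes it, and analyzes the output; the adapt phase
#' copies the model, executes it, and produces a comparative visualization.
#' With \code{invalid_fraction > 0}, a seeded subset of events is corrupted
#' with a violation the pattern engine detects (required used entity
#' removed, required attribute blanked, or unknown activity type); the
#' corrupted ids are listed in the stream's manifest
#' (\code{\link{stream_manifest}}), so the expected error-log content is
#' exactly computable.
#'
#' @param script A \code{\link{study_script}}.
#' @param patterns Pattern set (used only to keep generated streams aligned
#'   with the active patterns; defaults to the shipped set).
#' @return List of \code{prov_event} with a \code{"manifest"} attribute.
#' @export
generate_stream <- function(script, patterns = default_patterns()) {
  stopifnot(inherits(script, "study_script"))
  events <- list()
  counter <- 0L
  editor <- list(name = "vscode", version = "1.90")
  runner <- list(name = "mlrules", version = "3.0")
  pyenv <- list(name = "python", version = "3.10")

  add <- function(event_type, agent, used, generated) {
    counter <<- counter + 1L
    events[[counter]] <<- prov_event(
      event_id = sprintf("ev-%04d", counter),
      event_type = event_type,
      agent = agent, used = used, generated = generated,
      timestamp = stream_timestamp(counter)
    )
  }
  d <- function(entity_type, path, content = NULL) {
    out <- list(entity_type = entity_type, name = basename(path), path = path)
    if (!is.null(content)) {
      out$content <- content
      out$content_hash <- hash_content(content)
    }
    out
  }
  blob <- function(tag, i) sprintf("%s #%d (seed %d)", tag, i, script$seed)

  conceptual <- function(i) {
    ref <- sprintf("refs/reference_%02d.md", i)
    add("specifying_reference", editor, list(),
        list(d("Reference", ref, blob("reference", i))))
    add("specifying_research_question", editor,
        list(d("Reference", ref)),
        list(d("ResearchQuestion", "concept/question_main.md", blob("question", i))))
    add("specifying_assumption", editor,
        list(d("Reference", ref)),
        list(d("Assumption", sprintf("concept/assumption_%02d.md", i), blob("assumption", i))))
    add("specifying_requirement", editor,
        list(d("ResearchQuestion", "concept/question_main.md")),
        list(d("Requirement", sprintf("concept/requirement_%02d.md", i), blob("requirement", i))))
  }
  refine <- function(i) {
    add("specifying_simulation_model", editor, list(),
        list(d("SimulationModel", "models/model_main.mlr", blob("rule set", i))))
    add("specifying_simulation_experiment", editor,
        list(d("SimulationModel", "models/model_main.mlr")),
        list(d("SimulationExperiment", "experiments/experiment_main.py", blob("experiment", i))))
    add("executing_simulation_experiment", runner,
        list(
          d("SimulationExperiment", "experiments/experiment_main.py"),
          d("SimulationModel", "models/model_main.mlr")
        ),
        list(d("SimulationData", "output/data_sd.csv", blob("trajectories", i))))
    add("analyzing_simulation_data", pyenv,
        list(
          d("SimulationData", "output/data_sd.csv"),
          d("Script", "scripts/script_viz.py")
        ),
        list(d("Visualization", "figures/visualization_protein.svg", blob("figure", i))))
  }
  adapt <- function(i) {
    add("specifying_simulation_model", editor, list(),
        list(d("SimulationModel", "models/model_adapted.mlr", blob("adapted rules", i))))
    add("executing_simulation_experiment", runner,
        list(
          d("SimulationExperiment", "experiments/experiment_main.py"),
          d("SimulationModel", "models/model_adapted.mlr")
        ),
        list(d("SimulationData", "output/data_sd_adapted.csv", blob("adapted trajectories", i))))
    add("analyzing_simulation_data", pyenv,
        list(
          d("SimulationData", "output/data_sd.csv"),
          d("SimulationData", "output/data_sd_adapted.csv"),
          d("Script", "scripts/script_viz.py")
        ),
        list(d("Visualization", "figures/visualization_comparison.svg", blob("comparison", i))))
  }

  for (phase in script$phases) {
    for (i in seq_len(phase$iterations)) {
      switch(phase$kind, conceptual = conceptual(i), refine = refine(i), adapt = adapt(i))
    }
  }

  manifest <- tibble::tibble(event_id = character(0), corruption = character(0))
  n_corrupt <- round(script$invalid_fraction * length(events))
  if (n_corrupt > 0L) {
    sel <- with_seed(script$seed, {
      idx <- sort(sample(seq_along(events), n_corrupt))
      kinds <- character(length(idx))
      for (j in seq_along(idx)) {
        i <- idx[j]
        ev <- events[[i]]
        required_used <- required_used_types(patterns, ev$event_type)
        present_req <- vapply(ev$used, function(u) u$entity_type %in% required_used, logical(1))
        choices <- c(
          if (any(present_req)) "missing-entity",
          "missing-attribute", "unknown-activity"
        )
        kind <- if (length(choices) == 1L) choices else sample(choices, 1L)
        if (kind == "missing-entity") {
          ev$used <- ev$used[-which(present_req)[1]]
        } else if (kind == "missing-attribute") {
          ev$generated[[1]]$name <- ""
        } else {
          ev$event_type <- "calibrating_quantum_flux"
        }
        events[[i]] <- ev
        kinds[j] <- kind
      }
      list(idx = idx, kinds = kinds)
    })
    manifest <- tibble::tibble(
      event_id = vapply(sel$idx, function(i) events[[i]]$event_id, ""),
      corruption = sel$kinds
    )
  }
  attr(events, "manifest") <- manifest
  events
}

required_used_types <- function(patterns, event_type) {
  at <- tryCatch(parse_activity_type(event_type), error = function(e) NULL)
  if (is.null(at) || !at %in% names(patterns$patterns)) return(character(0))
  cs <- patterns$patterns[[at]]$used_constraints
  vapply(cs[vapply(cs, function(c) c$min_count >= 1L, logical(1))], `[[`, "", "entity_type")
}

#' Manifest of corrupted events in a generated stream
#'
#' @param events Stream from \code{\link{generate_stream}}.
#' @return Tibble with \code{event_id} and \code{corruption} columns.
#' @export
stream_manifest <- function(events) {
  attr(events, "manifest") %||%
    tibble::tibble(event_id = character(0), corruption = character(0))
}

#' The two-experiment worked-example stream
#'
#' Three events reproducing the canonical small provenance graph: two
#' experiment executions -- each using its own simulation model (SM1, SM2)
#' and experiment specification (E1, E2) and generating simulation data
#' (SD1, SD2) under the Tellurium agent (TEL) -- followed by one analysis
#' that uses SD1, SD2, and a Python script (S) to generate a visualization
#' (V) under the Python agent (PY). Ingesting it yields 8 entity versions,
#' 3 activities, 2 agents, and 13 typed edges (7 USED, 3 GENERATED_BY,
#' 3 ASSOCIATED_WITH).
#'
#' @return List of three \code{prov_event}.
#' @export
#' @examples
#' b <- ingest_stream(prov_builder(), fig2_stream())
#' graph_counts(b$graph)
fig2_stream <- function() {
  d <- function(entity_type, name, path) {
    list(entity_type = entity_type, name = name, path = path)
  }
  tel <- list(name = "TEL", version = "2.2")
  py <- list(name = "PY", version = "3.10")
  list(
    prov_event(
      "fig2-e1", "executing_simulation_experiment", tel,
      used = list(
        d("SimulationModel", "SM1", "models/model_sm1.te"),
        d("SimulationExperiment", "E1", "experiments/experiment_e1.py")
      ),
      generated = list(c(d("SimulationData", "SD1", "output/data_sd1.csv"),
                         content_hash = hash_content("sd1"))),
      timestamp = "2026-01-01T10:00:00Z"
    ),
    prov_event(
      "fig2-e2", "executing_simulation_experiment", tel,
      used = list(
        d("SimulationModel", "SM2", "models/model_sm2.te"),
        d("SimulationExperiment", "E2", "experiments/experiment_e2.py")
      ),
      generated = list(c(d("SimulationData", "SD2", "output/data_sd2.csv"),
                         content_hash = hash_content("sd2"))),
      timestamp = "2026-01-01T10:05:00Z"
    ),
    prov_event(
      "fig2-e3", "analyzing_simulation_data", py,
      used = list(
        d("SimulationData", "SD1", "output/data_sd1.csv"),
        d("SimulationData", "SD2", "output/data_sd2.csv"),
        d("Script", "S", "scripts/script_viz.py")
      ),
      generated = list(c(d("Visualization", "V", "figures/visualization_v.svg"),
                         content_hash = hash_content("v"))),
      timestamp = "2026-01-01T10:10:00Z"
    )
  )
}
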