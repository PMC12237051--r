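Package: simprov
Title: Provenance Capture and Graph Building for Simulation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Captures, validates, versions, and chains the provenance of
    simulation studies into a single acyclic provenance graph following the
    W3C PROV-DM model extended with simulation-study entity and activity
    types. Modeler actions arrive as JSON events, are validated against
    declarative YAML provenance patterns, and are chained into a growing
    typed graph with per-file entity versioning. Includes a reference
    capturer SDK (file tracking and execution wrapping), PROV-JSON and
    Graphviz DOT export, graph reductions (same-activity chain aggregation
    and transitive reduction), and deterministic synthetic event-stream
    generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    tibble,
    yaml
Suggests:
    httpuv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
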