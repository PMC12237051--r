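#' Run the provenance-builder REST service
#'
#' Minimal HTTP front end over \code{\link{prov_builder}}: capturers POST
#' events one at a time and the growing graph, error log, and exports are
#' readable back. Endpoints: \code{POST /events} (202 on acceptance, 200
#' with the rejection record when the event was logged as invalid),
#' \code{GET /graph} (PROV-JSON), \code{GET /errors} (error-log records),
#' \code{GET /export?format=prov-json|dot}.
#'
#' Requires the httpuv package. Blocks the session until interrupted unless
#' \code{background = TRUE}, in which case the server handle is returned
#' (stop it with \code{httpuv::stopServer}).
#'
#' @param patterns A \code{pattern_set}.
#' @param port TCP port.
#' @param host Bind address.
#' @param background Return immediately with a server handle.
#' @return The httpuv server handle (background) or never (foreground).
#' @export
prov_serve <- function(patterns = default_patterns(), port = 8977L,
                       host = "127.0.0.1", background = FALSE) {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    stop_simprov("missing_dependency", "prov_serve() requires the httpuv package")
  }
  state_env <- new.env(parent = emptyenv())
  state_env$state <- prov_builder(patterns)

  json_response <- function(status, body) {
    list(
      status = status,
      headers = list("Content-Type" = "application/json"),
      body = as.character(jsonlite::toJSON(body, auto_unbox = TRUE, null = "null"))
    )
  }

  app <- list(call = function(req) {
    path <- req$PATH_INFO
    method <- req$REQUEST_METHOD
    if (method == "POST" && path == "/events") {
      body <- rawToChar(req$rook.input$read())
      res <- tryCatch({
        ev <- parse_event(body)
        before <- length(state_env$state$error_log)
        state_env$state <- ingest_event(state_env$state, ev)
        if (length(state_env$state$error_log) > before) {
          rec <- state_env$state$error_log[[length(state_env$state$error_log)]]
          json_response(200L, list(
            status = "rejected", event_id = ev$event_id,
            violations = rec$violations
          ))
        } else {
          json_response(202L, list(status = "accepted", event_id = ev$event_id))
        }
      }, simprov_error = function(e) {
        json_response(400L, list(status = "error", message = conditionMessage(e)))
      })
      return(res)
    }
    if (method == "GET" && path == "/graph") {
      return(list(
        status = 200L, headers = list("Content-Type" = "application/json"),
        body = export_prov_json(state_env$state$graph)
      ))
    }
    if (method == "GET" && path == "/errors") {
      recs <- lapply(state_env$state$error_log, function(r) {
        list(event = event_to_list(r$event), violations = r$violations,
             received_at = r$received_at)
      })
      return(json_response(200L, recs))
    }
    if (method == "GET" && path == "/export") {
      fmt <- sub(".*format=([a-z-]+).*", "\\1", req$QUERY_STRING %||% "")
      if (identical(fmt, "dot")) {
        return(list(status = 200L, headers = list("Content-Type" = "text/vnd.graphviz"),
                    body = export_dot(state_env$state$graph)))
      }
      return(list(status = 200L, headers = list("Content-Type" = "application/json"),
                  body = export_prov_json(state_env$state$graph)))
    }
    list(status = 404L, headers = list("Content-Type" = "text/plain"), body = "not found")
  })

  if (background) {
    httpuv::startServer(host, port, app)
  } else {
    httpuv::runServer(host, port, app)
  }
}
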