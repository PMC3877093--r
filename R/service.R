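# JSON identification service: expose an index through two endpoints,
#   POST /v1/query          {reads, top_n?, weights?, gap_tolerance?, min_cluster?}
#   GET  /v1/reference/{id} -> single-record FASTA
# The handlers are pure functions of (service, request) so they can be
# served over HTTP (see `tapir_serve()`), or exercised in-process through a
# loopback backend that still serializes every request/response through
# JSON, exactly as the wire would.

#' Create a service around a loaded index
#'
#' @param index A `tapir_index`.
#' @param max_payload_bytes Reject serialized query payloads larger than this
#'   (default 10 MB); the design premise is that a query is a small sample of
#'   reads, not a full sequencing run.
#' @param index_id Label reported in responses.
#' @return A list of class `tapir_service`.
#' @export
tapir_service <- function(index, max_payload_bytes = 10e6, index_id = "tapir-index") {
  stopifnot(inherits(index, "tapir_index"))
  structure(list(index = index, max_payload_bytes = max_payload_bytes,
                 index_id = index_id),
            class = "tapir_service")
}

bad_request <- function(msg, details = NULL) {
  stop(structure(class = c("tapir_bad_request", "error", "condition"),
                 list(message = msg, call = NULL, details = details,
                      status = 400L)))
}

#' Handle an identification query
#'
#' Validates the request, scores the reads against the service's index and
#' returns the hit list.  Stateless: the response equals a local
#' [score_query_set()] call on the same inputs.
#'
#' @param service A [tapir_service()].
#' @param request A list with `reads` (character vector of DNA strings;
#'   mandatory, non-empty) and optional `top_n` (capped at 25), `weights`,
#'   `gap_tolerance`, `min_cluster`.
#' @param payload_bytes Size of the serialized request, if it arrived over a
#'   wire; requests over the service limit are rejected.
#' @return A list with `hits` (data frame), `index_id`, `k`.  Malformed
#'   requests signal a condition of class `tapir_bad_request` carrying
#'   per-read diagnostics in `$details`.
#' @export
handle_query <- function(service, request, payload_bytes = NULL) {
  stopifnot(inherits(service, "tapir_service"))
  if (!is.null(payload_bytes) && payload_bytes > service$max_payload_bytes)
    bad_request(sprintf("payload of %d bytes exceeds the %d byte limit",
                        payload_bytes, as.integer(service$max_payload_bytes)))
  reads <- request$reads
  if (is.null(reads) || length(reads) == 0L)
    bad_request("no reads in request")
  reads <- toupper(unlist(reads, use.names = FALSE))
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad))
    bad_request("malformed reads (non-ACGTN characters)",
                details = data.frame(read_index = which(bad),
                                     sequence = reads[bad]))
  top_n <- min(25L, as.integer(request$top_n %||% 25L))
  k <- service$index$k
  hits <- score_query_set(
    read_set(reads, k = k), service$index,
    weights = as.numeric(request$weights %||% c(0.5, 0.5)),
    top_n = top_n,
    gap_tolerance = as.integer(request$gap_tolerance %||% (2L * k)),
    min_cluster = as.integer(request$min_cluster %||% 2L))
  list(hits = hits, index_id = service$index_id, k = k)
}

#' Handle a reference-retrieval request
#'
#' @param service A [tapir_service()].
#' @param ref_id Reference id.
#' @return A single-record FASTA document (one string, 60-column wrapped,
#'   header `>ref_id description`).  Unknown ids signal `tapir_not_found`.
#' @export
handle_fetch <- function(service, ref_id) {
  stopifnot(inherits(service, "tapir_service"))
  rec <- index_reference(service$index, ref_id)
  body <- gsub("(.{60})", "\\1\n", rec$sequence)
  body <- sub("\n$", "", body)
  paste0(">", rec$ref_id, " ", rec$description, "\n", body, "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- backends (client side) ----------------------------------------------

new_backend <- function(transport, label) {
  structure(list(transport = transport, label = label),
            class = "tapir_backend")
}

#' In-process loopback backend
#'
#' Wraps a [tapir_service()] behind the client backend interface, pushing
#' every request and response through JSON serialization exactly as the HTTP
#' wire would, which makes local/remote equivalence testable without a
#' network.
#'
#' @param service A [tapir_service()].
#' @return A `tapir_backend`.
#' @export
loopback_backend <- function(service) {
  new_backend(function(action, path, body = NULL) {
    if (action == "query") {
      request <- jsonlite::fromJSON(body, simplifyVector = TRUE)
      resp <- handle_query(service, request, payload_bytes = nchar(body, "bytes"))
      jsonlite::toJSON(list(hits = resp$hits, index_id = resp$index_id,
                            k = resp$k),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
    } else {
      handle_fetch(service, path)
    }
  }, label = "loopback")
}

#' Remote HTTP backend
#'
#' Talks to a server started with [tapir_serve()] (or any implementation of
#' the same endpoints).  Requires the `curl` package.
#'
#' @param base_url Server base URL, e.g. `"http://localhost:8080"`.
#' @return A `tapir_backend`.
#' @export
remote_backend <- function(base_url) {
  if (!requireNamespace("curl", quietly = TRUE))
    stop("remote_backend requires the 'curl' package")
  base_url <- sub("/$", "", base_url)
  new_backend(function(action, path, body = NULL) {
    res <- tryCatch({
      h <- curl::new_handle()
      if (action == "query") {
        curl::handle_setopt(h, post = TRUE, postfields = body)
        curl::handle_setheaders(h, "Content-Type" = "application/json")
        curl::curl_fetch_memory(paste0(base_url, "/v1/query"), handle = h)
      } else {
        curl::curl_fetch_memory(paste0(base_url, "/v1/reference/", path),
                                handle = h)
      }
    }, error = function(e)
      stop(structure(class = c("tapir_transport_error", "error", "condition"),
                     list(message = paste0("transport failure: ",
                                           conditionMessage(e)), call = NULL))))
    txt <- rawToChar(res$content)
    if (res$status_code == 404L)
      stop(structure(class = c("tapir_not_found", "error", "condition"),
                     list(message = txt, call = NULL)))
    if (res$status_code >= 400L)
      stop(structure(class = c("tapir_bad_request", "error", "condition"),
                     list(message = txt, call = NULL, status = res$status_code)))
    txt
  }, label = base_url)
}

backend_query <- function(backend, sample, weights = c(0.5, 0.5), top_n = 25L,
                          gap_tolerance = NULL, min_cluster = 2L) {
  sample <- if (inherits(sample, "tapir_read_set")) sample else read_set(sample)
  req <- list(reads = sample$sequences, top_n = top_n, weights = weights,
              min_cluster = min_cluster)
  if (!is.null(gap_tolerance)) req$gap_tolerance <- gap_tolerance
  body <- jsonlite::toJSON(req, auto_unbox = FALSE, digits = NA)
  resp <- jsonlite::fromJSON(backend$transport("query", "/v1/query", body),
                             simplifyVector = TRUE)
  hits <- resp$hits
  if (is.null(hits) || length(hits) == 0L || NROW(hits) == 0L) return(empty_hits())
  hits <- as.data.frame(hits)
  hits$rank <- as.integer(hits$rank)
  hits
}

backend_fetch <- function(backend, ref_id) {
  fasta <- backend$transport("fetch", ref_id)
  lines <- strsplit(fasta, "\n", fixed = TRUE)[[1L]]
  header <- sub("^>", "", lines[1L])
  toks <- strsplit(header, " ", fixed = TRUE)[[1L]]
  seq <- paste(lines[-1L], collapse = "")
  list(ref_id = toks[1L],
       description = paste(toks[-1L], collapse = " "),
       source = "remote", length = nchar(seq), sequence = seq)
}

#' Serve an index over HTTP
#'
#' Minimal blocking JSON server for the query and reference-retrieval
#' endpoints (`POST /v1/query`, `GET /v1/reference/{id}`).  Requires the
#' `httpuv` package.
#'
#' @param index A `tapir_index` (or `tapir_service`).
#' @param port TCP port.
#' @param background Start without blocking (returns the server handle).
#' @return The `httpuv` server handle (background) or never returns
#'   (foreground; interrupt to stop).
#' @export
tapir_serve <- function(index, port = 8080L, background = FALSE) {
  if (!requireNamespace("httpuv", quietly = TRUE))
    stop("tapir_serve requires the 'httpuv' package")
  service <- if (inherits(index, "tapir_service")) index else tapir_service(index)
  app <- list(call = function(req) {
    respond <- function(status, body, type = "application/json")
      list(status = status, headers = list("Content-Type" = type), body = body)
    tryCatch({
      if (req$REQUEST_METHOD == "POST" && req$PATH_INFO == "/v1/query") {
        body <- rawToChar(req$rook.input$read())
        request <- jsonlite::fromJSON(body, simplifyVector = TRUE)
        resp <- handle_query(service, request,
                             payload_bytes = nchar(body, "bytes"))
        respond(200L, jsonlite::toJSON(list(hits = resp$hits,
                                            index_id = resp$index_id,
                                            k = resp$k),
                                       dataframe = "rows", auto_unbox = TRUE,
                                       digits = NA))
      } else if (req$REQUEST_METHOD == "GET" &&
                 startsWith(req$PATH_INFO, "/v1/reference/")) {
        ref_id <- utils::URLdecode(sub("^/v1/reference/", "", req$PATH_INFO))
        respond(200L, handle_fetch(service, ref_id), type = "text/x-fasta")
      } else {
        respond(404L, "unknown endpoint", type = "text/plain")
      }
    },
    tapir_bad_request = function(e)
      respond(e$status %||% 400L, conditionMessage(e), type = "text/plain"),
    tapir_not_found = function(e)
      respond(404L, conditionMessage(e), type = "text/plain"),
    error = function(e)
      respond(500L, conditionMessage(e), type = "text/plain"))
  })
  if (background) {
    httpuv::startServer("127.0.0.1", port, app)
  } else {
    server <- httpuv::startServer("127.0.0.1", port, app)
    on.exit(httpuv::stopServer(server))
    message("tapir service listening on port ", port)
    httpuv::service(Inf)
  }
}
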