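# Optional HTTP front end: maps real socket requests onto the same
# dispatcher the in-process client uses. Requires the httpuv package.

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  pairs <- strsplit(qs, "&", fixed = TRUE)[[1L]]
  out <- list()
  for (p in pairs[nzchar(pairs)]) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1L]]
    key <- utils::URLdecode(kv[1L])
    out[[key]] <- if (length(kv) > 1L) utils::URLdecode(kv[2L]) else ""
  }
  out
}

#' Serve the store over HTTP
#'
#' Starts a blocking HTTP server (httpuv) exposing [route_request()] on
#' real sockets: same URL grammar, JSON bodies, status codes and caching
#' headers as the in-process interface.
#'
#' @param store an [object_store()].
#' @param port TCP port.
#' @param host bind address.
#' @return never returns; interrupt to stop.
#' @export
serve_http <- function(store, port = 8000L, host = "127.0.0.1") {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    stop("serve_http() requires the httpuv package")
  }
  app <- list(
    call = function(req) {
      body <- NULL
      if (!is.null(req$rook.input)) {
        raw <- req$rook.input$read()
        if (length(raw) > 0) body <- rawToChar(raw)
      }
      headers <- list()
      for (nm in ls(req)) {
        if (startsWith(nm, "HTTP_")) {
          headers[[gsub("_", "-", tolower(sub("^HTTP_", "", nm)))]] <- req[[nm]]
        }
      }
      resp <- route_request(
        store, req$REQUEST_METHOD, req$PATH_INFO,
        params = parse_query_string(req$QUERY_STRING),
        body = body, headers = headers
      )
      out_headers <- c(resp$headers, list("Content-Type" = "application/json"))
      list(
        status = resp$status,
        headers = out_headers,
        body = if (is.null(resp$body)) "" else as.character(response_json(resp))
      )
    }
  )
  message(sprintf("serving on http://%s:%d/ (interrupt to stop)", host, port))
  httpuv::runServer(host, port, app)
}
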