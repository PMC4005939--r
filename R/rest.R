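# REST-style request interface over the store. URLs follow the grammar
#
#   /namespace/object_type/            GET list+filter, POST create/bulk
#                                      update, DELETE bulk delete
#   /namespace/object_type/id/         GET single, POST update, DELETE
#   /namespace/object_type/id/acl/     GET/POST permissions, DELETE -> 405
#   /datafiles/id/                     GET array payload (full or slice)
#
# with the namespaces "electrophysiology", "metadata" and "datafiles".
# All bodies are JSON; errors carry {"message": ...}; single-object GETs
# honour If-None-Match / If-Modified-Since with 304 responses.

.namespaces <- c("electrophysiology", "metadata", "datafiles")

api_response <- function(status, body = NULL, headers = list()) {
  structure(list(status = as.integer(status), headers = headers, body = body),
            class = "api_response")
}

#' Render a response body as JSON
#'
#' @param resp an `api_response` from [route_request()].
#' @return a JSON string.
#' @export
response_json <- function(resp) {
  jsonlite::toJSON(resp$body, auto_unbox = TRUE, digits = NA, null = "null")
}

iso_utc <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%OS6Z")
}

#' Parse a resource URL
#'
#' @param path URL path, e.g. `"/electrophysiology/spiketrain/BE8O27N959/"`.
#' @return list with `namespace`, `object_type`, `id`, `subresource`
#'   (each possibly `NULL`).
#' @export
parse_resource_url <- function(path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  if (length(parts) < 1L) stop_not_found("empty resource path")
  ns <- parts[1L]
  if (!ns %in% .namespaces) stop_not_found(sprintf("unknown namespace '%s'", ns))
  if (ns == "datafiles") {
    if (length(parts) != 2L) stop_not_found("datafile URLs have the form /datafiles/id/")
    if (!is_valid_id(parts[2L])) stop_bad_request(sprintf("malformed datafile id '%s'", parts[2L]))
    return(list(namespace = ns, object_type = NULL, id = parts[2L], subresource = NULL))
  }
  if (length(parts) < 2L || length(parts) > 4L) stop_not_found("malformed resource path")
  type <- parts[2L]
  if (!type %in% object_kinds(ns)) {
    stop_not_found(sprintf("unknown object type '%s' in namespace '%s'", type, ns))
  }
  id <- NULL
  sub <- NULL
  if (length(parts) >= 3L) {
    if (!is_valid_id(parts[3L])) stop_bad_request(sprintf("malformed object id '%s'", parts[3L]))
    id <- parts[3L]
  }
  if (length(parts) == 4L) {
    if (!identical(parts[4L], "acl")) stop_not_found(sprintf("unknown subresource '%s'", parts[4L]))
    sub <- "acl"
  }
  list(namespace = ns, object_type = type, id = id, subresource = sub)
}

record_location <- function(record) {
  ns <- object_schema(record$kind)$namespace
  sprintf("/%s/%s/%s/", ns, record$kind, record$id)
}

#' Serialize a stored record to its JSON document form
#'
#' Quantities become `{"value": v, "units": u}`; persisted arrays become
#' references into the datafiles namespace (`{"url", "units", "length"}`,
#' plus inclusive `start_index`/`end_index` when a time-window slice is
#' requested); parent relationships are plain ids. The document also
#' carries the permalink location, owner, e-Tag and last-modified time.
#'
#' @param record a `versioned_record`.
#' @param store the [object_store()] (needed to resolve arrays for spike
#'   train slicing).
#' @param slice optional list with `start_time` / `end_time` / `duration`
#'   values; bare numbers are interpreted in the units of the object's
#'   `t_start` attribute.
#' @return a list ready for JSON encoding.
#' @export
serialize_record <- function(record, store = NULL, slice = NULL) {
  schema <- object_schema(record$kind)
  fields <- list()
  for (a in names(schema$attrs)) {
    v <- record$fields[[a]]
    if (is.null(v)) next
    spec <- schema$attrs[[a]]
    fields[[a]] <- switch(spec$type,
      quantity = list(value = v$value, units = v$units),
      array = serialize_array_field(record, a, v, store, slice),
      v
    )
  }
  for (p in names(schema$parents)) {
    if (!is.null(record$fields[[p]])) fields[[p]] <- record$fields[[p]]
  }
  if (!is.null(record$fields$metadata)) fields$metadata <- as.list(record$fields$metadata)
  doc <- list(
    id = record$id,
    model = record$kind,
    location = record_location(record),
    owner = record$owner,
    fields = fields,
    etag = record$etag,
    last_modified = iso_utc(record$valid_from)
  )
  if (record$deleted) doc$deleted <- TRUE
  doc
}

serialize_array_field <- function(record, attr, ref, store, slice) {
  out <- list(
    url = sprintf("/datafiles/%s/", ref$file_id),
    units = ref$units,
    length = ref$length
  )
  if (is.null(slice) || ref$length == 0L) return(out)
  window <- resolve_window_params(slice, record, store)
  if (identical(record$kind, "analogsignal") && identical(attr, "signal")) {
    b <- slice_indices(window, record$fields$t_start, record$fields$sampling_rate, ref$length)
    out$start_index <- b$first_index
    out$end_index <- b$last_index
    out$url <- sprintf("/datafiles/%s/?start_index=%d&end_index=%d",
                       ref$file_id, b$first_index, b$last_index)
  } else if (identical(record$kind, "spiketrain") && identical(attr, "times")) {
    times <- store$load_array(ref$file_id)
    canon <- times * .unit_table$time[[ref$units]]
    tol_lo <- .slice_tol * max(1, abs(window$start))
    tol_hi <- .slice_tol * max(1, abs(window$end))
    inside <- which(canon >= window$start - tol_lo & canon < window$end - tol_hi)
    if (length(inside) > 0L) {
      out$start_index <- min(inside) - 1L
      out$end_index <- max(inside) - 1L
      out$url <- sprintf("/datafiles/%s/?start_index=%d&end_index=%d",
                         ref$file_id, out$start_index, out$end_index)
    } else {
      out$empty_slice <- TRUE
    }
  }
  out
}

# slice params may be bare numbers (units taken from the object's t_start
# attribute, as in the URL examples) or quantity objects
resolve_window_params <- function(slice, record, store) {
  t_start <- record$fields$t_start
  if (is.null(t_start)) stop_bad_request("object has no time axis to slice")
  as_time_qty <- function(v) {
    if (is_quantity(v)) return(v)
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) stop_bad_request("slice parameters must be numbers or quantities")
    quantity(n, t_start$units)
  }
  params <- list()
  for (k in intersect(names(slice), c("start_time", "end_time", "duration"))) {
    params[[k]] <- as_time_qty(slice[[k]])
  }
  t_stop <- if (identical(record$kind, "spiketrain")) {
    record$fields$t_stop
  } else {
    ref <- record$fields$signal
    rate <- canonical_value(record$fields$sampling_rate, "frequency")
    quantity(canonical_value(t_start, "time") + ref$length / rate, "s")
  }
  resolve_slice_window(params, t_start, t_stop)
}

#' Parse a JSON document into attribute fields
#'
#' The inverse of [serialize_record()] for the `fields` map:
#' `{"value", "units"}` becomes a [quantity()], `{"data", "units"}` an
#' inline [array_values()], `{"url", ...}` a reference to an existing
#' datafile, parent keys plain ids. Unknown keys are rejected with a
#' message listing them.
#'
#' @param kind target object kind.
#' @param doc named list (decoded JSON): the fields of the object.
#' @return named attribute list suitable for [create_object()] /
#'   [update_object()].
#' @export
deserialize_document <- function(kind, doc) {
  schema <- object_schema(kind)
  if (!is.list(doc) || (length(doc) > 0 && is.null(names(doc)))) {
    stop_bad_request("request body must be a JSON object")
  }
  known <- c(names(schema$attrs), names(schema$parents), "metadata")
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0) {
    stop_bad_request(sprintf("unknown keys in document: %s", paste(unknown, collapse = ", ")))
  }
  fields <- list()
  for (a in names(schema$attrs)) {
    v <- doc[[a]]
    if (is.null(v)) next
    spec <- schema$attrs[[a]]
    fields[[a]] <- switch(spec$type,
      quantity = {
        if (!is.list(v) || is.null(v$value) || is.null(v$units)) {
          stop_bad_request(sprintf("field '%s' must be {\"value\", \"units\"}", a))
        }
        quantity(v$value, v$units)
      },
      array = deserialize_array_field(a, v),
      {
        if (is.list(v)) v <- unlist(v)
        if (length(v) != 1L) stop_bad_request(sprintf("field '%s' must be a scalar", a))
        v
      }
    )
  }
  for (p in names(schema$parents)) {
    v <- doc[[p]]
    if (is.null(v)) next
    fields[[p]] <- as.character(v)
  }
  if (!is.null(doc$metadata)) fields$metadata <- as.character(unlist(doc$metadata))
  fields
}

deserialize_array_field <- function(name, v) {
  if (!is.list(v)) stop_bad_request(sprintf("field '%s' must be an array document", name))
  if (!is.null(v$data)) {
    if (is.null(v$units)) stop_bad_request(sprintf("field '%s' needs units", name))
    return(array_values(as.numeric(unlist(v$data)), v$units))
  }
  if (!is.null(v$url)) {
    m <- regmatches(v$url, regexec("/datafiles/([A-Z2-7]{10})/", v$url))[[1L]]
    if (length(m) < 2L) stop_bad_request(sprintf("field '%s' has a malformed datafile url", name))
    return(data_array(m[2L], v$length %||% NA_integer_, v$units))
  }
  stop_bad_request(sprintf("field '%s' must carry either data+units or a datafile url", name))
}

#' Evaluate conditional-GET headers against a record
#'
#' A request carrying `If-None-Match` equal to the record's current
#' e-Tag, or `If-Modified-Since` not earlier than its last modification,
#' is answered `304 Not Modified` with an empty body.
#'
#' @param headers named list of request headers (case-insensitive).
#' @param record the resolved `versioned_record`.
#' @return `TRUE` if a 304 should be returned.
#' @export
conditional_get <- function(headers, record) {
  h <- normalize_headers(headers)
  inm <- h[["if-none-match"]]
  if (!is.null(inm)) {
    return(gsub('"', "", inm, fixed = TRUE) == record$etag)
  }
  ims <- h[["if-modified-since"]]
  if (!is.null(ims)) {
    t <- tryCatch(parse_timestamp(ims), ephystore_error = function(e) NULL)
    if (!is.null(t)) return(t >= record$valid_from)
  }
  FALSE
}

normalize_headers <- function(headers) {
  if (length(headers) == 0) return(list())
  stats::setNames(as.list(headers), tolower(names(headers)))
}

#' Serve a stored array, full or sliced
#'
#' Returns the raw numbers of a datafile, optionally restricted to
#' inclusive 0-based index bounds, and optionally written out as an HDF5
#' file with a single root dataset. Sliced datafiles carry numbers only;
#' units and start times must be read from the owning object.
#'
#' @param store an [object_store()].
#' @param file_id datafile id.
#' @param start_index,end_index optional inclusive 0-based bounds.
#' @param path optional destination; when given, an HDF5 file holding the
#'   (sliced) dataset is written there.
#' @return list with `file_id`, `data`, `length`, and the bounds used.
#' @export
serve_datafile <- function(store, file_id, start_index = NULL, end_index = NULL,
                           path = NULL) {
  ref <- store$array_ref(file_id)
  data <- if (is.null(start_index) && is.null(end_index)) {
    store$load_array(file_id)
  } else {
    store$load_array(file_id, start_index, end_index)
  }
  if (!is.null(path)) h5_write_array(path, data)
  list(
    file_id = file_id, data = data, length = length(data),
    start_index = start_index, end_index = end_index, path = path
  )
}

#' Dispatch one API request
#'
#' The single entry point of the HTTP layer: routes a
#' method/URL/parameters/body tuple to the store operations, maps store
#' conditions to HTTP status codes (400 bad request, 403 forbidden, 404
#' not found, 405 not supported, 410 gone, 412 precondition failed), and
#' logs the request. The acting user comes from `actor` or from a
#' `Authorization: Bearer <token>` header resolved through the store's
#' pluggable identity function.
#'
#' @param store an [object_store()].
#' @param method `"GET"`, `"POST"` or `"DELETE"`.
#' @param path resource path (see [parse_resource_url()]).
#' @param params named list of query parameters.
#' @param body request body: a named list, or a JSON string.
#' @param headers named list of request headers.
#' @param actor acting user id; overrides the Authorization header.
#' @return an `api_response`: list with `status`, `headers`, `body`.
#' @examples
#' store <- object_store()
#' r <- route_request(store, "POST", "/electrophysiology/block/",
#'                    body = list(name = "dataset 1"), actor = "alice")
#' r$status  # 201
#' @export
route_request <- function(store, method, path, params = list(), body = NULL,
                          headers = list(), actor = NULL) {
  h <- normalize_headers(headers)
  if (is.null(actor) && !is.null(h$authorization)) {
    token <- sub("^Bearer +", "", h$authorization)
    actor <- store$identity(token)
  }
  resp <- tryCatch(
    dispatch_request(store, method, path, params, body, h, actor),
    ephystore_error = function(e) {
      api_response(http_status_for(e), body = list(message = conditionMessage(e)))
    }
  )
  store$log_request(method, path, resp$status, actor)
  resp
}

dispatch_request <- function(store, method, path, params, body, headers, actor) {
  if (!method %in% c("GET", "POST", "DELETE")) {
    stop_not_allowed(sprintf("method %s is not supported", method))
  }
  if (is.character(body) && length(body) == 1L) {
    body <- tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
                     error = function(e) stop_bad_request("request body is not valid JSON"))
  }
  url <- parse_resource_url(path)

  if (identical(url$namespace, "datafiles")) {
    if (!identical(method, "GET")) stop_not_allowed("datafiles support GET only")
    payload <- serve_datafile(store, url$id,
                              start_index = params$start_index,
                              end_index = params$end_index)
    payload$path <- NULL
    return(api_response(200L, body = payload,
                        headers = list("Content-Type" = "application/x-hdf5")))
  }

  kind <- url$object_type

  if (identical(url$subresource, "acl")) {
    return(handle_acl(store, method, url$id, body, params, actor))
  }

  if (!is.null(url$id)) {
    return(handle_single(store, method, kind, url$id, params, body, headers, actor))
  }
  handle_collection(store, method, kind, params, body, actor)
}

handle_acl <- function(store, method, id, body, params, actor) {
  if (identical(method, "DELETE")) {
    stop_not_allowed("DELETE is not supported on permission resources")
  }
  if (!store$has_id(id)) stop_not_found(sprintf("no object with id %s", id))
  acl <- store$get_acl(id)
  if (!identical(actor, acl$owner)) {
    stop_forbidden("object permissions are available to the owner only")
  }
  if (identical(method, "GET")) {
    return(api_response(200L, body = list(
      safety_level = acl$safety_level,
      shared_with = as.list(acl$shared_with)
    )))
  }
  recursive <- isTRUE(params$recursive) ||
    (!is.null(params$recursive) &&
       tolower(as.character(params$recursive)) %in% c("true", "1", "yes"))
  new <- store$set_acl(id, body, actor, recursive = recursive)
  api_response(200L, body = list(
    safety_level = new$safety_level,
    shared_with = as.list(new$shared_with)
  ))
}

handle_single <- function(store, method, kind, id, params, body, headers, actor) {
  if (identical(method, "GET")) {
    record <- store$get_object(id, actor, at_time = params$at_time)
    if (!identical(record$kind, kind)) stop_not_found("object is of a different type")
    if (conditional_get(headers, record)) {
      return(api_response(304L, headers = list(
        ETag = record$etag, "Last-Modified" = iso_utc(record$valid_from)
      )))
    }
    slice <- params[intersect(names(params), c("start_time", "end_time", "duration"))]
    if (length(slice) == 0L) slice <- NULL
    return(api_response(200L,
      body = serialize_record(record, store, slice = slice),
      headers = list(ETag = record$etag, "Last-Modified" = iso_utc(record$valid_from))
    ))
  }
  if (identical(method, "POST")) {
    if (is.null(body)) stop_bad_request("update requires a JSON body")
    im <- headers[["if-match"]]
    if (!is.null(im)) {
      cur <- store$get_object(id, actor)
      if (gsub('"', "", im, fixed = TRUE) != cur$etag) {
        stop_conflict("e-Tag mismatch: object was modified by someone else")
      }
    }
    fields <- deserialize_document(kind, body)
    v <- store$update_object(id, fields, actor)
    return(api_response(200L, body = serialize_record(v, store),
                        headers = list(ETag = v$etag)))
  }
  store$delete_object(id, actor)
  api_response(200L, body = list(message = sprintf("object %s deleted", id)))
}

handle_collection <- function(store, method, kind, params, body, actor) {
  if (identical(method, "GET")) {
    spec <- parse_query_params(params, kind)
    res <- evaluate_query(store, spec, actor)
    docs <- lapply(res$records, serialize_record, store = store, slice = spec$slice)
    return(api_response(200L, body = list(
      objects = docs, total = res$total,
      offset = res$offset, max_results = res$max_results
    )))
  }
  if (identical(method, "POST")) {
    if (is.null(body)) stop_bad_request("create/update requires a JSON body")
    if (!is.null(body$fields)) {  # bulk update: {ids?, filters?, fields}
      ids <- as.character(unlist(body$ids))
      if (length(ids) == 0L && !is.null(body$filters)) {
        spec <- parse_query_params(body$filters, kind)
        spec$max_results <- 1000L
        res <- evaluate_query(store, spec, actor)
        ids <- vapply(res$records, `[[`, character(1), "id")
      }
      fields <- deserialize_document(kind, body$fields)
      updated <- character()
      for (id in ids) {
        v <- store$update_object(id, fields, actor)
        updated <- c(updated, v$id)
      }
      return(api_response(200L, body = list(updated = as.list(updated),
                                            total = length(updated))))
    }
    fields <- deserialize_document(kind, body)
    if (is.null(actor)) stop_forbidden("authentication required to create objects")
    v <- store$create_object(kind, fields, actor)
    return(api_response(201L, body = serialize_record(v, store),
                        headers = list(ETag = v$etag, Location = record_location(v))))
  }
  # bulk delete: everything matching the filters that the actor may write
  spec <- parse_query_params(params, kind)
  spec$max_results <- 1000L
  res <- evaluate_query(store, spec, actor)
  deleted <- character()
  for (rec in res$records) {
    if (identical(effective_access(store$get_acl(rec$id), actor), "read-write")) {
      store$delete_object(rec$id, actor)
      deleted <- c(deleted, rec$id)
    }
  }
  api_response(200L, body = list(deleted = as.list(deleted), total = length(deleted)))
}
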