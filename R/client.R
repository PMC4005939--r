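# Native client. Hides the request protocol behind R functions: remote
# objects are mapped to in-memory model structures, arrays are fetched
# lazily (only when asked for, optionally as a time-window slice), and
# GETs of single objects are revalidated through the e-Tag cache.

#' Open a client session
#'
#' The session speaks only the request contract of [route_request()]. The
#' default transport dispatches in-process against a store; any function
#' with the same signature (e.g. one doing real HTTP) can be substituted.
#'
#' @param store an [object_store()] to talk to.
#' @param user user id; sent as a bearer token and resolved through the
#'   store's identity function.
#' @param cache keep an e-Tag document cache? Cached documents are never
#'   served without conditional-GET revalidation.
#' @return a `Session` R6 object.
#' @examples
#' store <- object_store()
#' s <- api_session(store, "alice")
#' blk <- session_save(s, list(kind = "block", fields = list(name = "demo")))
#' session_select(s, "block")[[1]]$fields$name
#' @export
api_session <- function(store, user, cache = TRUE) {
  transport <- function(method, path, params = list(), body = NULL, headers = list()) {
    route_request(store, method, path, params = params, body = body, headers = headers)
  }
  Session$new(transport, user, cache = cache)
}

client_error <- function(status, message) {
  class <- switch(as.character(status),
    "400" = "bad_request", "403" = "forbidden", "404" = "not_found",
    "405" = "method_not_allowed", "410" = "gone",
    "412" = c("conflict", "precondition_failed"),
    "server_error"
  )
  stop(store_error(c("client_error", class),
                   sprintf("server returned %d: %s", status, message)))
}

remote_object <- function(kind, doc) {
  structure(
    list(
      kind = kind,
      id = doc$id,
      location = doc$location,
      owner = doc$owner,
      etag = doc$etag,
      fields = deserialize_document(kind, doc$fields)
    ),
    class = c(paste0("remote_", kind), "remote_object")
  )
}

#' @export
print.remote_object <- function(x, ...) {
  cat(sprintf("<%s %s> %s\n", x$kind, x$id,
              x$fields$name %||% x$fields$label %||% ""))
  invisible(x)
}

#' @rdname api_session
#' @export
Session <- R6::R6Class("Session",
  public = list(
    #' @field user user id of this session.
    user = NULL,
    #' @field cache_enabled whether the e-Tag cache is on.
    cache_enabled = TRUE,
    #' @field stats named counts: requests sent, full responses, 304
    #'   revalidations.
    stats = NULL,

    #' @description Create a session over a transport function.
    #' @param transport `function(method, path, params, body, headers)`
    #'   returning an `api_response`.
    #' @param user user id (bearer token).
    #' @param cache enable the e-Tag cache.
    initialize = function(transport, user, cache = TRUE) {
      private$transport <- transport
      self$user <- user
      self$cache_enabled <- isTRUE(cache)
      private$docs <- new.env(parent = emptyenv())
      self$stats <- c(requests = 0L, full = 0L, not_modified = 0L)
    },

    #' @description Send one request; surfaces transport failures as
    #'   connection errors and 4xx/5xx responses as typed conditions.
    #' @param method,path,params,body,headers request parts.
    #' @param allow_error return error responses instead of raising.
    request = function(method, path, params = list(), body = NULL,
                       headers = list(), allow_error = FALSE) {
      headers$Authorization <- paste("Bearer", self$user)
      cached <- NULL
      if (self$cache_enabled && identical(method, "GET")) {
        key <- paste0(path, "?", paste(names(params), unlist(params),
                                       sep = "=", collapse = "&"))
        if (exists(key, envir = private$docs, inherits = FALSE)) {
          cached <- get(key, envir = private$docs, inherits = FALSE)
          headers[["If-None-Match"]] <- cached$etag
        }
      }
      resp <- tryCatch(
        private$transport(method, path, params, body, headers),
        ephystore_error = function(e) stop(e),
        error = function(e) {
          stop(store_error(c("client_error", "connection_error"),
                           sprintf("cannot reach server: %s", conditionMessage(e))))
        }
      )
      self$stats["requests"] <- self$stats["requests"] + 1L
      if (resp$status == 304L && !is.null(cached)) {
        self$stats["not_modified"] <- self$stats["not_modified"] + 1L
        return(api_response(200L, body = cached$body, headers = resp$headers))
      }
      if (resp$status >= 400L && !allow_error) {
        client_error(resp$status, resp$body$message %||% "unknown error")
      }
      self$stats["full"] <- self$stats["full"] + 1L
      if (self$cache_enabled && identical(method, "GET") &&
          resp$status == 200L && !is.null(resp$headers$ETag)) {
        assign(key, list(etag = resp$headers$ETag, body = resp$body),
               envir = private$docs)
      }
      resp
    },

    #' @description Select objects of a kind by filters (see
    #'   [session_select()]).
    #' @param kind object kind.
    #' @param filters named list of query parameters.
    select = function(kind, filters = list()) {
      ns <- object_schema(kind)$namespace
      resp <- self$request("GET", sprintf("/%s/%s/", ns, kind), params = filters)
      lapply(resp$body$objects, function(doc) remote_object(kind, doc))
    },

    #' @description Fetch one object by id.
    #' @param kind object kind.
    #' @param id object id.
    #' @param at_time optional historical timestamp.
    get = function(kind, id, at_time = NULL) {
      ns <- object_schema(kind)$namespace
      params <- if (is.null(at_time)) list() else list(at_time = at_time)
      resp <- self$request("GET", sprintf("/%s/%s/%s/", ns, kind, id), params = params)
      remote_object(kind, resp$body)
    },

    #' @description Create or update an object (see [session_save()]).
    #' @param object a `remote_object`, or a list with `kind` and
    #'   `fields` for a new object.
    save = function(object) {
      kind <- object$kind
      ns <- object_schema(kind)$namespace
      doc <- fields_document(kind, object$fields)
      if (is.null(object$id)) {
        resp <- self$request("POST", sprintf("/%s/%s/", ns, kind), body = doc)
      } else {
        headers <- list()
        if (!is.null(object$etag)) headers[["If-Match"]] <- object$etag
        resp <- self$request("POST", sprintf("/%s/%s/%s/", ns, kind, object$id),
                             body = doc, headers = headers)
      }
      remote_object(kind, resp$body)
    },

    #' @description Delete an object.
    #' @param object a `remote_object` (or list with `kind` and `id`).
    delete = function(object) {
      ns <- object_schema(object$kind)$namespace
      self$request("DELETE", sprintf("/%s/%s/%s/", ns, object$kind, object$id))
      invisible(NULL)
    },

    #' @description Annotate a data object with metadata values.
    #' @param object target `remote_object`.
    #' @param value_ids ids of metadata values to link.
    annotate = function(object, value_ids) {
      ns <- object_schema(object$kind)$namespace
      linked <- sort(unique(c(object$fields$metadata, value_ids)))
      resp <- self$request("POST",
                           sprintf("/%s/%s/%s/", ns, object$kind, object$id),
                           body = list(metadata = as.list(linked)))
      remote_object(object$kind, resp$body)
    },

    #' @description Fetch an object's array data (see
    #'   [session_fetch_array()]).
    #' @param object a `remote_object` with an array attribute.
    #' @param window optional time window: list with `start_time`,
    #'   `end_time`, `duration` ([quantity()] values).
    fetch_array = function(object, window = NULL) {
      field <- switch(object$kind,
        analogsignal = "signal", spiketrain = "times",
        stop_bad_request(sprintf("kind '%s' has no array attribute", object$kind))
      )
      ref <- object$fields[[field]]
      if (!is_data_array(ref)) stop_bad_request("object carries no stored array")
      if (is.null(window)) {
        resp <- self$request("GET", sprintf("/datafiles/%s/", ref$file_id))
        return(as.numeric(unlist(resp$body$data)))
      }
      ns <- object_schema(object$kind)$namespace
      params <- lapply(window, function(q) {
        if (is_quantity(q)) convert_quantity(q, object$fields$t_start$units)$value else q
      })
      resp <- self$request("GET",
                           sprintf("/%s/%s/%s/", ns, object$kind, object$id),
                           params = params)
      arr <- resp$body$fields[[field]]
      if (isTRUE(arr$empty_slice)) return(numeric(0))
      if (is.null(arr$start_index)) {
        stop_bad_request("server did not return slice bounds")
      }
      resp <- self$request("GET", sprintf("/datafiles/%s/", ref$file_id),
                           params = list(start_index = arr$start_index,
                                         end_index = arr$end_index))
      as.numeric(unlist(resp$body$data))
    }
  ),
  private = list(transport = NULL, docs = NULL)
)

# model fields -> plain JSON-ready document
fields_document <- function(kind, fields) {
  schema <- object_schema(kind)
  doc <- list()
  for (a in names(schema$attrs)) {
    v <- fields[[a]]
    if (is.null(v)) next
    doc[[a]] <- if (is_quantity(v)) {
      list(value = v$value, units = v$units)
    } else if (is_array_values(v)) {
      list(data = as.list(v$data), units = v$units)
    } else if (is_data_array(v)) {
      list(url = sprintf("/datafiles/%s/", v$file_id), units = v$units, length = v$length)
    } else {
      v
    }
  }
  for (p in names(schema$parents)) {
    if (!is.null(fields[[p]])) doc[[p]] <- fields[[p]]
  }
  if (!is.null(fields$metadata)) doc$metadata <- as.list(fields$metadata)
  doc
}

#' Select remote objects by filters
#'
#' @param session an [api_session()].
#' @param kind object kind.
#' @param filters named list of query parameters, same dialect as
#'   [parse_query_params()].
#' @return list of `remote_object`s (arrays left unfetched).
#' @export
session_select <- function(session, kind, filters = list()) {
  session$select(kind, filters)
}

#' Create or update a remote object
#'
#' Without an id the object is created; with an id it is updated, sending
#' `If-Match` with the locally held e-Tag so a concurrent modification on
#' the server raises a conflict instead of being overwritten.
#'
#' @param session an [api_session()].
#' @param object a `remote_object`, or `list(kind =, fields =)` for a new
#'   object.
#' @return the stored `remote_object` with server-assigned id and e-Tag.
#' @export
session_save <- function(session, object) session$save(object)

#' Fetch an object's array, optionally a time-window slice
#'
#' @param session an [api_session()].
#' @param object a `remote_object` of kind `analogsignal` or `spiketrain`.
#' @param window optional list with `start_time` / `end_time` /
#'   `duration` [quantity()] values; the server computes the index bounds
#'   and only the slice is transferred.
#' @return numeric vector.
#' @export
session_fetch_array <- function(session, object, window = NULL) {
  session$fetch_array(object, window)
}
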