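# The versioned object store. Every mutation (create, update, annotate,
# delete) appends a new version rather than overwriting: versions of one
# id partition time into contiguous validity intervals, so any historic
# state can be read back with at_time. Deletion writes a tombstone
# version -- the object disappears from live reads but its pre-delete
# states remain retrievable.

.base32_alphabet <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ234567", "")[[1]]
.id_regex <- "^[A-Z2-7]{10}$"

#' Is a token a syntactically valid object id?
#'
#' Object ids are 10-character strings over the RFC 4648 base-32
#' alphabet (A–Z, 2–7).
#'
#' @param id character token.
#' @return logical.
#' @export
is_valid_id <- function(id) {
  is.character(id) && length(id) == 1L && grepl(.id_regex, id)
}

#' Generate a fresh object identifier
#'
#' Draws 10 characters from the base-32 alphabet, retrying on the
#' (vanishingly rare) collision with an existing id.
#'
#' @param store an [object_store()].
#' @return a 10-character id string.
#' @export
generate_id <- function(store) store$generate_id()

new_version <- function(kind, id, owner, fields, valid_from, etag, deleted = FALSE) {
  structure(
    list(
      kind = kind, id = id, owner = owner, fields = fields,
      valid_from = valid_from, valid_to = Inf, etag = etag, deleted = deleted
    ),
    class = "versioned_record"
  )
}

#' Create a versioned object store
#'
#' The store holds every version of every object, per-object access
#' control lists, a user registry, and an HDF5-backed array directory.
#' All state is in memory except arrays, which live as one HDF5 file per
#' array under `dir`.
#'
#' @param dir directory for HDF5 array files; created if missing.
#'   Defaults to a fresh temporary directory.
#' @return an `ObjectStore` R6 object.
#' @examples
#' store <- object_store()
#' ev <- create_object(store, "block", list(name = "my dataset"), owner = "alice")
#' get_object(store, ev$id, actor = "alice")$fields$name
#' @export
object_store <- function(dir = tempfile("ephystore-")) {
  ObjectStore$new(dir = dir)
}

#' @rdname object_store
#' @export
ObjectStore <- R6::R6Class("ObjectStore",
  public = list(
    #' @field dir array file directory.
    dir = NULL,
    #' @field identity function mapping an auth token to a user id (the
    #'   pluggable identity stub; default is the identity function).
    identity = NULL,

    #' @description Create a store.
    #' @param dir array file directory.
    initialize = function(dir = tempfile("ephystore-")) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      self$dir <- dir
      self$identity <- function(token) token
      private$records <- new.env(parent = emptyenv())
      private$acls <- new.env(parent = emptyenv())
      private$users <- new.env(parent = emptyenv())
      private$arrays <- new.env(parent = emptyenv())
      private$clock <- as.numeric(ISOdatetime(2020, 1, 1, 0, 0, 0, tz = "UTC"))
    },

    #' @description Register a user id so it may appear in ACL shares.
    #' @param user user id.
    register_user = function(user) {
      assign(user, TRUE, envir = private$users)
      invisible(self)
    },

    #' @description Is a user known to the store?
    #' @param user user id.
    knows_user = function(user) {
      exists(user, envir = private$users, inherits = FALSE)
    },

    #' @description Advance and return the internal clock (seconds).
    tick = function() {
      private$clock <- private$clock + 1e-3
      private$clock
    },

    #' @description Fresh 10-character base-32 id, unique store-wide.
    generate_id = function() {
      repeat {
        id <- paste(sample(.base32_alphabet, 10L, replace = TRUE), collapse = "")
        if (!self$has_id(id) &&
            !exists(id, envir = private$arrays, inherits = FALSE)) {
          return(id)
        }
      }
    },

    #' @description Does any object (live or deleted) use this id?
    #' @param id object id.
    has_id = function(id) {
      exists(id, envir = private$records, inherits = FALSE)
    },

    #' @description All versions of an object, in order.
    #' @param id object id.
    versions = function(id) {
      if (!self$has_id(id)) return(NULL)
      get(id, envir = private$records, inherits = FALSE)
    },

    #' @description Latest live version, or NULL if absent or deleted.
    #'   No access check; used for reference resolution.
    #' @param id object id.
    peek = function(id) {
      vs <- self$versions(id)
      if (is.null(vs)) return(NULL)
      last <- vs[[length(vs)]]
      if (last$deleted) NULL else last
    },

    #' @description The version whose validity interval contains `t`
    #'   (tombstones included), or NULL.
    #' @param id object id.
    #' @param t numeric timestamp.
    version_at = function(id, t) {
      vs <- self$versions(id)
      if (is.null(vs)) return(NULL)
      for (v in vs) {
        if (v$valid_from <= t && t < v$valid_to) return(v)
      }
      NULL
    },

    #' @description All ids, optionally of one kind.
    #' @param kind optional kind filter.
    ids = function(kind = NULL) {
      out <- ls(private$records)
      if (!is.null(kind)) {
        keep <- vapply(out, function(id) {
          identical(self$versions(id)[[1L]]$kind, kind)
        }, logical(1))
        out <- out[keep]
      }
      out
    },

    #' @description Snapshot of records of one kind: live versions, or the
    #'   versions valid at `at_time`. Not access-filtered.
    #' @param kind kind name.
    #' @param at_time optional timestamp.
    snapshot = function(kind, at_time = NULL) {
      recs <- list()
      for (id in self$ids(kind)) {
        v <- if (is.null(at_time)) self$peek(id) else self$version_at(id, at_time)
        if (!is.null(v) && !v$deleted) recs[[length(recs) + 1L]] <- v
      }
      recs
    },

    #' @description Create an object (see [create_object()]).
    #' @param kind kind name.
    #' @param fields attribute list.
    #' @param owner owner user id.
    #' @param now optional timestamp.
    create_object = function(kind, fields, owner, now = NULL) {
      schema <- tryCatch(object_schema(kind), ephystore_error = function(e) {
        stop_bad_request(conditionMessage(e))
      })
      rep <- validate_object(kind, fields, store = self)
      if (!rep$ok) {
        stop_bad_request(paste0(
          "validation failed: ",
          paste(rep$violations$field, rep$violations$problem, sep = ": ", collapse = "; ")
        ), violations = rep$violations)
      }
      now <- private$resolve_now(now)
      self$register_user(owner)
      id <- self$generate_id()
      fields <- private$persist_arrays(kind, fields)
      v <- new_version(kind, id, owner, fields, now, private$make_etag(id, now, 1L))
      assign(id, list(v), envir = private$records)
      assign(id, new_acl(owner), envir = private$acls)
      v
    },

    #' @description Update an object (see [update_object()]).
    #' @param id object id.
    #' @param fields partial attribute list, merged over the current state.
    #' @param actor acting user id.
    #' @param now optional timestamp.
    update_object = function(id, fields, actor, now = NULL) {
      vs <- self$versions(id)
      if (is.null(vs)) stop_not_found(sprintf("no object with id %s", id))
      cur <- vs[[length(vs)]]
      if (cur$deleted) stop_gone("object has been deleted and is not available for updates")
      private$require_access(id, actor, "read-write")
      merged <- utils::modifyList(cur$fields, fields)
      rep <- validate_object(cur$kind, merged, store = self, id = id)
      if (!rep$ok) {
        stop_bad_request(paste0(
          "validation failed: ",
          paste(rep$violations$field, rep$violations$problem, sep = ": ", collapse = "; ")
        ), violations = rep$violations)
      }
      now <- private$resolve_now(now, after = cur$valid_from)
      merged <- private$persist_arrays(cur$kind, merged)
      cur$valid_to <- now
      v <- new_version(cur$kind, id, cur$owner, merged, now,
                       private$make_etag(id, now, length(vs) + 1L))
      assign(id, c(vs[-length(vs)], list(cur), list(v)), envir = private$records)
      v
    },

    #' @description Soft-delete an object (see [delete_object()]).
    #' @param id object id.
    #' @param actor acting user id.
    #' @param now optional timestamp.
    delete_object = function(id, actor, now = NULL) {
      vs <- self$versions(id)
      if (is.null(vs)) stop_not_found(sprintf("no object with id %s", id))
      cur <- vs[[length(vs)]]
      if (cur$deleted) stop_not_found("object already deleted")
      private$require_access(id, actor, "read-write")
      now <- private$resolve_now(now, after = cur$valid_from)
      cur$valid_to <- now
      v <- new_version(cur$kind, id, cur$owner, cur$fields, now,
                       private$make_etag(id, now, length(vs) + 1L), deleted = TRUE)
      assign(id, c(vs[-length(vs)], list(cur), list(v)), envir = private$records)
      invisible(v)
    },

    #' @description Read an object (see [get_object()]).
    #' @param id object id.
    #' @param actor acting user id.
    #' @param at_time optional timestamp or ISO-8601 string for
    #'   historical reads.
    get_object = function(id, actor, at_time = NULL) {
      if (!is_valid_id(id)) stop_bad_request(sprintf("malformed object id '%s'", id))
      if (!self$has_id(id)) stop_not_found(sprintf("no object with id %s", id))
      if (effective_access(self$get_acl(id), actor) == "none") {
        stop_forbidden("you do not have read access to this object")
      }
      if (is.null(at_time)) {
        v <- self$peek(id)
        if (is.null(v)) stop_not_found("object has been deleted")
        return(v)
      }
      t <- parse_timestamp(at_time)
      v <- self$version_at(id, t)
      if (is.null(v) || v$deleted) stop_not_found("no version of this object at the requested time")
      v
    },

    #' @description Annotate a data object with metadata values (see
    #'   [annotate()]).
    #' @param target_id id of the object to annotate.
    #' @param value_ids ids of metadata value objects.
    #' @param actor acting user id.
    #' @param now optional timestamp.
    annotate = function(target_id, value_ids, actor, now = NULL) {
      if (is.null(self$peek(target_id))) {
        stop_not_found(sprintf("no object with id %s", target_id))
      }
      for (vid in value_ids) {
        v <- self$peek(vid)
        if (is.null(v)) stop_not_found(sprintf("no metadata value with id %s", vid))
        if (!identical(v$kind, "value")) {
          stop_bad_request(sprintf("object %s is not a metadata value", vid))
        }
      }
      cur <- self$peek(target_id)
      linked <- sort(unique(c(cur$fields$metadata, value_ids)))
      self$update_object(target_id, list(metadata = linked), actor, now)
    },

    #' @description Current ACL of an object.
    #' @param id object id.
    get_acl = function(id) {
      if (!self$has_id(id)) stop_not_found(sprintf("no object with id %s", id))
      get(id, envir = private$acls, inherits = FALSE)
    },

    #' @description Replace an object's ACL (see [set_acl()]).
    #' @param id object id.
    #' @param acl list with `safety_level` and `shared_with`.
    #' @param actor acting user id (must be the owner).
    #' @param recursive also apply to contained objects owned by `actor`.
    set_acl = function(id, acl, actor, recursive = FALSE) {
      cur <- self$get_acl(id)
      if (!identical(actor, cur$owner)) {
        stop_forbidden("only the object owner may change permissions")
      }
      new <- validate_acl(acl, cur$owner, self)
      assign(id, new, envir = private$acls)
      if (isTRUE(recursive)) {
        for (child in private$children_of(id)) {
          child_acl <- self$get_acl(child)
          if (identical(child_acl$owner, actor)) {
            self$set_acl(child, acl, actor, recursive = TRUE)
          }
        }
      }
      new
    },

    #' @description Persist a numeric array as an HDF5 file (see
    #'   [store_array()]).
    #' @param values numeric vector.
    #' @param units unit symbol.
    store_array = function(values, units = "V") {
      file_id <- self$generate_id()
      h5_write_array(h5_array_path(self$dir, file_id), values)
      ref <- data_array(file_id, length(values), units)
      assign(file_id, ref, envir = private$arrays)
      ref
    },

    #' @description Load a persisted array or slice (see [load_array()]).
    #' @param file_id array file id.
    #' @param first,last optional 0-based inclusive bounds.
    load_array = function(file_id, first = NULL, last = NULL) {
      ref <- self$array_ref(file_id)
      h5_read_array(h5_array_path(self$dir, file_id), first, last, length = ref$length)
    },

    #' @description Reference (length, units) of a stored array.
    #' @param file_id array file id.
    array_ref = function(file_id) {
      if (!exists(file_id, envir = private$arrays, inherits = FALSE)) {
        stop_not_found(sprintf("no datafile with id %s", file_id))
      }
      get(file_id, envir = private$arrays, inherits = FALSE)
    },

    #' @description Append one entry to the structured request log.
    #' @param method,path,status,actor request method, path, response
    #'   status and acting user.
    log_request = function(method, path, status, actor) {
      private$reqlog[[length(private$reqlog) + 1L]] <- list(
        method = method, path = path, status = as.integer(status),
        actor = actor %||% NA_character_, time = self$tick()
      )
      invisible(self)
    },

    #' @description The request log as a tibble (method, path, status,
    #'   actor, time).
    request_log = function() {
      tibble::tibble(
        method = vapply(private$reqlog, `[[`, character(1), "method"),
        path = vapply(private$reqlog, `[[`, character(1), "path"),
        status = vapply(private$reqlog, `[[`, integer(1), "status"),
        actor = vapply(private$reqlog, `[[`, character(1), "actor"),
        time = vapply(private$reqlog, `[[`, numeric(1), "time")
      )
    }
  ),

  private = list(
    records = NULL,
    acls = NULL,
    users = NULL,
    arrays = NULL,
    clock = NULL,
    reqlog = list(),

    resolve_now = function(now, after = NULL) {
      now <- if (is.null(now)) self$tick() else parse_timestamp(now)
      if (!is.null(after) && now <= after) now <- after + 1e-6
      if (now > private$clock) private$clock <- now
      now
    },

    make_etag = function(id, valid_from, n) {
      digest::digest(list(id, sprintf("%.6f", valid_from), n), algo = "xxhash64")
    },

    require_access = function(id, actor, level) {
      got <- effective_access(self$get_acl(id), actor)
      ok <- switch(level,
        "read" = got %in% c("read", "read-write"),
        "read-write" = identical(got, "read-write")
      )
      if (!ok) stop_forbidden(sprintf("%s access required", level))
    },

    persist_arrays = function(kind, fields) {
      schema <- object_schema(kind)
      for (a in names(schema$attrs)) {
        if (identical(schema$attrs[[a]]$type, "array") && is_array_values(fields[[a]])) {
          fields[[a]] <- self$store_array(fields[[a]]$data, fields[[a]]$units)
        }
      }
      fields
    },

    children_of = function(id) {
      out <- character()
      for (other in ls(private$records)) {
        v <- self$peek(other)
        if (is.null(v)) next
        parents <- names(object_schema(v$kind)$parents)
        for (p in parents) {
          if (identical(v$fields[[p]], id)) out <- c(out, other)
        }
      }
      unique(out)
    }
  )
)

#' Parse a timestamp
#'
#' Accepts a numeric POSIX timestamp (seconds) or an ISO-8601 string
#' (UTC), e.g. `"2013-09-15 15:36:55"` or `"2013-09-15T15:36:55"`.
#'
#' @param x numeric or character timestamp.
#' @return numeric seconds since the epoch.
#' @export
parse_timestamp <- function(x) {
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) return(as.numeric(x))
  if (is.character(x) && length(x) == 1L) {
    t <- suppressWarnings(as.POSIXct(x,
      tz = "UTC",
      tryFormats = c(
        "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M",
        "%Y-%m-%d %H:%M", "%Y-%m-%d"
      )
    ))
    if (!is.na(t)) return(as.numeric(t))
  }
  stop_bad_request(sprintf("cannot parse timestamp '%s'", paste(x, collapse = ",")))
}

# --- functional wrappers over the R6 store -------------------------------

#' Create an object in the store
#'
#' Validates the attributes against the kind schema, persists any inline
#' arrays to HDF5, assigns a fresh base-32 id and e-Tag, and opens the
#' first validity interval. The new object is private to its owner.
#'
#' @param store an [object_store()].
#' @param kind object kind, see [object_kinds()].
#' @param fields named attribute list (see [validate_object()]).
#' @param owner owning user id.
#' @param now optional explicit timestamp ([parse_timestamp()]).
#' @return the stored `versioned_record`.
#' @export
create_object <- function(store, kind, fields, owner, now = NULL) {
  store$create_object(kind, fields, owner, now)
}

#' Update an object, creating a new version
#'
#' The previous version's validity interval is closed at `now` and a new
#' open version with the merged fields and a fresh e-Tag is appended.
#' Requires read-write access; deleted objects are gone for updates.
#'
#' @inheritParams create_object
#' @param id object id.
#' @param fields partial attribute list; unnamed attributes keep their
#'   current values.
#' @param actor acting user id.
#' @return the new `versioned_record`.
#' @export
update_object <- function(store, id, fields, actor, now = NULL) {
  store$update_object(id, fields, actor, now)
}

#' Soft-delete an object
#'
#' Writes a tombstone version: the object disappears from live reads and
#' queries but all earlier versions remain readable with `at_time`.
#'
#' @inheritParams update_object
#' @return the tombstone record, invisibly.
#' @export
delete_object <- function(store, id, actor, now = NULL) {
  store$delete_object(id, actor, now)
}

#' Read an object, current or as of a past instant
#'
#' Without `at_time`, returns the current live version (404 semantics if
#' deleted). With `at_time`, returns the version whose validity interval
#' contains that instant — time travel over the object's history.
#'
#' @inheritParams update_object
#' @param at_time optional timestamp (numeric or ISO-8601 string).
#' @return a `versioned_record`.
#' @export
get_object <- function(store, id, actor, at_time = NULL) {
  store$get_object(id, actor, at_time)
}

#' Annotate a data object with metadata values
#'
#' Adds annotation links from the target object to the given metadata
#' value objects, with set semantics (duplicates collapse). Annotation
#' changes object state, so the target receives a new version and e-Tag.
#'
#' @inheritParams update_object
#' @param target_id id of the object being annotated.
#' @param value_ids character vector of metadata value ids.
#' @return the new `versioned_record` of the target.
#' @export
annotate <- function(store, target_id, value_ids, actor, now = NULL) {
  store$annotate(target_id, value_ids, actor, now)
}
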