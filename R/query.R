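# Django-style field-lookup queries over the store. A query selects
# objects of one kind by attribute filters (name__icontains=...), by
# filters on related objects through parent/child links
# (property__name__icontains=...), by annotation with metadata values,
# and by owner; results are visibility-filtered, stably ordered and
# paginated.

.lookups <- c(
  "exact", "iexact", "contains", "icontains", "gt", "gte", "lt", "lte",
  "in", "startswith", "isnull"
)

.reserved_params <- c(
  "owner", "at_time", "offset", "max_results", "metadata",
  "start_time", "end_time", "duration"
)

#' Construct a query specification
#'
#' Usually built from URL parameters with [parse_query_params()].
#'
#' @param kind object kind to query.
#' @param filters list of filters, each `list(path, field, lookup, value)`
#'   where `path` is a (possibly empty) chain of relation names.
#' @param metadata_values character vector of metadata value ids; a
#'   matching object must be annotated with all of them.
#' @param owner restrict to objects owned by this user.
#' @param at_time query the store as of this instant.
#' @param offset,max_results pagination (default page size 100, hard cap
#'   1000).
#' @param slice optional time-window parameters passed through to array
#'   slicing.
#' @return a `query_spec` object.
#' @export
query_spec <- function(kind, filters = list(), metadata_values = NULL,
                       owner = NULL, at_time = NULL, offset = 0L,
                       max_results = 100L, slice = NULL) {
  object_schema(kind)  # errors on unknown kind
  offset <- as.integer(offset)
  max_results <- as.integer(max_results)
  if (is.na(offset) || offset < 0L) stop_bad_request("offset must be a count >= 0")
  if (is.na(max_results) || max_results < 1L) stop_bad_request("max_results must be >= 1")
  max_results <- min(max_results, 1000L)
  structure(
    list(
      kind = kind, filters = filters, metadata_values = metadata_values,
      owner = owner, at_time = at_time, offset = offset,
      max_results = max_results, slice = slice
    ),
    class = "query_spec"
  )
}

# relation names available on a kind: parent reference fields, plus child
# kinds that declare a parent reference back to this kind
kind_relations <- function(kind) {
  schema <- object_schema(kind)
  parents <- lapply(schema$parents, function(p) list(direction = "parent", kind = p$kind))
  children <- list()
  for (ck in object_kinds()) {
    cps <- object_schema(ck)$parents
    via <- names(cps)[vapply(cps, function(p) identical(p$kind, kind), logical(1))]
    if (length(via) > 0 && !identical(ck, kind)) {
      children[[ck]] <- list(direction = "child", kind = ck, via = via)
    }
  }
  c(parents, children)
}

#' Parse URL query parameters into a query specification
#'
#' Keys of the form `field`, `field__lookup` or `relation__field__lookup`
#' become filters (a bare field means the `exact` lookup); the reserved
#' keys `owner`, `at_time`, `offset`, `max_results`, `metadata` (a
#' comma-separated list of value ids) and the slicing keys `start_time`,
#' `end_time`, `duration` are routed to their slots. Supported lookups:
#' `r paste(ephystore:::.lookups, collapse = ", ")`. Unknown lookups or
#' fields are rejected.
#'
#' @param params named list (or vector) of parameter values, as decoded
#'   from a URL query string.
#' @param kind object kind the query targets.
#' @return a [query_spec()].
#' @examples
#' parse_query_params(list(name__icontains = "luminance"), "property")
#' @export
parse_query_params <- function(params, kind) {
  params <- as.list(params)
  filters <- list()
  slice <- list()
  spec_args <- list(kind = kind)
  for (key in names(params)) {
    val <- params[[key]]
    if (key %in% c("start_time", "end_time", "duration")) {
      slice[[key]] <- val
    } else if (key == "metadata") {
      ids <- unlist(strsplit(as.character(val), ",", fixed = TRUE))
      spec_args$metadata_values <- ids[nzchar(ids)]
    } else if (key == "owner") {
      spec_args$owner <- as.character(val)
    } else if (key == "at_time") {
      spec_args$at_time <- parse_timestamp(val)
    } else if (key %in% c("offset", "max_results")) {
      n <- suppressWarnings(as.integer(val))
      if (is.na(n)) stop_bad_request(sprintf("'%s' must be an integer", key))
      spec_args[[key]] <- n
    } else {
      filters[[length(filters) + 1L]] <- parse_filter_key(key, val, kind)
    }
  }
  spec_args$filters <- filters
  if (length(slice) > 0) spec_args$slice <- slice
  do.call(query_spec, spec_args)
}

parse_filter_key <- function(key, value, kind) {
  tokens <- strsplit(key, "__", fixed = TRUE)[[1L]]
  resolve <- function(kind, tokens, path) {
    if (length(path) > 2L) {
      stop_bad_request(sprintf("filter '%s': relationship paths deeper than 2 are not supported", key))
    }
    schema <- object_schema(kind)
    t1 <- tokens[1L]
    is_attr <- t1 %in% names(schema$attrs)
    if (length(tokens) == 1L) {
      if (!is_attr) {
        stop_bad_request(sprintf("unknown field '%s' for kind '%s'", t1, kind))
      }
      return(list(path = path, field = t1, lookup = "exact", value = value))
    }
    if (is_attr && length(tokens) == 2L) {
      if (!tokens[2L] %in% .lookups) {
        stop_bad_request(sprintf("unknown lookup '%s' in filter '%s'", tokens[2L], key))
      }
      return(list(path = path, field = t1, lookup = tokens[2L], value = value))
    }
    rels <- kind_relations(kind)
    if (t1 %in% names(rels)) {
      return(resolve(rels[[t1]]$kind, tokens[-1L], c(path, t1)))
    }
    if (is_attr) {
      stop_bad_request(sprintf("unknown lookup '%s' in filter '%s'", tokens[2L], key))
    }
    stop_bad_request(sprintf("unknown field or relation '%s' for kind '%s'", t1, kind))
  }
  resolve(kind, tokens, character())
}

#' Evaluate a query against the store
#'
#' Applies version selection (`at_time`), visibility (an object is
#' visible to the actor iff [effective_access()] is not `"none"`), the
#' owner restriction, all attribute and relationship filters (AND
#' semantics), and the metadata-annotation conjunction; orders results
#' stably by `(valid_from, id)` and returns one page.
#'
#' @param store an [object_store()].
#' @param spec a [query_spec()].
#' @param actor acting user id (`NULL` for anonymous).
#' @return list with `records` (the page, a list of `versioned_record`s),
#'   `total` (matching records before pagination), `offset` and
#'   `max_results`.
#' @export
evaluate_query <- function(store, spec, actor) {
  recs <- store$snapshot(spec$kind, spec$at_time)
  keep <- vapply(recs, function(rec) {
    if (effective_access(store$get_acl(rec$id), actor) == "none") return(FALSE)
    if (!is.null(spec$owner) && !identical(rec$owner, spec$owner)) return(FALSE)
    for (f in spec$filters) {
      if (!filter_matches(store, rec, f, spec$at_time)) return(FALSE)
    }
    if (!is.null(spec$metadata_values) &&
        !all(spec$metadata_values %in% rec$fields$metadata)) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  recs <- recs[keep]
  ord <- order(
    vapply(recs, `[[`, numeric(1), "valid_from"),
    vapply(recs, `[[`, character(1), "id")
  )
  recs <- recs[ord]
  total <- length(recs)
  lo <- spec$offset + 1L
  hi <- min(total, spec$offset + spec$max_results)
  page <- if (lo > total) list() else recs[lo:hi]
  list(records = page, total = total, offset = spec$offset, max_results = spec$max_results)
}

filter_matches <- function(store, rec, filter, at_time) {
  vals <- resolve_field_values(store, rec, filter$path, filter$field, at_time)
  if (identical(filter$lookup, "isnull")) {
    want <- isTRUE(filter$value) || tolower(as.character(filter$value)) %in% c("true", "1", "yes")
    present <- any(!vapply(vals, is.null, logical(1))) && length(vals) > 0
    return(if (want) !present else present)
  }
  for (v in vals) {
    if (!is.null(v) && lookup_matches(v, filter$lookup, filter$value)) return(TRUE)
  }
  FALSE
}

# values of `field` reached from rec through the relation path; child
# relations can yield several related objects, hence a list
resolve_field_values <- function(store, rec, path, field, at_time) {
  if (length(path) == 0L) {
    return(list(attr_value(rec, field)))
  }
  rel <- path[1L]
  rels <- kind_relations(rec$kind)
  info <- rels[[rel]]
  targets <- list()
  if (identical(info$direction, "parent")) {
    pid <- rec$fields[[rel]]
    if (!is.null(pid)) {
      t <- if (is.null(at_time)) store$peek(pid) else store$version_at(pid, at_time)
      if (!is.null(t) && !t$deleted) targets <- list(t)
    }
  } else {
    for (child in store$snapshot(info$kind, at_time)) {
      for (via in info$via) {
        if (identical(child$fields[[via]], rec$id)) {
          targets[[length(targets) + 1L]] <- child
          break
        }
      }
    }
  }
  out <- list()
  for (t in targets) {
    out <- c(out, resolve_field_values(store, t, path[-1L], field, at_time))
  }
  out
}

attr_value <- function(rec, field) {
  v <- rec$fields[[field]]
  if (is.null(v)) return(NULL)
  if (is_quantity(v)) return(canonicalize_quantity(v, unit_dimension(v$units))$value)
  if (is_data_array(v) || is_array_values(v)) return(NULL)  # arrays are not filterable
  v
}

lookup_matches <- function(value, lookup, fv) {
  num <- is.numeric(value)
  fnum <- if (num) suppressWarnings(as.numeric(fv)) else NULL
  s <- as.character(value)
  fs <- as.character(fv)
  switch(lookup,
    exact = if (num && !is.na(fnum)) isTRUE(value == fnum) else identical(s, fs),
    iexact = identical(tolower(s), tolower(fs)),
    contains = grepl(fs, s, fixed = TRUE),
    icontains = grepl(tolower(fs), tolower(s), fixed = TRUE),
    gt = compare_values(value, fv, `>`),
    gte = compare_values(value, fv, `>=`),
    lt = compare_values(value, fv, `<`),
    lte = compare_values(value, fv, `<=`),
    `in` = {
      set <- if (is.character(fv) && length(fv) == 1L) {
        strsplit(fv, ",", fixed = TRUE)[[1L]]
      } else {
        as.character(fv)
      }
      if (num) {
        nset <- suppressWarnings(as.numeric(set))
        isTRUE(any(value == nset[!is.na(nset)]))
      } else {
        s %in% set
      }
    },
    startswith = startsWith(s, fs),
    stop_bad_request(sprintf("unknown lookup '%s'", lookup))
  )
}

compare_values <- function(value, fv, op) {
  if (is.numeric(value)) {
    fnum <- suppressWarnings(as.numeric(fv))
    if (is.na(fnum)) return(FALSE)
    isTRUE(op(value, fnum))
  } else {
    isTRUE(op(as.character(value), as.character(fv)))
  }
}

#' Summarize query results as a tibble
#'
#' One row per record: id, kind, owner, name/label, validity start and
#' e-Tag, with the full field list as a list-column.
#'
#' @param records list of `versioned_record`s, e.g.
#'   `evaluate_query(...)$records`.
#' @return a tibble.
#' @export
records_tibble <- function(records) {
  tibble::tibble(
    id = vapply(records, `[[`, character(1), "id"),
    kind = vapply(records, `[[`, character(1), "kind"),
    owner = vapply(records, `[[`, character(1), "owner"),
    name = vapply(records, function(r) {
      r$fields$name %||% r$fields$label %||% NA_character_
    }, character(1)),
    valid_from = vapply(records, `[[`, numeric(1), "valid_from"),
    etag = vapply(records, `[[`, character(1), "etag"),
    fields = lapply(records, `[[`, "fields")
  )
}
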