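# Declarative attribute and relationship schemas for every object kind.
#
# The recorded-data kinds follow the Neo object model: a block groups
# experimental trials (segments); each segment holds regularly sampled
# analog signals, spike trains of sorted units, and stimulus events.
# Recording channel groups and channels describe the electrode layout.
# The metadata kinds follow the odML model: nested sections grouping
# properties, each property holding values; annotation links connect any
# data object to metadata values.

.text_attr  <- function(required = FALSE) list(type = "text", required = required)
.num_attr   <- function(required = FALSE) list(type = "number", required = required)
.qty_attr   <- function(dim, required = TRUE) list(type = "quantity", dim = dim, required = required)
.array_attr <- function(dim, required = TRUE) list(type = "array", dim = dim, required = required)
.parent     <- function(kind, required = TRUE) list(kind = kind, required = required)

.kind_schema <- list(
  block = list(
    namespace = "electrophysiology",
    attrs = list(name = .text_attr(TRUE), comment = .text_attr()),
    parents = list()
  ),
  segment = list(
    namespace = "electrophysiology",
    attrs = list(name = .text_attr(TRUE), comment = .text_attr()),
    parents = list(block = .parent("block"))
  ),
  analogsignal = list(
    namespace = "electrophysiology",
    attrs = list(
      name = .text_attr(TRUE),
      comment = .text_attr(),
      t_start = .qty_attr("time"),
      sampling_rate = .qty_attr("frequency"),
      signal = .array_attr("voltage")
    ),
    parents = list(
      segment = .parent("segment"),
      recordingchannel = .parent("recordingchannel", required = FALSE)
    )
  ),
  spiketrain = list(
    namespace = "electrophysiology",
    attrs = list(
      name = .text_attr(TRUE),
      comment = .text_attr(),
      t_start = .qty_attr("time"),
      t_stop = .qty_attr("time"),
      times = .array_attr("time")
    ),
    parents = list(
      segment = .parent("segment"),
      unit = .parent("unit", required = FALSE)
    )
  ),
  event = list(
    namespace = "electrophysiology",
    attrs = list(
      label = .text_attr(TRUE),
      comment = .text_attr(),
      time = .qty_attr("time")
    ),
    parents = list(segment = .parent("segment"))
  ),
  recordingchannelgroup = list(
    namespace = "electrophysiology",
    attrs = list(name = .text_attr(TRUE), comment = .text_attr()),
    parents = list(block = .parent("block"))
  ),
  recordingchannel = list(
    namespace = "electrophysiology",
    attrs = list(name = .text_attr(TRUE), comment = .text_attr(), index = .num_attr()),
    parents = list(recordingchannelgroup = .parent("recordingchannelgroup"))
  ),
  unit = list(
    namespace = "electrophysiology",
    attrs = list(name = .text_attr(TRUE), comment = .text_attr()),
    parents = list(recordingchannelgroup = .parent("recordingchannelgroup"))
  ),
  section = list(
    namespace = "metadata",
    attrs = list(name = .text_attr(TRUE), comment = .text_attr()),
    parents = list(
      parent_section = .parent("section", required = FALSE),
      block = .parent("block", required = FALSE)
    )
  ),
  property = list(
    namespace = "metadata",
    attrs = list(name = .text_attr(TRUE), comment = .text_attr()),
    parents = list(section = .parent("section"))
  ),
  value = list(
    namespace = "metadata",
    attrs = list(data = list(type = "scalar", required = TRUE)),
    parents = list(property = .parent("property"))
  )
)

#' Object kinds known to the store
#'
#' @param namespace optionally restrict to one namespace
#'   (`"electrophysiology"` or `"metadata"`).
#' @return character vector of kind names.
#' @export
object_kinds <- function(namespace = NULL) {
  kinds <- names(.kind_schema)
  if (!is.null(namespace)) {
    kinds <- kinds[vapply(.kind_schema, function(s) s$namespace, "") == namespace]
  }
  kinds
}

#' Attribute and relationship schema of a kind
#'
#' @param kind object kind name.
#' @return list with `namespace`, `attrs` (per-attribute type, dimension,
#'   required flag) and `parents` (per-relationship target kind and
#'   required flag).
#' @export
object_schema <- function(kind) {
  s <- .kind_schema[[kind]]
  if (is.null(s)) stop_unknown_type(sprintf("unknown object kind '%s'", kind))
  s
}

#' Inline numeric array values with units
#'
#' Used to hand an array attribute (an analog signal's samples, a spike
#' train's spike times) to [create_object()] before it is persisted to
#' HDF5.
#'
#' @param data numeric vector.
#' @param units unit symbol for the array values.
#' @return object of class `array_values`.
#' @export
array_values <- function(data, units) {
  if (!is.numeric(data)) stop_bad_request("array data must be numeric")
  dim <- unit_dimension(units)
  if (is.na(dim)) stop_unit_dimension(sprintf("unknown unit symbol '%s'", units))
  structure(list(data = as.numeric(data), units = units), class = "array_values")
}

is_array_values <- function(x) inherits(x, "array_values")
is_data_array <- function(x) inherits(x, "data_array")

# units of an array field whether inline or persisted
array_units <- function(x) x$units

violation <- function(field, problem) list(field = field, problem = problem)

#' Validate an object's attributes against its kind schema
#'
#' Checks required attributes, unit dimensions, parent kinds (when a
#' store is supplied to resolve references), spike-time ordering and
#' bounds, and — for metadata sections — that parent links do not form a
#' cycle. Spike trains with unsorted times are rejected rather than
#' silently sorted.
#'
#' @param kind object kind name.
#' @param fields named list of attribute values: text/number scalars,
#'   [quantity()] objects, [array_values()] (or persisted array
#'   references), and parent-object ids.
#' @param store optionally, an [object_store()] used to resolve parent
#'   references (existence, kind, section-cycle detection).
#' @param id the object's own id, if it already exists (needed for
#'   section cycle detection on update).
#' @return list with `ok` (logical) and `violations`, a tibble with
#'   columns `field` and `problem` (zero rows when valid).
#' @examples
#' validate_object("event", list(label = "stimulus", time = quantity(120, "ms"),
#'                               segment = "AAAAAAAAAA"))
#' @export
validate_object <- function(kind, fields, store = NULL, id = NULL) {
  schema <- object_schema(kind)
  v <- list()
  known <- c(names(schema$attrs), names(schema$parents), "metadata")

  for (f in setdiff(names(fields), known)) {
    v[[length(v) + 1L]] <- violation(f, "unknown attribute")
  }

  for (a in names(schema$attrs)) {
    spec <- schema$attrs[[a]]
    val <- fields[[a]]
    if (is.null(val)) {
      if (isTRUE(spec$required)) v[[length(v) + 1L]] <- violation(a, "missing required attribute")
      next
    }
    v <- c(v, check_attr(a, spec, val))
  }

  for (p in names(schema$parents)) {
    spec <- schema$parents[[p]]
    val <- fields[[p]]
    if (is.null(val)) {
      if (isTRUE(spec$required)) v[[length(v) + 1L]] <- violation(p, "missing required attribute")
      next
    }
    if (!is.character(val) || length(val) != 1L) {
      v[[length(v) + 1L]] <- violation(p, "parent reference must be a single id")
      next
    }
    if (!is.null(store)) {
      rec <- store$peek(val)
      if (is.null(rec)) {
        v[[length(v) + 1L]] <- violation(p, "parent object not found")
      } else if (!identical(rec$kind, spec$kind)) {
        v[[length(v) + 1L]] <- violation(p, "bad parent kind")
      }
    }
  }

  if (!is.null(fields$metadata)) {
    if (!is.character(fields$metadata)) {
      v[[length(v) + 1L]] <- violation("metadata", "metadata must be a vector of value ids")
    }
  }

  if (identical(kind, "spiketrain")) v <- c(v, check_spiketrain(fields))
  if (identical(kind, "analogsignal")) v <- c(v, check_analogsignal(fields))
  if (identical(kind, "section") && !is.null(store)) {
    v <- c(v, check_section_cycle(fields, store, id))
  }

  list(
    ok = length(v) == 0L,
    violations = tibble::tibble(
      field = vapply(v, `[[`, "", "field"),
      problem = vapply(v, `[[`, "", "problem")
    )
  )
}

check_attr <- function(name, spec, val) {
  v <- list()
  switch(spec$type,
    text = {
      if (!is.character(val) || length(val) != 1L) {
        v[[length(v) + 1L]] <- violation(name, "must be a single text value")
      }
    },
    number = {
      if (!is.numeric(val) || length(val) != 1L) {
        v[[length(v) + 1L]] <- violation(name, "must be a single number")
      }
    },
    scalar = {
      if (!(is.character(val) || is.numeric(val)) || length(val) != 1L) {
        v[[length(v) + 1L]] <- violation(name, "must be a single text or numeric value")
      }
    },
    quantity = {
      if (!is_quantity(val) || length(val$value) != 1L) {
        v[[length(v) + 1L]] <- violation(name, "must be a quantity with units")
      } else if (!identical(unit_dimension(val$units), spec$dim)) {
        v[[length(v) + 1L]] <- violation(name, "wrong unit dimension")
      }
    },
    array = {
      if (!(is_array_values(val) || is_data_array(val))) {
        v[[length(v) + 1L]] <- violation(name, "must be array values with units")
      } else if (!identical(unit_dimension(array_units(val)), spec$dim)) {
        v[[length(v) + 1L]] <- violation(name, "wrong unit dimension")
      }
    }
  )
  v
}

check_spiketrain <- function(fields) {
  v <- list()
  times <- fields$times
  if (!is_array_values(times)) return(v)  # persisted ref: checked on write
  if (is.unsorted(times$data)) {
    v[[length(v) + 1L]] <- violation("times", "spike times must be non-decreasing")
    return(v)
  }
  if (length(times$data) > 0 && is_quantity(fields$t_start) && is_quantity(fields$t_stop)) {
    t <- times$data * .unit_table$time[[times$units]]
    t0 <- canonical_value(fields$t_start, "time")
    t1 <- canonical_value(fields$t_stop, "time")
    if (min(t) < t0) v[[length(v) + 1L]] <- violation("times", "spike time before t_start")
    if (max(t) >= t1) v[[length(v) + 1L]] <- violation("times", "spike time at or after t_stop")
  }
  v
}

check_analogsignal <- function(fields) {
  v <- list()
  sr <- fields$sampling_rate
  if (is_quantity(sr) && length(sr$value) == 1L && sr$value <= 0) {
    v[[length(v) + 1L]] <- violation("sampling_rate", "sampling rate must be positive")
  }
  v
}

check_section_cycle <- function(fields, store, id) {
  v <- list()
  parent <- fields$parent_section
  if (is.null(parent)) return(v)
  seen <- if (is.null(id)) character() else id
  cur <- parent
  while (!is.null(cur)) {
    if (cur %in% seen) {
      v[[length(v) + 1L]] <- violation("parent_section", "section cycle")
      return(v)
    }
    seen <- c(seen, cur)
    rec <- store$peek(cur)
    if (is.null(rec)) break
    cur <- rec$fields$parent_section
  }
  v
}
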