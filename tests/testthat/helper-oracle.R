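# Independent brute-force oracles. These deliberately re-derive expected
# results from first principles (explicit timestamp enumeration, replay
# of an operation log, naive filtering loops) and share no code with the
# implementation paths they check.

# --- slicing: enumerate every sample timestamp ---------------------------

oracle_slice_indices <- function(t0, rate_hz, len, start_s, end_s) {
  ts <- t0 + (seq_len(len) - 1) / rate_hz
  hit <- which(ts >= start_s & ts < end_s)
  if (length(hit) == 0) return(NULL)
  c(first = min(hit) - 1L, last = max(hit) - 1L)
}

# --- versioning: replay the operation log truncated at t -----------------

# log entries: list(op = "create"|"update"|"delete", time, fields)
oracle_replay_state <- function(log, t) {
  state <- NULL
  alive <- FALSE
  for (entry in log) {
    if (entry$time > t) break
    if (entry$op == "create") {
      state <- entry$fields
      alive <- TRUE
    } else if (entry$op == "update") {
      for (k in names(entry$fields)) state[[k]] <- entry$fields[[k]]
    } else if (entry$op == "delete") {
      alive <- FALSE
    }
  }
  if (!alive) NULL else state
}

# --- access: restated from the sharing rules -----------------------------

oracle_access <- function(acl, actor) {
  if (!is.null(actor) && identical(actor, acl$owner)) return("read-write")
  if (!is.null(actor) && actor %in% names(acl$shared_with)) {
    return(unname(acl$shared_with[[actor]]))
  }
  if (identical(acl$safety_level, "public")) return("read")
  "none"
}

# --- queries: naive filtering loops --------------------------------------

.oracle_parents <- list(
  segment = c(block = "block"),
  recordingchannelgroup = c(block = "block"),
  recordingchannel = c(recordingchannelgroup = "recordingchannelgroup"),
  unit = c(recordingchannelgroup = "recordingchannelgroup"),
  analogsignal = c(segment = "segment", recordingchannel = "recordingchannel"),
  spiketrain = c(segment = "segment", unit = "unit"),
  event = c(segment = "segment"),
  section = c(parent_section = "section", block = "block"),
  property = c(section = "section"),
  value = c(property = "property"),
  block = character()
)

.oracle_unit_factor <- c(
  s = 1, ms = 1e-3, us = 1e-6, Hz = 1, kHz = 1e3, V = 1, mV = 1e-3, uV = 1e-6
)

oracle_field_value <- function(rec, field) {
  v <- rec$fields[[field]]
  if (is.null(v)) return(NULL)
  if (inherits(v, "quantity")) return(v$value * .oracle_unit_factor[[v$units]])
  if (inherits(v, "data_array") || inherits(v, "array_values")) return(NULL)
  v
}

oracle_lookup <- function(value, lookup, fv) {
  if (lookup == "isnull") stop("handled by caller")
  if (is.null(value)) return(FALSE)
  s <- as.character(value)
  fs <- as.character(fv)
  if (is.numeric(value)) {
    fn <- suppressWarnings(as.numeric(fv))
    if (lookup %in% c("exact", "gt", "gte", "lt", "lte")) {
      if (is.na(fn)) return(lookup == "exact" && s == fs)
      return(switch(lookup,
        exact = value == fn, gt = value > fn, gte = value >= fn,
        lt = value < fn, lte = value <= fn
      ))
    }
    if (lookup == "in") {
      set <- suppressWarnings(as.numeric(strsplit(fs, ",")[[1]]))
      return(value %in% set[!is.na(set)])
    }
  }
  switch(lookup,
    exact = s == fs,
    iexact = tolower(s) == tolower(fs),
    contains = grepl(fs, s, fixed = TRUE),
    icontains = grepl(tolower(fs), tolower(s), fixed = TRUE),
    startswith = substr(s, 1, nchar(fs)) == fs,
    `in` = s %in% strsplit(fs, ",")[[1]],
    gt = s > fs, gte = s >= fs, lt = s < fs, lte = s <= fs,
    FALSE
  )
}

# values of `field` reached from rec through relation names in `path`
oracle_reach <- function(store, rec, path, field) {
  if (length(path) == 0) return(list(oracle_field_value(rec, field)))
  rel <- path[1]
  parents <- .oracle_parents[[rec$kind]]
  targets <- list()
  if (rel %in% names(parents)) {
    pid <- rec$fields[[rel]]
    if (!is.null(pid)) {
      t <- store$peek(pid)
      if (!is.null(t)) targets <- list(t)
    }
  } else {
    # child relation: rel is a kind whose parent fields can point at rec
    for (child in store$snapshot(rel)) {
      cps <- .oracle_parents[[rel]]
      for (p in names(cps)) {
        if (cps[[p]] == rec$kind && identical(child$fields[[p]], rec$id)) {
          targets <- c(targets, list(child))
          break
        }
      }
    }
  }
  out <- list()
  for (t in targets) out <- c(out, oracle_reach(store, t, path[-1], field))
  out
}

oracle_filter_matches <- function(store, rec, f) {
  vals <- oracle_reach(store, rec, f$path, f$field)
  if (f$lookup == "isnull") {
    want <- tolower(as.character(f$value)) %in% c("true", "1", "yes")
    present <- length(vals) > 0 && any(!vapply(vals, is.null, logical(1)))
    return(if (want) !present else present)
  }
  for (v in vals) if (oracle_lookup(v, f$lookup, f$value)) return(TRUE)
  FALSE
}

# full naive query: returns the ids in stable (valid_from, id) order,
# unpaginated
oracle_query_ids <- function(store, kind, actor, filters = list(),
                             owner = NULL, metadata = NULL) {
  hits <- list()
  for (rec in store$snapshot(kind)) {
    if (oracle_access(store$get_acl(rec$id), actor) == "none") next
    if (!is.null(owner) && !identical(rec$owner, owner)) next
    ok <- TRUE
    for (f in filters) {
      if (!oracle_filter_matches(store, rec, f)) { ok <- FALSE; break }
    }
    if (!ok) next
    if (!is.null(metadata) && !all(metadata %in% rec$fields$metadata)) next
    hits[[length(hits) + 1]] <- rec
  }
  ord <- order(
    vapply(hits, `[[`, numeric(1), "valid_from"),
    vapply(hits, `[[`, character(1), "id")
  )
  vapply(hits[ord], `[[`, character(1), "id")
}

query_ids <- function(store, kind, actor, filters = list(), owner = NULL,
                      metadata = NULL, offset = 0, max_results = 1000) {
  spec <- query_spec(kind,
    filters = filters, metadata_values = metadata, owner = owner,
    offset = offset, max_results = max_results
  )
  res <- evaluate_query(store, spec, actor)
  vapply(res$records, `[[`, character(1), "id")
}

qfilter <- function(field, lookup = "exact", value, path = character()) {
  list(path = path, field = field, lookup = lookup, value = value)
}
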