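# HDF5 persistence for numeric arrays. Every array attribute (analog
# signal samples, spike times) is stored as one dataset named "data" in
# the root of its own HDF5 file; the owning object keeps a reference
# (file id, length, units). Sliced downloads carry raw numbers only --
# units and start times live on the parent object.

data_array <- function(file_id, length, units, dtype = "double") {
  structure(
    list(file_id = file_id, length = as.integer(length), units = units, dtype = dtype),
    class = "data_array"
  )
}

h5_array_path <- function(dir, file_id) file.path(dir, paste0(file_id, ".h5"))

h5_write_array <- function(path, values) {
  rhdf5::h5createFile(path)
  if (length(values) == 0L) {
    rhdf5::h5createDataset(path, "data", dims = 0, storage.mode = "double")
  } else {
    rhdf5::h5write(as.numeric(values), path, "data")
  }
  invisible(path)
}

h5_read_array <- function(path, first = NULL, last = NULL, length = NULL) {
  if (!file.exists(path)) stop_not_found("datafile not found")
  if (is.null(first) && is.null(last)) {
    return(as.numeric(rhdf5::h5read(path, "data")))
  }
  check_array_bounds(first, last, length)
  if (length == 0L) return(numeric(0))
  as.numeric(rhdf5::h5read(path, "data", index = list((first + 1L):(last + 1L))))
}

# 0-based inclusive bounds, both required together
check_array_bounds <- function(first, last, length) {
  if (is.null(first) || is.null(last)) {
    stop_bad_request("both first and last indices must be given")
  }
  first <- as.numeric(first); last <- as.numeric(last)
  if (is.na(first) || is.na(last) || first != floor(first) || last != floor(last)) {
    stop_bad_request("array indices must be integers")
  }
  if (first < 0 || last < first || last >= length) {
    stop_bad_request(sprintf(
      "index bounds [%s, %s] invalid for array of length %d", first, last, length
    ))
  }
  invisible(TRUE)
}

#' Persist a numeric array
#'
#' Writes the values as a single HDF5 dataset in the root of a new file
#' under the store's data directory and returns a reference carrying the
#' file id, length and units.
#'
#' @param store an [object_store()].
#' @param values numeric vector (may be empty).
#' @param units unit symbol for the values.
#' @return a `data_array` reference with fields `file_id`, `length`,
#'   `units`.
#' @export
store_array <- function(store, values, units = "V") {
  store$store_array(values, units)
}

#' Load a persisted array, optionally a contiguous slice
#'
#' @param store an [object_store()].
#' @param file_id the array's file id.
#' @param first,last optional 0-based inclusive index bounds; both or
#'   neither. `load_array(store, id, 50, 149)` returns 100 values.
#' @return numeric vector.
#' @export
load_array <- function(store, file_id, first = NULL, last = NULL) {
  store$load_array(file_id, first, last)
}
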