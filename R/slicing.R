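# Partial data requests: convert a requested time window into inclusive
# array index bounds, using the object's own attributes (start time,
# sampling rate) and their units. Windows are half-open [start, end), so
# slices over a partition of the time axis compose back to the full
# signal with no duplicates or gaps.

# relative tolerance on canonical seconds for boundary comparisons;
# absorbs float error introduced by unit conversion
.slice_tol <- 1e-9

#' Resolve time-window request parameters against an object
#'
#' Missing `start_time` defaults to the object's `t_start`; the window
#' end comes from `end_time` or `start + duration`, defaulting to the end
#' of the signal. At most one of `end_time` and `duration` may be given.
#' The window is half-open: `[start, end)`.
#'
#' @param params list with optional entries `start_time`, `end_time`,
#'   `duration`, each a [quantity()] with time units.
#' @param t_start the object's start time ([quantity()]).
#' @param t_stop the end of the object's time axis ([quantity()]): a
#'   spike train's `t_stop`, or `t_start + length / sampling_rate` for a
#'   signal.
#' @return a `slice_window`: list with `start` and `end` in canonical
#'   seconds.
#' @examples
#' resolve_slice_window(
#'   list(start_time = quantity(50, "ms"), duration = quantity(100, "ms")),
#'   t_start = quantity(0, "ms"), t_stop = quantity(1, "s")
#' )
#' @export
resolve_slice_window <- function(params, t_start, t_stop) {
  if (!is.null(params$end_time) && !is.null(params$duration)) {
    stop_bad_request("give at most one of end_time and duration")
  }
  t0 <- canonical_value(t_start, "time")
  t1 <- canonical_value(t_stop, "time")
  start <- if (is.null(params$start_time)) t0 else canonical_value(params$start_time, "time")
  end <- if (!is.null(params$end_time)) {
    canonical_value(params$end_time, "time")
  } else if (!is.null(params$duration)) {
    start + canonical_value(params$duration, "time")
  } else {
    t1
  }
  if (!(start < end)) stop_bad_request("empty time window: start must precede end")
  if (end <= t0 || start >= t1) {
    stop_bad_request("requested window lies entirely outside the signal")
  }
  structure(list(start = start, end = end), class = "slice_window")
}

# smallest integer >= x, treating near-integers (relative tol) as exact
ceil_tol <- function(x) {
  r <- round(x)
  if (abs(x - r) <= .slice_tol * max(1, abs(x))) r else ceiling(x)
}

#' Index bounds of the samples falling in a time window
#'
#' Sample `i` (0-based) of a regularly sampled signal sits at
#' `t_start + i / sampling_rate`. Returns the inclusive 0-based bounds of
#' the samples with `start <= t_i < end`, clamped to the array, erroring
#' if no sample falls inside the window. Comparisons use a relative
#' tolerance of 1e-9 on canonical seconds so unit conversion cannot
#' shift a boundary sample off by one.
#'
#' @param window a [resolve_slice_window()] result.
#' @param t_start signal start time ([quantity()]).
#' @param sampling_rate signal sampling rate ([quantity()]).
#' @param length number of stored samples (> 0).
#' @return list with `first_index` and `last_index` (0-based, inclusive).
#' @examples
#' w <- resolve_slice_window(
#'   list(start_time = quantity(50, "ms"), duration = quantity(100, "ms")),
#'   quantity(0, "s"), quantity(1, "s")
#' )
#' slice_indices(w, quantity(0, "s"), quantity(1, "kHz"), 1000)  # 50..149
#' @export
slice_indices <- function(window, t_start, sampling_rate, length) {
  if (length <= 0) stop_bad_request("cannot slice an empty array")
  t0 <- canonical_value(t_start, "time")
  rate <- canonical_value(sampling_rate, "frequency")
  if (rate <= 0) stop_bad_request("sampling rate must be positive")
  first <- ceil_tol((window$start - t0) * rate)          # first i with t_i >= start
  n_end <- (window$end - t0) * rate                      # i < n_end  <=>  t_i < end
  last <- ceil_tol(n_end) - 1
  first <- max(first, 0)
  last <- min(last, length - 1)
  if (first > last) stop_bad_request("no sample falls within the requested window")
  list(first_index = as.integer(first), last_index = as.integer(last))
}

#' Spike times falling in a time window
#'
#' @param times sorted numeric spike times, in canonical seconds.
#' @param window a [resolve_slice_window()] result.
#' @return the (possibly empty) subsequence of `times` in
#'   `[start, end)`, order preserved.
#' @export
slice_spiketrain <- function(times, window) {
  if (length(times) == 0L) return(numeric(0))
  tol_lo <- .slice_tol * max(1, abs(window$start))
  tol_hi <- .slice_tol * max(1, abs(window$end))
  times[times >= window$start - tol_lo & times < window$end - tol_hi]
}
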