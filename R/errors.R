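# Condition classes used across the store and the request dispatcher.
# Each class maps onto one HTTP status code in route_request().

store_error <- function(class, message, ...) {
  structure(
    class = c(class, "ephystore_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
}

stop_bad_request <- function(message, ...) stop(store_error("bad_request", message, ...))
stop_not_found   <- function(message, ...) stop(store_error("not_found", message, ...))
stop_forbidden   <- function(message, ...) stop(store_error("forbidden", message, ...))
stop_gone        <- function(message, ...) stop(store_error("gone", message, ...))
stop_conflict    <- function(message, ...) stop(store_error("precondition_failed", message, ...))
stop_not_allowed <- function(message, ...) stop(store_error("method_not_allowed", message, ...))
stop_unknown_type <- function(message, ...) stop(store_error(c("unknown_type", "bad_request"), message, ...))
stop_unit_dimension <- function(message, ...) stop(store_error(c("unit_dimension_error", "bad_request"), message, ...))

#' Map a store condition to an HTTP status code
#' @param cond a condition object
#' @return integer HTTP status
#' @keywords internal
http_status_for <- function(cond) {
  if (inherits(cond, "not_found")) return(404L)
  if (inherits(cond, "forbidden")) return(403L)
  if (inherits(cond, "gone")) return(410L)
  if (inherits(cond, "method_not_allowed")) return(405L)
  if (inherits(cond, "precondition_failed")) return(412L)
  if (inherits(cond, "bad_request")) return(400L)
  500L
}
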