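# Physical quantities: a numeric value plus a unit symbol from a closed
# table. Three dimensions are supported -- time, frequency, voltage --
# matching the attributes of the recorded-data object model (start times,
# sampling rates, signal amplitudes).

.unit_table <- list(
  time      = c(s = 1, ms = 1e-3, us = 1e-6),
  frequency = c(Hz = 1, kHz = 1e3),
  voltage   = c(V = 1, mV = 1e-3, uV = 1e-6)
)

.base_unit <- c(time = "s", frequency = "Hz", voltage = "V")

#' Create a physical quantity
#'
#' A quantity is a numeric value tagged with a unit symbol from a closed
#' table: time (`s`, `ms`, `us`), frequency (`Hz`, `kHz`) and voltage
#' (`V`, `mV`, `uV`). Unknown symbols are rejected rather than passed
#' through.
#'
#' @param value numeric scalar (or vector, e.g. spike times).
#' @param units unit symbol, one of `s, ms, us, Hz, kHz, V, mV, uV`.
#' @return an object of class `quantity` with fields `value` and `units`.
#' @examples
#' quantity(50, "ms")
#' canonicalize_quantity(quantity(50, "ms"), "time")   # 0.05 s
#' convert_quantity(quantity(1, "kHz"), "Hz")          # 1000 Hz
#' @export
quantity <- function(value, units) {
  if (!is.numeric(value)) stop_bad_request("quantity value must be numeric")
  dim <- unit_dimension(units)
  if (is.na(dim)) stop_unit_dimension(sprintf("unknown unit symbol '%s'", units))
  structure(list(value = as.numeric(value), units = units), class = "quantity")
}

is_quantity <- function(x) inherits(x, "quantity")

#' @export
format.quantity <- function(x, ...) paste(format(x$value, ...), x$units)

#' @export
print.quantity <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' Dimension of a unit symbol
#'
#' @param units unit symbol.
#' @return `"time"`, `"frequency"` or `"voltage"`; `NA` if unknown.
#' @export
unit_dimension <- function(units) {
  if (!is.character(units) || length(units) != 1L) return(NA_character_)
  for (dim in names(.unit_table)) {
    if (units %in% names(.unit_table[[dim]])) return(dim)
  }
  NA_character_
}

#' Rescale a quantity to the base unit of a dimension
#'
#' Base units are `s` (time), `Hz` (frequency) and `V` (voltage). The
#' quantity must already carry a unit of the expected dimension; a
#' mismatch (e.g. millivolts where a time is required) is an error, not a
#' coercion.
#'
#' @param q a [quantity()].
#' @param expected_dimension `"time"`, `"frequency"` or `"voltage"`.
#' @return a `quantity` in the base unit of the dimension.
#' @export
canonicalize_quantity <- function(q, expected_dimension) {
  if (!is_quantity(q)) stop_bad_request("not a quantity")
  expected_dimension <- match.arg(expected_dimension, names(.unit_table))
  dim <- unit_dimension(q$units)
  if (!identical(dim, expected_dimension)) {
    stop_unit_dimension(sprintf(
      "unit '%s' has dimension %s, expected %s", q$units, dim, expected_dimension
    ))
  }
  factor <- .unit_table[[dim]][[q$units]]
  quantity(q$value * factor, .base_unit[[dim]])
}

#' Convert a quantity to another unit of the same dimension
#'
#' @param q a [quantity()].
#' @param units target unit symbol.
#' @return a `quantity` expressed in `units`.
#' @export
convert_quantity <- function(q, units) {
  if (!is_quantity(q)) stop_bad_request("not a quantity")
  from_dim <- unit_dimension(q$units)
  to_dim <- unit_dimension(units)
  if (is.na(to_dim)) stop_unit_dimension(sprintf("unknown unit symbol '%s'", units))
  if (!identical(from_dim, to_dim)) {
    stop_unit_dimension(sprintf(
      "cannot convert %s (%s) to %s (%s)", q$units, from_dim, units, to_dim
    ))
  }
  factor <- .unit_table[[from_dim]][[q$units]] / .unit_table[[to_dim]][[units]]
  quantity(q$value * factor, units)
}

# numeric value in base units, for comparisons and index arithmetic
canonical_value <- function(q, expected_dimension) {
  canonicalize_quantity(q, expected_dimension)$value
}
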