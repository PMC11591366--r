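# Classed conditions so callers (and the command-line driver) can map
# failure modes to exit codes without string matching.

stop_cartscan <- function(msg, class, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "cartscan_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

stop_validation <- function(msg, ...) {
  stop_cartscan(msg, "cartscan_validation_error", ...)
}

stop_io <- function(msg, ...) {
  stop_cartscan(msg, "cartscan_io_error", ...)
}

stop_geometry <- function(msg, ...) {
  stop_cartscan(msg, "cartscan_geometry_error", ...)
}

stop_numerical <- function(msg, ...) {
  stop_cartscan(msg, "cartscan_numerical_error", ...)
}

stop_ambiguity <- function(msg, ...) {
  stop_cartscan(msg, c("cartscan_ambiguity_error", "cartscan_geometry_error"), ...)
}

#' Map a cartscan condition to a command-line exit code
#'
#' Exit-code contract used by the `inst/cli/cartscan.R` driver: 0 success,
#' 2 input/validation error, 3 geometry or coverage error, 4 numerical failure.
#'
#' @param cond A condition object.
#' @return Integer exit code.
#' @keywords internal
#' @export
exit_code_for <- function(cond) {
  if (inherits(cond, "cartscan_numerical_error")) return(4L)
  if (inherits(cond, "cartscan_geometry_error")) return(3L)
  if (inherits(cond, c("cartscan_validation_error", "cartscan_io_error"))) return(2L)
  2L
}
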