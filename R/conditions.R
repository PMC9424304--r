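#' Signal a classed error
#'
#' All package errors carry a condition class of the form `uvplume_<kind>` so
#' callers (and tests) can catch them precisely.
#'
#' @param class condition class suffix, e.g. "bounds_error"
#' @param message human-readable message
#' @param ... fields stored on the condition object
#' @noRd
uvp_stop <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("uvplume_", class), "uvplume_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' @noRd
uvp_warn <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("uvplume_", class), "uvplume_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cond)
}
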