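# Structured conditions: every error/log carries a class so callers and tests
# can dispatch on it rather than matching message text.

nm_stop <- function(msg, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "nm_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

nm_arg_error  <- function(msg, ...) nm_stop(msg, "nm_argument_error", sys.call(-1), ...)
nm_parse_error <- function(msg, line = NA_integer_, ...)
  nm_stop(msg, "nm_parse_error", sys.call(-1), line = line, ...)
nm_structure_error <- function(msg, ...) nm_stop(msg, "nm_structure_error", sys.call(-1), ...)
nm_geometry_error  <- function(msg, ...) nm_stop(msg, "nm_geometry_error", sys.call(-1), ...)

#' @noRd
nm_log <- function(msg, class = "nm_log") {
  message(structure(
    class = c(class, "nm_log", "message", "condition"),
    list(message = paste0(msg, "\n"), call = NULL)
  ))
}

# fallbacks/clamps that tests assert on
nm_fallback <- function(msg) nm_log(msg, class = "nm_fallback")
nm_warn <- function(msg, class = "nm_warning") {
  warning(structure(
    class = c(class, "nm_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}
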