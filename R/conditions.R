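# Typed condition helpers. Three error families so callers (and the CLI
# wrapper) can map failures to distinct exit codes:
#   carnsize_config_error  -- bad configuration / arguments
#   carnsize_data_error    -- malformed or inconsistent input data
#   carnsize_numeric_error -- numerical failure (singularity, non-convergence)

abort_typed <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "carnsize_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_config <- function(msg, ...) abort_typed("carnsize_config_error", msg, ...)
abort_data <- function(msg, ...) abort_typed("carnsize_data_error", msg, ...)
abort_numeric <- function(msg, ...) abort_typed("carnsize_numeric_error", msg, ...)

#' @keywords internal
msg_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
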