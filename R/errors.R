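#' @title Classed error helper
#' @description All famsim errors carry a class of the form
#'   `famsim_error_<name>` so callers and tests can catch specific failure
#'   modes rather than matching on message text.
#' @param class short error name, e.g. "dim_mismatch"
#' @param msg human-readable message
#' @param ... fields attached to the condition object
#' @keywords internal
famsim_stop <- function(class, msg, ...) {
  cond <- structure(
    class = c(paste0("famsim_error_", class), "famsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' @keywords internal
famsim_warn <- function(class, msg, ...) {
  cond <- structure(
    class = c(paste0("famsim_warning_", class), "famsim_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  warning(cond)
}

# assert that a file exists before attempting to read it
check_file_exists <- function(path) {
  if (!file.exists(path)) {
    famsim_stop("missing_file", sprintf("file does not exist: '%s'", path),
                path = path)
  }
  invisible(path)
}
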