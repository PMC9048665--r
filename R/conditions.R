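# Classed error conditions so callers (and the CLI) can distinguish
# bad configuration, bad user input, invalid domain objects and IO failures.

rve_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rve_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_config     <- function(msg, ...) rve_stop("rve_config_error", msg, ...)
stop_validation <- function(msg, ...) rve_stop("rve_validation_error", msg, ...)
stop_input      <- function(msg, ...) rve_stop("rve_input_error", msg, ...)
stop_io         <- function(msg, ...) rve_stop("rve_io_error", msg, ...)
stop_internal   <- function(msg, ...) rve_stop("rve_internal_error", msg, ...)

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
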