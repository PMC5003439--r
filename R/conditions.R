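# Classed error conditions so callers (and tests) can distinguish malformed
# files, invariant violations, bad configuration and I/O failures.

qc_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "qc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format     <- function(fmt, ...) qc_stop("qc_format_error", fmt, ...)
stop_validation <- function(fmt, ...) qc_stop("qc_validation_error", fmt, ...)
stop_config     <- function(fmt, ...) qc_stop("qc_config_error", fmt, ...)
stop_io         <- function(fmt, ...) qc_stop("qc_io_error", fmt, ...)
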