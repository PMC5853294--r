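# Condition constructors shared across the package. Every user-facing error
# carries a subclass so callers (and the CLI) can map failures to exit codes.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tagflux_input_error", "tagflux_error")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tagflux_config_error", "tagflux_error")))
}

stop_schema <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tagflux_schema_error", "tagflux_error")))
}

stop_undefined <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tagflux_undefined_error", "tagflux_error")))
}
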