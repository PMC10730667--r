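# Structured error conditions so the CLI can map failures to exit codes:
# parse/validation/input problems -> exit 2, anything else -> exit 1.

stop_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mfnj_parse_error", "mfnj_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mfnj_validation_error", "mfnj_error")))
}

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mfnj_input_error", "mfnj_error")))
}
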