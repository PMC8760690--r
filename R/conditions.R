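# Classed conditions so the CLI can map failures onto exit codes
# (2 = config/schema, 3 = domain) without string-matching messages.

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fiska_input_error", "fiska_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fiska_config_error", "fiska_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fiska_domain_error", "fiska_error")))
}
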