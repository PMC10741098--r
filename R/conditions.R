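# Classed conditions so callers (and tests) can distinguish configuration,
# input and file-format failures without matching message text.

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("polyratio_config_error", "polyratio_error")))
}

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("polyratio_input_error", "polyratio_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("polyratio_format_error", "polyratio_error")))
}

# Run log: every filter/drop is reported through here so it is visible and
# suppressible; tests assert on these messages.
pr_log <- function(fmt, ...) message("polyratio: ", sprintf(fmt, ...))
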