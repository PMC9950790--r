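# Classed conditions so callers can distinguish bad files from bad science.

ss_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "synergyscreen_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

format_error <- function(msg, ...) ss_error("format_error", msg, ...)

degenerate_input_error <- function(msg, ...) {
  ss_error("degenerate_input_error", msg, ...)
}

feature_unavailable_error <- function(msg, ...) {
  ss_error("feature_unavailable_error", msg, ...)
}

ss_log <- function(stage, msg, ...) {
  if (isTRUE(getOption("synergyscreen.quiet", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
  invisible(NULL)
}
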