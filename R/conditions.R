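# Classed conditions so callers (and tests) can distinguish failure modes.

rg_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "ratgait_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

rg_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "ratgait_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
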