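# Classed errors so callers and tests can match failures by condition class
# rather than message text.
gl_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "gaitlatentError", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  ))
}
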