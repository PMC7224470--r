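# Classed conditions so callers (and tests) can discriminate failure modes
# without matching message text.
agl_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "agl_error")))
}

agl_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "agl_warning")))
}
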