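# Structured error conditions. Every user-facing failure signals a condition
# of class c("codonsmith_error_<tag>", "codonsmith_error", "error") so callers
# (and tests) can branch on the tag rather than on message text.

cs_stop <- function(tag, msg, ..., call. = FALSE) {
  stop(errorCondition(
    sprintf(msg, ...),
    class = c(paste0("codonsmith_error_", tag), "codonsmith_error")
  ))
}

cs_warn <- function(tag, msg, ...) {
  warning(warningCondition(
    sprintf(msg, ...),
    class = c(paste0("codonsmith_warning_", tag), "codonsmith_warning")
  ))
}
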