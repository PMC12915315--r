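# Classed conditions used throughout the package. Every domain error carries a
# subclass so callers (and tests) can discriminate without matching messages.

tig_error <- function(class, message, ..., call = NULL) {
  data <- list(...)
  cnd <- structure(
    class = c(class, "tig_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
  stop(cnd)
}

tig_warning <- function(class, message, ...) {
  cnd <- structure(
    class = c(class, "tig_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  )
  warning(cnd)
}
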