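# Classed error conditions: every domain error carries a stable code as its
# condition class so callers (and tests) can dispatch on it.
stop_dietshift <- function(code, message, ...) {
  cond <- structure(
    class = c(code, "dietshift_error", "error", "condition"),
    list(message = sprintf(message, ...), call = sys.call(-1))
  )
  stop(cond)
}

warn_dietshift <- function(code, message, ...) {
  cond <- structure(
    class = c(code, "dietshift_warning", "warning", "condition"),
    list(message = sprintf(message, ...), call = sys.call(-1))
  )
  warning(cond)
}
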