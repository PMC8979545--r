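# Structured condition helpers: every domain error carries a subclass so
# callers (and the pipeline runner) can branch on the failure mode rather
# than parse messages.

stop_segtraj <- function(subclass, message, ..., call = sys.call(-1)) {
  data <- list(...)
  cond <- structure(
    class = c(subclass, "segtraj_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
  stop(cond)
}

warn_segtraj <- function(subclass, message, ..., call = sys.call(-1)) {
  data <- list(...)
  cond <- structure(
    class = c(subclass, "segtraj_warning", "warning", "condition"),
    c(list(message = message, call = call), data)
  )
  warning(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
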