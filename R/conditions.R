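# Classed conditions so callers (and tests) can discriminate failure modes
# without string matching.

pc_stop <- function(class, message, ..., call = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "pc_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}

pc_invalid_parameter <- function(message, ...) {
  pc_stop("pc_invalid_parameter", message, ..., call = sys.call(-1))
}

pc_invalid_state <- function(message, ...) {
  pc_stop("pc_invalid_state", message, ..., call = sys.call(-1))
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    pc_stop("pc_invalid_parameter", sprintf("%s must be finite numeric", what))
  }
  invisible(x)
}
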