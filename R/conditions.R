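# Classed conditions so callers can distinguish failure modes programmatically.

cmt_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("cmt_", class), "cmt_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

cmt_warn <- function(class, msg) {
  warning(structure(
    class = c(paste0("cmt_", class), "cmt_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    cmt_stop("invalid_argument", sprintf("'%s' must be finite numeric", name))
  }
  invisible(x)
}
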