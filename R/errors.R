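# Classed conditions so callers (and the CLI) can distinguish bad input,
# bad configuration, and computation failures.

stop_input <- function(msg, ...) {
  rlang::abort(msg, class = "fop_input_error", ...)
}

stop_config <- function(msg, ...) {
  rlang::abort(msg, class = "fop_config_error", ...)
}

stop_compute <- function(msg, ...) {
  rlang::abort(msg, class = "fop_compute_error", ...)
}

fop_warn <- function(msg) {
  rlang::warn(msg, class = "fop_warning")
}
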