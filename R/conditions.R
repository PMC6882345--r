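# Classed conditions so callers (and the CLI) can map error kinds to distinct
# exit codes.

gg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gwasgrid_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

gg_config_error     <- function(msg) gg_stop(msg, "gg_config_error")
gg_input_error      <- function(msg) gg_stop(msg, "gg_input_error")
gg_validation_error <- function(msg) gg_stop(msg, "gg_validation_error")
gg_capacity_error   <- function(msg) gg_stop(msg, "gg_capacity_error")
gg_io_error         <- function(msg) gg_stop(msg, "gg_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
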