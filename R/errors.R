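# Classed conditions so callers (and the CLI) can distinguish bad input from
# bad usage. Every package error inherits from "cytorec_error".

abort <- function(message, class) {
  stop(structure(
    class = c(class, "cytorec_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_parse      <- function(msg) abort(msg, "cytorec_parse_error")
abort_validation <- function(msg) abort(msg, "cytorec_validation_error")
abort_schema     <- function(msg) abort(msg, "cytorec_schema_error")
abort_length     <- function(msg) abort(msg, "cytorec_length_error")
abort_degenerate <- function(msg) abort(msg, "cytorec_degenerate_error")
abort_alignment  <- function(msg) abort(msg, "cytorec_alignment_error")
abort_training   <- function(msg) abort(msg, "cytorec_training_error")
abort_composition <- function(msg) abort(msg, "cytorec_composition_error")
abort_stratification <- function(msg) abort(msg, "cytorec_stratification_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
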