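# Classed conditions so callers can distinguish failure modes programmatically.
# All errors inherit "recalldyn_error".

abort_rdyn <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "recalldyn_error")))
}

abort_schema    <- function(msg, ...) abort_rdyn(msg, "rdyn_schema_error", ...)
abort_integrity <- function(msg, ...) abort_rdyn(msg, "rdyn_integrity_error", ...)
abort_duplicate <- function(msg, ...) abort_rdyn(msg, "rdyn_duplicate_error", ...)
abort_capacity  <- function(msg, ...) abort_rdyn(msg, "rdyn_capacity_error", ...)
abort_constraint <- function(msg, ...) abort_rdyn(msg, "rdyn_constraint_error", ...)
abort_undefined <- function(msg, ...) abort_rdyn(msg, "rdyn_undefined_error", ...)
abort_config    <- function(msg, ...) abort_rdyn(msg, "rdyn_config_error", ...)
abort_degenerate <- function(msg, ...) abort_rdyn(msg, "rdyn_degenerate_error", ...)
abort_lookup    <- function(msg, ...) abort_rdyn(msg, "rdyn_lookup_error", ...)
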