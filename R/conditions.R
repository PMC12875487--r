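# Classed conditions used across the package. Every domain error carries a
# subclass so callers (and tests) can distinguish contract violations from
# plain R errors.

abort_mtrf <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "musictrf_error")))
}

warn_mtrf <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "musictrf_warning")))
}

#' @keywords internal
stop_monophony <- function(msg) abort_mtrf("monophony_error", msg)
stop_format <- function(msg) abort_mtrf("format_error", msg)
stop_degenerate <- function(msg) abort_mtrf("degenerate_melody_error", msg)
stop_config <- function(msg) abort_mtrf("config_error", msg)
stop_empty_model <- function(msg) abort_mtrf("empty_model_error", msg)
stop_alphabet <- function(msg) abort_mtrf("alphabet_error", msg)
stop_alignment <- function(msg) abort_mtrf("alignment_error", msg)
stop_data <- function(msg) abort_mtrf("data_error", msg)
stop_data_quality <- function(msg) abort_mtrf("data_quality_error", msg)
stop_interpolation <- function(msg) abort_mtrf("interpolation_error", msg)
warn_power <- function(msg) warn_mtrf("power_warning", msg)
warn_data_quality <- function(msg) warn_mtrf("data_quality_warning", msg)
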