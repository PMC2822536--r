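# Classed conditions so callers (and detect_bimodal) can distinguish
# per-gene failure modes from programming errors.

stop_bimodr <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "bimodr_error"), call = call))
}

stop_degenerate <- function(msg) stop_bimodr(msg, "bimodr_degenerate_error")
stop_insufficient <- function(msg) stop_bimodr(msg, "bimodr_insufficient_error")
stop_parse <- function(msg) stop_bimodr(msg, "bimodr_parse_error")
stop_validation <- function(msg) stop_bimodr(msg, "bimodr_validation_error")
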