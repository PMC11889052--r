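# Classed conditions so callers (and tests) can distinguish contract
# violations from range/lookup/convergence failures.

ltra_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ltra_error"), call = call))
}

stop_contract <- function(msg) ltra_error(msg, "ltra_contract_error")
stop_range <- function(msg) ltra_error(msg, "ltra_range_error")
stop_lookup <- function(msg) ltra_error(msg, "ltra_lookup_error")
stop_convergence <- function(msg) ltra_error(msg, "ltra_convergence_error")
stop_config <- function(msg) ltra_error(msg, "ltra_config_error")
stop_consistency <- function(msg) ltra_error(msg, "ltra_consistency_error")

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
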