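# Structured error conditions so callers and tests can distinguish failure
# modes (format vs consistency vs leakage ...) without matching message text.

hsi_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message,
                      class = c(paste0("hsicnn_", class), "hsicnn_error"),
                      call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
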