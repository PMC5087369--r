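# Classed conditions so callers can distinguish failure modes programmatically.

stop_aiqp <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(paste0("aiqp_", subclass), "aiqp_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

#' @noRd
rms <- function(x) sqrt(mean(x^2))
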