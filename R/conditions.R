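# Classed conditions so the pipeline can react to specific failures
# (e.g. a missing segmentation class) without string-matching messages.

stop_dfameter <- function(subclass, message, ...) {
  cond <- structure(
    class = c(paste0("dfameter_", subclass), "dfameter_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}
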