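# Classed conditions so callers can distinguish failure modes programmatically.

lbp_error <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "lbp_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

lbp_format_error     <- function(msg, ...) lbp_error("lbp_format_error", msg, ...)
lbp_integrity_error  <- function(msg, ...) lbp_error("lbp_integrity_error", msg, ...)
lbp_enablement_error <- function(msg, ...) lbp_error("lbp_enablement_error", msg, ...)
lbp_domain_error     <- function(msg, ...) lbp_error("lbp_domain_error", msg, ...)
lbp_not_found_error  <- function(msg, ...) lbp_error("lbp_not_found_error", msg, ...)
lbp_version_error    <- function(msg, ...) lbp_error("lbp_version_error", msg, ...)
lbp_empty_plan_error <- function(msg, ...) lbp_error("lbp_empty_plan_error", msg, ...)
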