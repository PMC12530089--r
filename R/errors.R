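# Condition classes used across the package.  Every user-facing failure is
# one of: usage (bad CLI invocation), validation (bad arguments/config),
# io (filesystem), integrity (corrupt or inconsistent data), not_found
# (unknown read ID), capability (codec not available in this build).

abort_usage <- function(msg, ...) {
  abort(msg, class = c("sigrow_usage_error", "sigrow_error"), ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = c("sigrow_validation_error", "sigrow_error"), ...)
}

abort_io <- function(msg, ...) {
  abort(msg, class = c("sigrow_io_error", "sigrow_error"), ...)
}

abort_integrity <- function(msg, ...) {
  abort(msg, class = c("sigrow_integrity_error", "sigrow_error"), ...)
}

abort_not_found <- function(msg, ...) {
  abort(msg, class = c("sigrow_not_found_error", "sigrow_error"), ...)
}

abort_capability <- function(msg, ...) {
  abort(msg, class = c("sigrow_capability_error", "sigrow_error"), ...)
}

abort_conversion <- function(msg, ...) {
  abort(msg, class = c("sigrow_conversion_error", "sigrow_error"), ...)
}

# Re-classify C++ stop() messages that carry a "codec-range:" or
# "malformed-payload:" prefix.
reclassify_cpp_error <- function(expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (grepl("^codec-range:", msg)) abort_validation(msg)
    if (grepl("^malformed-payload:", msg)) abort_integrity(msg)
    if (inherits(e, "sigrow_error")) stop(e)
    abort_integrity(msg)
  })
}
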