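# Structured error classes. Every user-facing failure is classed so the
# command-line wrappers can map it onto a stable exit code:
#   schema/input errors      -> 2
#   statistical preconditions -> 3
#   internal inconsistencies  -> 4

stop_schema <- function(message, ...) {
  abort(message, class = c("regiqa_schema_error", "regiqa_error"), ...)
}

stop_precondition <- function(message, ...) {
  abort(message, class = c("regiqa_precondition_error", "regiqa_error"), ...)
}

stop_inconsistency <- function(message, ...) {
  abort(message, class = c("regiqa_inconsistency_error", "regiqa_error"), ...)
}

# Exit code associated with a condition, used by the CLI runners.
exit_code_for <- function(cond) {
  if (inherits(cond, "regiqa_schema_error")) return(2L)
  if (inherits(cond, "regiqa_precondition_error")) return(3L)
  if (inherits(cond, "regiqa_inconsistency_error")) return(4L)
  1L
}
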