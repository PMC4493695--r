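# Condition constructors. Argument errors (bad parameters, infeasible
# requests) and format errors (malformed input files) are distinguished so
# the command-line interface can map them to different exit codes.

hoodsArgumentError <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("hoods_argument_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

hoodsFormatError <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("hoods_format_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

.checkAlpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    hoodsArgumentError("'alpha' must be a single number in [0, 1]")
  as.numeric(alpha)
}

.checkMaxSize <- function(maxSize) {
  if (!is.numeric(maxSize) || length(maxSize) != 1L || is.na(maxSize) ||
      maxSize < 1)
    hoodsArgumentError("'maxSize' must be a single number >= 1 (or Inf)")
  maxSize
}
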