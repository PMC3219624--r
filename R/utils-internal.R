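# Internal helpers shared across modules.

# Error constructors: validation errors (bad inputs, schema violations) are
# distinguished from stage failures so callers (and the CLI) can map them to
# distinct exit codes.
validationError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("poolfit_validation_error", "poolfit_error")))
}

parameterError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("poolfit_parameter_error", "poolfit_error")))
}

calibrationError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("poolfit_calibration_error", "poolfit_error")))
}

stopifnotScalarCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    parameterError("'%s' must be a single integer >= %d (got %s)",
                   name, min, paste(format(x), collapse = ","))
  invisible(as.integer(x))
}

stopifnotProportion <- function(x, name, allowOne = TRUE) {
  hi <- if (allowOne) 1 else 1 - .Machine$double.eps
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > hi)
    parameterError("'%s' must be a single proportion in [0,%s]", name,
                   if (allowOne) "1" else "1)")
  invisible(as.numeric(x))
}

# Deterministic per-stage seed derived from a single global seed; keeps all
# derived seeds positive 32-bit integers.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + 97 * offset) %% 2147483629L) + 1L
}

# Median that returns NA (not an error) on empty input.
safeMedian <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

# Group-wise means of a long vector, returned aligned to `levels(group)`.
groupMeans <- function(x, group) {
  s <- rowsum(x, group, na.rm = TRUE)
  n <- rowsum(as.numeric(!is.na(x)), group)
  drop(s / n)
}
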