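# Internal helpers shared across modules.

# Deterministic child seed derivation; stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647L) * 7919 + offset) %% 2147483647L
}

# Classed conditions so callers can distinguish bad inputs from bad config
# and from estimation failures.
abort_input <- function(msg, ...) {
  abort(msg, class = "mrmediate_input_error", ...)
}
abort_config <- function(msg, ...) {
  abort(msg, class = "mrmediate_config_error", ...)
}
abort_estimation <- function(msg, ...) {
  abort(msg, class = "mrmediate_estimation_error", ...)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    abort_input(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s (got %s)",
      name, if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

z_crit <- function(level = 0.95) qnorm(1 - (1 - level) / 2)

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
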