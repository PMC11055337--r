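# internal helpers shared across modules

# scalar numeric check used by argument validation
is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_number(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside the admissible range %s%g, %g%s.",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

# (1 + r)^(-U), the single-rotation discount factor
discount_factor <- function(r, U) (1 + r)^(-U)

# derive a stream-specific 32-bit seed from a user seed; keeps independent
# stages decorrelated while remaining reproducible from one integer
derive_seed <- function(seed, stream) {
  stopifnot(is_number(seed))
  offsets <- c(
    panel = 104729L, adjacency = 1299709L, cost_inputs = 15485863L,
    sdm = 32452843L, lstm = 49979687L, effects = 67867967L,
    noise = 86028121L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 2654435761 + off) %% 2147483647)
}
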