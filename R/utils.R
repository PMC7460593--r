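# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("protonrbe_config_error", "error")))
}

#' @keywords internal
assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    stop_config("'", name, "' must be a finite numeric value")
  }
  if (any(x < lower) || any(x > upper)) {
    stop_config("'", name, "' must lie in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

# Scoped RNG: generators are pure functions of (parameters, seed) and leave
# the caller's RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  assert_number(seed, "seed")
  withr::with_seed(as.integer(seed), code)
}

# Derive distinct sub-seeds for pipeline stages from one master seed,
# kept below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483587L
}

label_condition <- function(mode, position) paste0(mode, position)
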