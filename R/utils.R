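# internal argument checks -------------------------------------------------

stop_input <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_input(name, " must be a single non-missing number")
  if (x < lower || x > upper)
    stop_input(name, " must be in [", lower, ", ", upper, "]")
  if (integer && x != round(x))
    stop_input(name, " must be a whole number")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}
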