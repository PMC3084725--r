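## internal helpers shared across modules

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# stop() with a consistent prefix and no call in the condition message
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# log-uniform draw on [lo, hi], both > 0
rloguniform <- function(n, lo, hi) {
  exp(runif(n, log(lo), log(hi)))
}
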