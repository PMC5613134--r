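# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up: 10% of 72 parents must give 7, not base round()'s banker 7/8 ambiguity
round_half_up <- function(x) floor(x + 0.5)

# per-set RNG substream: stable under changes of n_sets, stays below 2^31
substream_seed <- function(root_seed, index) {
  (as.integer(root_seed) + 7919L * as.integer(index)) %% 2147483647L
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
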