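# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  All stochastic operations in the package go
# through this so results are reproducible and never disturb the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

stop_dtiforge <- function(message, class) {
  abort(message, class = c(class, "dtiforge_error"))
}

assert_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x)) {
    stop_dtiforge(sprintf("`%s` must be a single integer", name),
                  "dtiforge_config_error")
  }
  as.integer(x)
}
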