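# Seed hygiene: every stochastic stage scopes its RNG use so that callers'
# RNG streams are untouched and results are reproducible from one integer.

local_seed <- function(seed, .env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = .env)
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + as.double(salt) * 16807) %% 2147483629)
}
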