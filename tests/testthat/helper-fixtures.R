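# Shared fixtures: small, deterministic, built in code.

specs_default <- load_bounds()

# a small study context reused across tests (3 years, all treatments)
ctx_small <- study_context(years = 3, weather_seed_base = 100L)

# one short-but-sufficient weather series + control treatment
weather_1 <- ctx_small$weather[[1]]
plan_w1 <- ctx_small$plans$W1

midpoints <- midpoint_defaults(specs_default)

# a valid non-midpoint parameter set used by determinism/recovery tests
offset_params <- function(specs = specs_default, shift = 0.18) {
  u <- 0.5 + shift * sin(seq_len(nrow(specs)))
  to_physical(u, specs)
}
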