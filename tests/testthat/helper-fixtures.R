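# Shared mini-scale fixture bundle, generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())

get_fixtures <- function() {
  if (is.null(.fixture_cache$fx)) .fixture_cache$fx <- make_fixtures(seed = 1)
  .fixture_cache$fx
}

# Scaled-down configuration for fast pipeline tests.
test_config <- function() scale_config(dbs_config(), N_c = 30, N_m = 24,
                                       fan_in = 14)
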