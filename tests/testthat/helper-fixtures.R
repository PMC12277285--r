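# Shared fixtures: tiny configurations and networks built in code.

# Minimal network (100 E + 25 I) for microcircuit-level checks; background
# off by default so drives can be controlled exactly.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(profile = "test", scale = 0.01, nu_ext_hz = 0, growth_s = 0,
         dt_ms = 0.1),
    list(...))
  do.call(default_config, args)
}

tiny_network <- function(cfg = tiny_config(), seed = 1L) {
  new_network(cfg, seed = seed)
}

# Deterministic synapse injection: replace the E-E multiset.
set_synapses <- function(net, pre, post) {
  net$ee_pre <- as.integer(pre)
  net$ee_post <- as.integer(post)
  net
}

# Bookkeeping view of an E-E synapse multiset.
bound_counts <- function(n_E, pre, post) {
  list(axon = tabulate(pre, nbins = n_E), dend = tabulate(post, nbins = n_E))
}

# Cache for expensive shared objects (grown networks, sweep tables),
# computed lazily once per test session.
.hsp_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .hsp_test_cache)) {
    assign(key, builder(), envir = .hsp_test_cache)
  }
  get(key, envir = .hsp_test_cache)
}
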