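# Shared fixtures and small oracles for the suite.

ad_net <- build_ad_network()

# final counts of the tracked species over an ensemble of single runs,
# replicate i seeded base + i - 1 (the package's ensemble stream contract)
replicate_finals <- function(fixture, species, n, t_end, seed = 42L,
                             method = "direct", tau = 0.4) {
  vapply(seq_len(n), function(i) {
    cfg <- sim_config(method, tau = tau, t_end = t_end, record_dt = t_end,
                      seed = seed + i - 1L)
    tr <- simulate_network(fixture$network, fixture$init, cfg)
    tr$state[nrow(tr$state), species]
  }, 0)
}

# random non-negative state over the default network's species
random_ad_state <- function(max_count = 1000) {
  stats::setNames(stats::runif(nrow(ad_net$species), 0, max_count),
                  ad_net$species$name)
}
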