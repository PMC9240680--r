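# a short run (12 years, 8 burn-in) for tests that only need a converged-ish
# structure, not the full study-length accumulation
short_config <- function() {
  cfg <- default_config()
  cfg$grid$n_years <- 12
  cfg$grid$burn_in_years <- 8
  cfg
}

# the canonical 5x5 dispersal grid; simulations are cached across test files
# because grid simulation dominates the suite runtime
.sim_cache <- new.env(parent = emptyenv())

cached_grid_sims <- function(key = "acc5", config = default_config(),
                             grid = default_dispersal_grid(5)) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_grid(config, grid)
  }
  .sim_cache[[key]]
}

cached_short_sims <- function() {
  cached_grid_sims("short3", short_config(),
                   default_dispersal_grid(3))
}

# constant-temperature environment pair for toy dynamics
constant_envs <- function(T_c = 15) {
  list(juvenile = site_environment(T_c, T_c),
       adult = site_environment(T_c, T_c))
}
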