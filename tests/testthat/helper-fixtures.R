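# Shared fixtures, memoized so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_positions <- function(n = 16, span = 2) seq(0, span, length.out = n)

# diffusive-kernel ensemble whose recurrent operator lies exactly in the
# span of the GLM derivative regressors (reference for model recovery)
fixture_ensemble <- function(noise_sd = 0.1) {
  ensemble_model(tau_ms = 20, gain = 1, threshold = 0,
                 kernel = local_kernel(fixture_positions(), a0 = 0.12, a2 = 0.02),
                 noise_sd = noise_sd)
}

fixture_field_params <- function() bidomain_params()

# small recording used by several modules
fixture_recording <- function() {
  memo("rec_small", {
    cfg <- generator_config(n_trials = 6, n_channels = 16, delay_ms = 120,
                            cue_angles_deg = c(0, 120, 240),
                            ensemble = fixture_ensemble(), master_seed = 42)
    simulate_recording(cfg)
  })
}

# recovery-scale generator config (validated scales for model comparison)
fixture_bmc_config <- function(ephaptic, seed) {
  generator_config(n_trials = 12, n_channels = 16, delay_ms = 400,
                   ensemble = fixture_ensemble(),
                   ephaptic = ephaptic,
                   field_params = if (ephaptic) fixture_field_params(),
                   coupling = 0.3, master_seed = seed)
}
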