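# Shared fixtures, computed once per run and cached.

.fixtures <- new.env(parent = emptyenv())

# chicken-feed reference trajectory (default params and scenario)
chicken_traj <- function() {
  if (is.null(.fixtures$chicken))
    .fixtures$chicken <- simulate_deb(deb_params(), deb_scenario())
  .fixtures$chicken
}

# noiseless observation series on the default sampling grid
chicken_obs_clean <- function() {
  if (is.null(.fixtures$obs_clean))
    .fixtures$obs_clean <- generate_observations(
      deb_params(), deb_scenario(), noise = noise_model(0, 0, seed = NULL))
  .fixtures$obs_clean
}

# random-but-valid parameter draw for property tests (call under local seed)
draw_params <- function() {
  deb_params(a_max = stats::runif(1, 0.8, 2.0),
             Y = stats::runif(1, 0.2, 0.8),
             m = stats::runif(1, 0.02, 0.2),
             s_max = stats::runif(1, 0.6, 2.5),
             x5 = stats::runif(1, 0.3, 0.9),
             k_B = stats::runif(1, 5, 20),
             x_A = stats::runif(1, 0.7, 0.95),
             k_A = stats::runif(1, 8, 25),
             Y_L = stats::runif(1, 0.2, 0.6))
}
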