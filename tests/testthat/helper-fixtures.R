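# Shared fixtures: small configurations and canned generating parameters.

tiny_config <- function(n_blocks = 2L, trials_per_block = 12L) {
  session_config(n_blocks = n_blocks, trials_per_block = trials_per_block)
}

# moderate hybrid parameters used across tests
theta_hybrid <- function() {
  param_vector(c_mf = 0.3, f_mf = 0.2,
               c_mb = c(0.3, 0.3, 0.25, 0.25, 0.2, 0.1),
               f_mb = 0.15, pr = 0.2, f_p = 0.5)
}

theta_pure_mf <- function(c_mf = 0.5) {
  param_vector(c_mf = c_mf, f_mf = 0.2, c_mb = 0, f_mb = 0, pr = 0.1,
               f_p = 0.5)
}

theta_pure_mb <- function(c_mb = 0.5) {
  param_vector(c_mf = 0, f_mf = 0, c_mb = c_mb, f_mb = 0.2, pr = 0.1,
               f_p = 0.5)
}

sim_test_session <- function(theta = theta_hybrid(), seed = 1,
                             config = session_config()) {
  map <- build_task_map(seed = seed)
  plan <- generate_session_plan(map, config, seed = seed + 1)
  simulate_session(theta, plan, seed = seed + 2)
}

# simulate a cohort at a single (point-mass) parameter vector
sim_point_cohort <- function(theta, n, seed, config = session_config()) {
  generate_synthetic_cohort(n, param_sampler = function(k) rep(list(theta), k),
                            config = config, seed = seed)
}
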