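# Shared fixtures: simulations are cached per test run so several test
# files can reuse the same trial without regenerating it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# clean baseline: no noise, perfectly periodic strides
sim_clean_baseline <- function() {
  cached("clean_baseline", simulate_trial(
    scenario_preset("baseline", kinematic_noise_sd = 0,
                    stride_duration_cv = 0, n_strides = 8,
                    emg_noise_floor = 0)))
}

sim_noisy_baseline <- function() {
  cached("noisy_baseline", simulate_trial(
    scenario_preset("baseline", n_strides = 8, seed = 4)))
}

sim_clean_iFL <- function() {
  cached("clean_iFL", simulate_trial(
    scenario_preset("iFL_moderate", kinematic_noise_sd = 0,
                    stride_duration_cv = 0, n_strides = 8, emg_noise_floor = 0),
    condition = "iFL", induction_side = "left"))
}

sim_clean_iHL <- function() {
  cached("clean_iHL", simulate_trial(
    scenario_preset("iHL_moderate", kinematic_noise_sd = 0,
                    stride_duration_cv = 0, n_strides = 8, emg_noise_floor = 0),
    condition = "iHL", induction_side = "left"))
}

events_of <- function(sim) detect_hindlimb_impacts(sim$trial)

# per-detected-impact error (s) against generator truth, nearest match
impact_errors <- function(detected, truth) {
  vapply(detected, function(d) min(abs(truth - d)), numeric(1))
}

# independent step-up false-discovery-rate adjustment (brute force oracle)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}
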