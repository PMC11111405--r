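# Shared fixtures: small, fast configurations used across test files.

# compact experiment: quick to simulate, enough structure for estimators
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 40, d_total = 20, d_used = 10, n_unfamiliar = 120,
         n_familiar = 20, n_trials = 4, seed = 1L),
    list(...))
  do.call(sim_config, args)
}

# noiseless linear population: gaussian noise with sd 0 and a gain small
# enough that rates never rectify
noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 12, d_total = 8, d_used = 4, n_unfamiliar = 60,
         n_familiar = 8, n_trials = 1, baseline_hz = 30, peak_hz = 36,
         noise_model = "gaussian", noise_sd = 0,
         shift_magnitude = 0, rotation_angle_deg = 0, familiar_gain = 1,
         seed = 2L),
    list(...))
  do.call(sim_config, args)
}

# faces + deterministic linear rates straight from a population model
# (no temporal structure); returns list(faces, R = cells x faces Hz)
linear_rates <- function(pop, faces, noise_sd = 0, axes = pop$axes,
                         seed = 99L) {
  F <- feature_matrix(faces, d_used = nrow(axes))
  R <- pop$c0 + (pop$g_rel * pop$gain_hz) * t(F %*% axes)
  if (noise_sd > 0) {
    R <- R + withr::with_seed(seed, matrix(rnorm(length(R), 0, noise_sd),
                                           nrow(R)))
  }
  R
}

expect_within <- function(x, lo, hi, label = NULL) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
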