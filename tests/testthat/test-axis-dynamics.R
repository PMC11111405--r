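test_that("axis similarity has the exact trivial values", {
  a <- list(coef = c(1, 0, 0))
  b <- list(coef = c(0, 1, 0))
  expect_equal(axis_similarity(a, a), 1)
  expect_equal(axis_similarity(a, b), 0)
  c60 <- list(coef = c(cos(pi / 3), sin(pi / 3), 0))
  expect_equal(axis_similarity(a, c60), 0.5, tolerance = 1e-12)
  expect_error(axis_similarity(a, list(coef = c(1, 0))),
               class = "facegeom_invalid_argument")
  expect_error(axis_similarity(a, list(coef = c(0, 0, 0))),
               class = "facegeom_undefined_similarity")
})

# small direct-rate fixture for UU/UF: 30 cells, 120 unfamiliar + 20
# familiar faces, optional rotated familiar axes
uu_uf_fixture <- function(angle_deg, seed = 1, noise_sd = 2,
                          gain_fam = 1) {
  cfg <- small_config(rotation_angle_deg = angle_deg, shift_magnitude = 0,
                      n_cells = 30, seed = seed)
  pop <- make_population(cfg)
  faces <- as_face_set(dplyr::bind_rows(
    sample_face_space(120, 10, seed = seed + 1, prefix = "u"),
    sample_face_space(20, 10, seed = seed + 2, familiar = TRUE, prefix = "f")
  ))
  F <- feature_matrix(faces)
  fam <- faces$familiar
  g <- pop$g_rel * pop$gain_hz
  R <- pop$c0 + g * t(F %*% pop$axes)
  R[, fam] <- pop$c0 + gain_fam * g * t(F[fam, ] %*% pop$axes_rotated)
  R <- R + withr::with_seed(seed + 3,
                            matrix(rnorm(length(R), 0, noise_sd), nrow(R)))
  rownames(R) <- pop$cell_ids
  list(R = R, faces = faces, pop = pop)
}

test_that("UU and UF are indistinguishable without rotation and attenuated with it", {
  fx0 <- uu_uf_fixture(0, seed = 10)
  cmp0 <- uu_uf_comparison(fx0$R, fx0$faces, n_heldout = 20, d_used = 10,
                           n_resamples = 10, seed = 3)
  expect_gt(attr(cmp0, "p_value"), 0.05)

  fx60 <- uu_uf_fixture(60, seed = 11)
  cmp60 <- uu_uf_comparison(fx60$R, fx60$faces, n_heldout = 20, d_used = 10,
                            n_resamples = 10, seed = 3)
  expect_lt(attr(cmp60, "p_value"), 0.001)
  # attenuation-corrected recovery: mean UF ~ mean UU * cos(60)
  expect_equal(attr(cmp60, "mean_uf"), attr(cmp60, "mean_uu") * 0.5,
               tolerance = 0.16)
})

test_that("mean UF decreases monotonically with rotation angle", {
  ufs <- vapply(c(0, 30, 60, 90), function(a) {
    fx <- uu_uf_fixture(a, seed = 20)
    attr(uu_uf_comparison(fx$R, fx$faces, n_heldout = 20, d_used = 10,
                          n_resamples = 8, seed = 2), "mean_uf")
  }, numeric(1))
  expect_true(all(diff(ufs) < 0))
})

test_that("axis comparisons are invariant to per-cell response rescaling", {
  fx <- uu_uf_fixture(45, seed = 30)
  cmp1 <- uu_uf_comparison(fx$R, fx$faces, n_heldout = 20, d_used = 10,
                           n_resamples = 5, seed = 4)
  scaled <- fx$R * runif(nrow(fx$R), 0.5, 2)
  cmp2 <- uu_uf_comparison(scaled, fx$faces, n_heldout = 20, d_used = 10,
                           n_resamples = 5, seed = 4)
  expect_equal(cmp1$uu, cmp2$uu, tolerance = 1e-10)
  expect_equal(cmp1$uf, cmp2$uf, tolerance = 1e-10)
})

test_that("pure gain scaling passes the contrast control", {
  # low-contrast faces at half gain, much noisier axis estimates: the
  # SNR-matched null must absorb the attenuation
  fx <- uu_uf_fixture(0, seed = 40, noise_sd = 6)
  lc <- sample_face_space(20, 10, seed = 44, prefix = "lc")
  Flc <- feature_matrix(lc)
  g <- fx$pop$g_rel * fx$pop$gain_hz
  Rlc <- fx$pop$c0 + 0.5 * g * t(Flc %*% fx$pop$axes) +
    withr::with_seed(45, matrix(rnorm(30 * 20, 0, 6), 30))
  R <- cbind(fx$R[, !fx$faces$familiar], Rlc)
  faces <- as_face_set(dplyr::bind_rows(
    fx$faces[!fx$faces$familiar, ],
    dplyr::mutate(lc, subset_tag = "low_contrast")
  ))
  control <- faces$subset_tag == "low_contrast"
  cmp <- contrast_control(R, faces, control, d_used = 10, seed = 5)
  expect_gt(attr(cmp, "p_value"), 0.05)
  # the attenuation itself is real: the null mean sits below the
  # full-contrast reference similarity yet matches the observation
  expect_lt(abs(attr(cmp, "mean_observed") - attr(cmp, "mean_null")), 0.1)

  # negative control: a rotated set mislabeled as contrast is detected
  fx60 <- uu_uf_fixture(60, seed = 41)
  cmp_neg <- contrast_control(fx60$R, fx60$faces, fx60$faces$familiar,
                              d_used = 10, seed = 5)
  expect_lt(attr(cmp_neg, "p_value"), 0.01)
})

test_that("time-resolved axis similarity finds the rotation onset only", {
  cfg <- small_config(rotation_angle_deg = 60, rotation_onset_ms = 200,
                      shift_magnitude = 0, familiar_gain = 1,
                      n_cells = 60, n_trials = 6, seed = 50)
  sim <- simulate_experiment(cfg)
  tr <- time_resolved_axis_similarity(sim$tensor, sim$faces, n_heldout = 20,
                                      d_used = 10, n_resamples = 12, seed = 6)
  # at this reduced scale (60 cells) detection power allows up to two
  # windows of delay past the onset
  expect_within(tr$latency_ms, 200, 240)
  # UU trace stays near its ceiling across time (stationary tuning)
  uu_post <- tr$uu$value[tr$uu$time_ms >= 150]
  expect_lt(diff(range(uu_post)), 0.25)

  cfg0 <- small_config(rotation_angle_deg = 0, shift_magnitude = 0,
                       familiar_gain = 1, n_cells = 60, seed = 51)
  sim0 <- simulate_experiment(cfg0)
  tr0 <- time_resolved_axis_similarity(sim0$tensor, sim0$faces,
                                       n_heldout = 20, d_used = 10,
                                       n_resamples = 6, seed = 6)
  expect_true(is.na(tr0$latency_ms))
})

test_that("UF deficit replicates across contexts while the rate sign flips", {
  cfg <- small_config(rotation_angle_deg = 60, rotation_onset_ms = 150,
                      shift_magnitude = 0, familiar_gain = 1,
                      context_gain_rare = 1.3, n_cells = 60,
                      n_unfamiliar = 300, n_familiar = 36, seed = 60)
  pop <- make_population(cfg)
  fam <- sample_face_space(36, 20, seed = 61, familiar = TRUE, prefix = "fam")
  unf <- sample_face_space(300, 20, seed = 62, prefix = "unfam")
  cfgA <- small_config(rotation_angle_deg = 60, rotation_onset_ms = 150,
                       shift_magnitude = 0, familiar_gain = 1,
                       context_gain_rare = 1.3, n_cells = 60,
                       n_unfamiliar = 300, n_familiar = 36,
                       n_trials = 12, seed = 60)
  expA <- make_context_experiment(pop, fam, unf, c(34, 16), cfgA, seed = 63)
  expB <- make_context_experiment(pop, fam, unf, c(36, 300), cfg, seed = 64)
  res <- cross_context_axis_stability(expA, expB, window = c(50, 300),
                                      n_resamples = 8, seed = 7, d_used = 10)
  cmp <- res$comparison
  expect_lt(cmp$rate_diff_hz[cmp$context == "A"], 0)
  expect_gt(cmp$rate_diff_hz[cmp$context == "B"], 0)
  expect_true(all(cmp$p_value < 0.01))
  expect_gt(res$mean_stability, 0.5)

  # without rotation, neither context shows a deficit
  cfg0 <- small_config(rotation_angle_deg = 0, shift_magnitude = 0,
                       familiar_gain = 1, context_gain_rare = 1.3,
                       n_cells = 60, n_unfamiliar = 300, n_familiar = 36,
                       seed = 65)
  pop0 <- make_population(cfg0)
  cfg0A <- small_config(rotation_angle_deg = 0, shift_magnitude = 0,
                        familiar_gain = 1, context_gain_rare = 1.3,
                        n_cells = 60, n_unfamiliar = 300, n_familiar = 36,
                        n_trials = 12, seed = 65)
  exp0A <- make_context_experiment(pop0, fam, unf, c(34, 16), cfg0A, seed = 66)
  exp0B <- make_context_experiment(pop0, fam, unf, c(36, 300), cfg0, seed = 67)
  res0 <- cross_context_axis_stability(exp0A, exp0B, window = c(50, 300),
                                       n_resamples = 8, seed = 7, d_used = 10)
  expect_true(all(res0$comparison$p_value > 0.01))
})
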