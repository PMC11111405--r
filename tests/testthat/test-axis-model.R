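test_that("noiseless ramp data is fit exactly", {
  # r = 3 * f1 + 1 over 100 faces
  faces <- sample_face_space(100, 6, seed = 11)
  F <- feature_matrix(faces)
  r <- 3 * F[, 1] + 1
  fit <- fit_axis(r, faces, ridge = 0, d_used = 6)
  raw <- fit$coef / fit$scale                 # undo feature standardization
  expect_equal(abs(sum(raw * c(1, 0, 0, 0, 0, 0)) / sqrt(sum(raw^2))), 1,
               tolerance = 1e-9)
  # intercept on raw features: c0 - sum(coef * center / scale)
  intercept_raw <- fit$c0 - sum(fit$coef * fit$center / fit$scale)
  expect_equal(intercept_raw, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("ridge fits match an independently coded normal-equations oracle", {
  set.seed(12)
  faces <- sample_face_space(200, 20, seed = 13)
  F <- feature_matrix(faces)
  truth <- rnorm(20)
  r <- as.numeric(F %*% truth) + rnorm(200, 0, 0.5)
  fit <- fit_axis(r, faces, ridge = 0)
  # oracle: explicit closed-form least squares on the standardized design
  X <- scale(F)
  beta <- solve(t(X) %*% X, t(X) %*% (r - mean(r)))
  expect_equal(unname(fit$coef), as.numeric(beta), tolerance = 1e-8)

  # with ridge: (X'X + lambda I) beta = X'y, lambda = ridge * tr(X'X) / d
  fit_r <- fit_axis(r, faces, ridge = 1e-3)
  lam <- 1e-3 * sum(X^2) / ncol(X)
  beta_r <- solve(t(X) %*% X + diag(lam, 20), t(X) %*% (r - mean(r)))
  expect_equal(unname(fit_r$coef), as.numeric(beta_r), tolerance = 1e-8)
})

test_that("rank-deficient designs error with advice unless ridge > 0", {
  faces <- sample_face_space(30, 4, seed = 14)
  faces$f4 <- faces$f3                     # collinear features
  r <- rnorm(30)
  expect_error(fit_axis(r, faces, ridge = 0, d_used = 4),
               class = "facegeom_rank_deficient")
  expect_silent(fit_axis(r, faces, ridge = 1e-6, d_used = 4))
})

test_that("axis fits are scale equivariant and rotation equivariant", {
  set.seed(15)
  faces <- sample_face_space(150, 8, seed = 16)
  F <- feature_matrix(faces)
  r <- as.numeric(F %*% rnorm(8)) + rnorm(150, 0, 0.3)
  fit1 <- fit_axis(r, faces, ridge = 0, d_used = 8)
  fit2 <- fit_axis(3 * r, faces, ridge = 0, d_used = 8)
  expect_equal(fit2$coef, 3 * fit1$coef, tolerance = 1e-10)
  expect_equal(fit2$c0, 3 * fit1$c0, tolerance = 1e-10)
  expect_equal(fit2$unit, fit1$unit, tolerance = 1e-10)

  # rotating the feature basis by orthogonal Q maps c -> Q c
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))
  faces_rot <- faces
  faces_rot[paste0("f", 1:8)] <- F %*% t(Q)
  fit3 <- fit_axis(r, faces_rot, ridge = 0, d_used = 8)
  # compare on raw (unstandardized) coefficients, where the map is exact
  raw1 <- fit1$coef / fit1$scale
  raw3 <- fit3$coef / fit3$scale
  expect_equal(as.numeric(raw3), as.numeric(Q %*% raw1), tolerance = 1e-8)
})

test_that("split-half axis consistency tracks trial count and noise", {
  base <- small_config(shift_magnitude = 0, rotation_angle_deg = 0,
                       familiar_gain = 1)
  sim <- simulate_experiment(base)
  sh4 <- split_half_axis_consistency(sim$tensor, sim$faces, n_splits = 5,
                                     seed = 1, d_used = 10)
  # same population with fewer trials: lower consistency
  cfg2 <- small_config(shift_magnitude = 0, rotation_angle_deg = 0,
                       familiar_gain = 1, n_trials = 2)
  sim2 <- simulate_experiment(cfg2)
  sh2 <- split_half_axis_consistency(sim2$tensor, sim2$faces, n_splits = 5,
                                     seed = 1, d_used = 10)
  expect_gt(mean(sh4$mean_cosine), mean(sh2$mean_cosine))
  expect_gt(mean(sh4$mean_cosine), 0.5)
  # very weak tuning: consistency collapses
  cfg3 <- small_config(shift_magnitude = 0, rotation_angle_deg = 0,
                       familiar_gain = 1, n_trials = 2,
                       baseline_hz = 49.7, peak_hz = 50)
  sim3 <- simulate_experiment(cfg3)
  sh0 <- split_half_axis_consistency(sim3$tensor, sim3$faces, n_splits = 5,
                                     seed = 1, d_used = 10)
  expect_lt(mean(sh0$mean_cosine), 0.3)

  single <- facegeom:::subset_trials(sim$tensor, 1L)
  expect_error(split_half_axis_consistency(single, sim$faces),
               class = "facegeom_insufficient_data")
})

test_that("tuning curves are ramps for linear cells and flat when shuffled", {
  faces <- sample_face_space(300, 6, seed = 17)
  F <- feature_matrix(faces)
  truth <- c(2, 0, 0, 0, 0, 0)
  r <- as.numeric(F %*% truth) + rnorm(300, 0, 0.2)
  fit <- fit_axis(r, faces, d_used = 6)
  tc <- tuning_curve(fit, faces, r, n_points = 8)
  # binned means fall on a line
  lm_fit <- lm(mean_response ~ bin_center, data = tc$curve)
  expect_gt(summary(lm_fit)$r.squared, 0.98)
  expect_gt(coef(lm_fit)[2], 0)
  # shuffling responses across faces destroys the ramp
  r_shuf <- sample(r)
  tc2 <- tuning_curve(fit, faces, r_shuf, n_points = 8)
  slope <- coef(lm(mean_response ~ bin_center, data = tc2$curve))[2]
  expect_lt(abs(slope), 0.25 * abs(coef(lm_fit)[2]))
  expect_error(tuning_curve(fit, faces, r, n_points = 1),
               class = "facegeom_invalid_argument")
})

test_that("rotated familiar responses depart from the unfamiliar ramp", {
  cfg <- small_config(rotation_angle_deg = 70, rotation_onset_ms = 90,
                      shift_magnitude = 0, familiar_gain = 1, n_trials = 8)
  sim <- simulate_experiment(cfg)
  R <- window_response(sim$tensor, 100, 300)
  fam <- sim$faces$familiar
  fit <- fit_axes(R, sim$faces, d_used = 10, subset = !fam)
  i <- which.max(fit$r_squared)
  ref <- list(unit = fit$unit[, i], coef = fit$coef[, i],
              center = fit$center, scale = fit$scale)
  # residual of familiar responses from the unfamiliar ramp exceeds the
  # unfamiliar residual
  des_u <- feature_matrix(sim$faces, d_used = 10)
  X <- scale(des_u, center = ref$center, scale = ref$scale)
  proj <- as.numeric(X %*% ref$unit)
  ramp <- lm(R[i, !fam] ~ proj[!fam])
  pred_fam <- coef(ramp)[1] + coef(ramp)[2] * proj[fam]
  pred_unf <- fitted(ramp)
  expect_gt(mean(abs(R[i, fam] - pred_fam)),
            1.5 * mean(abs(R[i, !fam] - pred_unf)))
})
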