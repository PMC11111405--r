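test_that("RSA matrices recover block structure", {
  set.seed(3)
  # two categories with identical mean patterns vs an orthogonal third
  pat_a <- rnorm(40)
  pat_c <- rnorm(40)
  mk <- function(pat, n) pat + matrix(rnorm(40 * n, 0, 0.1), 40)
  rates <- cbind(mk(pat_a, 5), mk(pat_a, 5), mk(pat_c, 5))
  cats <- rep(c("fam_face", "unfam_face", "object"), each = 5)
  rsa <- rsa_matrix(rates, cats)
  expect_gt(rsa$matrix["fam_face", "unfam_face"],
            rsa$matrix["fam_face", "fam_face"] - 0.05)
  expect_lt(abs(rsa$matrix["fam_face", "object"]), 0.3)
  # single-exemplar categories mask their within-category entry
  rsa2 <- rsa_matrix(rates[, c(1, 6)], c("a", "b"))
  expect_true(is.na(rsa2$matrix["a", "a"]))
})

test_that("noiseless feature decoding inverts the encoding map", {
  cfg <- noiseless_config(n_cells = 20, d_used = 4)
  sim <- simulate_experiment(cfg)
  unfam <- which(!sim$faces$familiar)
  fam <- which(sim$faces$familiar)
  dec <- fit_feature_decoder(sim$tensor, sim$faces, train = unfam,
                             window = c(100, 200), d_used = 4,
                             ridge_rel = 1e-10)
  rec <- reconstruct_features(dec, sim$tensor, sim$faces, ids = unfam)
  expect_lt(rec$mse, 1e-8)
  # an orthogonal shift leaves reconstruction untouched (noiseless leakage)
  cfg_s <- noiseless_config(n_cells = 20, d_used = 4, shift_magnitude = 0.3,
                            shift_onset_ms = 90)
  sim_s <- simulate_experiment(cfg_s)
  dec_s <- fit_feature_decoder(sim_s$tensor, sim_s$faces, train = unfam,
                               window = c(100, 200), d_used = 4,
                               ridge_rel = 1e-10)
  rec_fam <- reconstruct_features(dec_s, sim_s$tensor, sim_s$faces, ids = fam)
  expect_lt(rec_fam$mse, 1e-10)
})

test_that("rotation at long latency breaks a short-latency-trained decoder", {
  cfg <- small_config(rotation_angle_deg = 60, rotation_onset_ms = 200,
                      shift_magnitude = 0, familiar_gain = 1,
                      n_cells = 60, n_trials = 6, seed = 71)
  sim <- simulate_experiment(cfg)
  unfam <- which(!sim$faces$familiar)
  fam <- which(sim$faces$familiar)
  short <- fit_feature_decoder(sim$tensor, sim$faces, train = unfam,
                               window = c(120, 170), d_used = 10)
  long <- fit_feature_decoder(sim$tensor, sim$faces, train = unfam,
                              window = c(220, 270), d_used = 10)
  err_short <- reconstruct_features(short, sim$tensor, sim$faces, ids = fam)
  err_long <- reconstruct_features(long, sim$tensor, sim$faces, ids = fam)
  sem <- sd(err_long$per_face$mse) / sqrt(length(fam))
  expect_gt(err_long$mse - err_short$mse, 3 * sem)
  # unfamiliar error is flat across epochs
  u_short <- reconstruct_features(short, sim$tensor, sim$faces, ids = unfam)
  u_long <- reconstruct_features(long, sim$tensor, sim$faces, ids = unfam)
  sem_u <- sd(u_long$per_face$mse) / sqrt(length(unfam))
  expect_lt(abs(u_long$mse - u_short$mse), 3 * sem_u)
})

test_that("identity-shuffled training gives a no-information error floor", {
  cfg <- small_config(shift_magnitude = 0, rotation_angle_deg = 0,
                      familiar_gain = 1, n_cells = 30, seed = 72,
                      t_start_ms = 100, t_end_ms = 200,
                      visual_onset_ms = 90)
  sim <- simulate_experiment(cfg)
  unfam <- which(!sim$faces$familiar)
  tr <- decode_features(sim$tensor, sim$faces, train = unfam[1:80],
                        test = unfam[81:120], width_ms = 50, step_ms = 50,
                        d_used = 10, shuffle_repeats = 5, seed = 3)
  # null MSE ~ feature variance (1) plus the shuffled decoder's own
  # prediction variance; informed decoding sits clearly below it
  expect_true(all(tr$null_level > 0.85 & tr$null_level < 2))
  expect_true(all(tr$value < 0.8 * tr$null_level))
})

test_that("familiarity decoding is at chance without effects and early with a shift", {
  cfg0 <- small_config(shift_magnitude = 0, rotation_angle_deg = 0,
                       familiar_gain = 1, seed = 73)
  sim0 <- simulate_experiment(cfg0)
  dec0 <- decode_familiarity(sim0$tensor, sim0$faces, n_perm = 40,
                             n_balance = 4, seed = 4)
  expect_true(is.na(latency_ms(dec0)))
  expect_lt(abs(mean(dec0$value) - 0.5), 0.1)

  cfg <- small_config(shift_magnitude = 2, shift_onset_ms = 100,
                      rotation_angle_deg = 0, familiar_gain = 1, seed = 74)
  sim <- simulate_experiment(cfg)
  dec <- decode_familiarity(sim$tensor, sim$faces, n_perm = 40,
                            n_balance = 4, seed = 4)
  expect_within(latency_ms(dec), 100, 120)
  expect_gt(mean(dec$value[dec$time_ms >= 200]), 0.9)
})

test_that("rotation alone delays familiarity decodability to its onset", {
  cfg <- small_config(shift_magnitude = 0, rotation_angle_deg = 60,
                      rotation_onset_ms = 200, familiar_gain = 1, seed = 75)
  sim <- simulate_experiment(cfg)
  dec <- decode_familiarity(sim$tensor, sim$faces, n_perm = 40,
                            n_balance = 4, seed = 4)
  lat <- latency_ms(dec)
  expect_true(is.na(lat) || lat >= 200)
})

test_that("centroid distance recovers an injected shift after debiasing", {
  cfg <- small_config(n_cells = 60, shift_magnitude = 1.5,
                      shift_onset_ms = 100, rotation_angle_deg = 0,
                      familiar_gain = 1, n_trials = 12, seed = 76)
  sim <- simulate_experiment(cfg)
  tr <- centroid_distance_trace(sim$tensor, sim$faces, normalize = "none",
                                width_ms = 100, step_ms = 50, seed = 5)
  injected <- 1.5 * sim$pop$sigma_pop
  asym <- mean(tr$excess[tr$time_ms >= 200])
  expect_lt(abs(asym - injected) / injected, 0.15)
  # no-effect control: familiar and matched-subset curves agree
  cfg0 <- small_config(n_cells = 60, shift_magnitude = 0,
                       rotation_angle_deg = 0, familiar_gain = 1,
                       n_trials = 12, seed = 77)
  sim0 <- simulate_experiment(cfg0)
  tr0 <- centroid_distance_trace(sim0$tensor, sim0$faces, normalize = "none",
                                 width_ms = 100, step_ms = 50, seed = 5)
  expect_true(all(abs(tr0$value - tr0$null_level) / tr0$null_level < 0.35))
})

test_that("d-prime matches the closed-form Gaussian answer", {
  # two unit-variance Gaussians, unit mean separation along a known axis
  set.seed(6)
  n <- 500
  R <- rbind(c(rnorm(n, 0), rnorm(n, 1)), matrix(rnorm(4 * 2 * n), 4))
  labels <- rep(c(FALSE, TRUE), each = n)
  res <- dprime_along_centroid(R, labels, n_shuffles = 200,
                               normalize = "none", seed = 7)
  expect_equal(res$dprime, 1.0, tolerance = 0.1)
  expect_true(res$significant)
  # identical distributions: d' ~ 0, not significant
  R0 <- matrix(rnorm(5 * 2 * n), 5)
  res0 <- dprime_along_centroid(R0, labels, n_shuffles = 200,
                                normalize = "none", seed = 7)
  expect_lt(res0$dprime, 0.2)
  expect_false(res0$significant)
})

test_that("d-prime significance time tracks the familiarity-decoding latency", {
  cfg <- small_config(shift_magnitude = 2, shift_onset_ms = 100,
                      rotation_angle_deg = 0, familiar_gain = 1, seed = 78)
  sim <- simulate_experiment(cfg)
  dpt <- dprime_trace(sim$tensor, sim$faces, n_shuffles = 100, seed = 8)
  dec <- decode_familiarity(sim$tensor, sim$faces, n_perm = 40,
                            n_balance = 4, seed = 8)
  expect_within(latency_ms(dpt), 100, 120)
  expect_lte(abs(latency_ms(dpt) - latency_ms(dec)), 10)
})

test_that("per-cell rate shifts are signed but balanced for an orthogonal shift", {
  cfg <- small_config(n_cells = 60, shift_magnitude = 2, shift_onset_ms = 100,
                      rotation_angle_deg = 0, familiar_gain = 1, seed = 79)
  sim <- simulate_experiment(cfg)
  rs <- rate_shift_distribution(sim$tensor, sim$faces,
                                windows = list(c(150, 300)))
  expect_gt(mean(rs$significant), 0.5)          # per-cell shifts detectable
  expect_gt(mean(rs$diff_hz > 0), 0.2)          # both signs present
  expect_gt(mean(rs$diff_hz < 0), 0.2)
  pop_p <- attr(rs, "population_tests")
  expect_gt(pop_p[[1]], 0.01)                   # population mean near zero

  # familiar suppression shifts the long-latency distribution negative
  cfg2 <- small_config(n_cells = 60, shift_magnitude = 0,
                       rotation_angle_deg = 0, familiar_gain = 0.7,
                       rotation_onset_ms = 200, seed = 80)
  sim2 <- simulate_experiment(cfg2)
  rs2 <- rate_shift_distribution(sim2$tensor, sim2$faces,
                                 windows = list(c(50, 200), c(200, 300)))
  med_by_win <- tapply(rs2$diff_hz, rs2$window, median)
  expect_lt(med_by_win[["[200,300)"]], -2)
  expect_gt(med_by_win[["[50,200)"]], -1)

  # no effects: significant fraction at the nominal level
  cfg3 <- small_config(n_cells = 60, shift_magnitude = 0,
                       rotation_angle_deg = 0, familiar_gain = 1, seed = 81)
  sim3 <- simulate_experiment(cfg3)
  rs3 <- rate_shift_distribution(sim3$tensor, sim3$faces,
                                 windows = list(c(50, 300)), alpha = 0.01)
  expect_lte(mean(rs3$significant), 0.05)
})

test_that("classifier and feature axes are orthogonal iff the shift is", {
  cfg <- small_config(n_cells = 100, shift_magnitude = 2,
                      shift_onset_ms = 100, rotation_angle_deg = 0,
                      familiar_gain = 1, seed = 82)
  sim <- simulate_experiment(cfg)
  unfam <- which(!sim$faces$familiar)
  clf <- fit_familiarity_classifier(sim$tensor, sim$faces,
                                    window = c(100, 300), seed = 2)
  dec <- fit_feature_decoder(sim$tensor, sim$faces, train = unfam,
                             window = c(100, 300), d_used = 10)
  orth <- familiarity_axis_orthogonality(clf, dec)
  expect_lt(mean(orth$abs_cosine), 0.15)

  sim_in <- simulate_experiment(cfg, shift_mode = "in_subspace")
  clf_in <- fit_familiarity_classifier(sim_in$tensor, sim_in$faces,
                                       window = c(100, 300), seed = 2)
  dec_in <- fit_feature_decoder(sim_in$tensor, sim_in$faces, train = unfam,
                                window = c(100, 300), d_used = 10)
  orth_in <- familiarity_axis_orthogonality(clf_in, dec_in)
  expect_gt(max(orth_in$abs_cosine), 0.5)
})

test_that("condition contrasts report normalized rate changes and preserved geometry", {
  cfg <- small_config(rotation_angle_deg = 60, rotation_onset_ms = 150,
                      shift_magnitude = 0, familiar_gain = 1,
                      n_cells = 60, seed = 83)
  sim <- simulate_experiment(cfg)
  # identical conditions: all changes zero
  cc0 <- condition_contrast(sim$tensor, sim$tensor, sim$faces,
                            n_heldout = 20, d_used = 10, n_resamples = 5)
  expect_true(all(abs(cc0$per_cell$change) < 1e-12))

  # condition B = global gain 1.5: normalized change (1.5-1)/(1.5+1) = 0.2
  tensorB <- sim$tensor
  tensorB$counts <- sim$tensor$counts * 1.5
  tensorB$normalized <- TRUE                 # real-valued counts
  cc <- condition_contrast(sim$tensor, tensorB, sim$faces,
                           n_heldout = 20, d_used = 10, n_resamples = 5)
  expect_equal(unique(round(cc$per_cell$change, 6)), 0.2)
  expect_gt(cc$paired_test$p_value, 0.05)    # both classes equally modulated
  # the UF deficit survives the gain change in both conditions
  expect_true(all(cc$axis_summaries$p_value < 0.01))
})
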