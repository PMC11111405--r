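test_that("the KS statistic matches the stats::ks.test oracle", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(25 + i)
    y <- rnorm(40, mean = runif(1, -1, 1))
    expect_equal(facegeom:::ks_stat(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y))$statistic),
                 tolerance = 1e-12)
  }
})

test_that("a perfect match is found when the pool contains the familiar set", {
  fam <- sample_face_space(12, 6, seed = 1, familiar = TRUE, prefix = "f")
  pool <- dplyr::bind_rows(
    dplyr::mutate(fam, face_id = paste0("copy_", face_id), familiar = FALSE),
    sample_face_space(100, 6, seed = 2, prefix = "u")
  )
  res <- match_subsets(fam, as_face_set(pool), k = 12, max_iter = 4000,
                       seed = 3)
  # the familiar side is the whole set; the pool side can reach objective 0
  # by selecting the duplicates
  expect_lt(res$objective_after, 0.4)
  expect_lt(max(res$per_feature_ks_after), 0.2)
})

test_that("a shifted feature is matched down to below half its divergence", {
  fam <- sample_face_space(36, 20, seed = 1, familiar = TRUE, prefix = "f")
  fam$f1 <- fam$f1 + 1
  pool <- sample_face_space(1000, 20, seed = 2, prefix = "u")
  res <- match_subsets(fam, pool, k = 30, max_iter = 4000, seed = 3)
  # brute-force verification on the returned subsets
  Ff <- feature_matrix(fam)[res$familiar_idx, ]
  Fu <- feature_matrix(pool)[res$unfamiliar_idx, ]
  ks1 <- unname(suppressWarnings(stats::ks.test(Ff[, 1], Fu[, 1]))$statistic)
  expect_equal(ks1, res$per_feature_ks_after[1], tolerance = 1e-12)
  # at k = 30 the KS statistic moves on a 1/30 grid; 0.2 = 6/30 is the
  # boundary notch and well below the same-distribution sampling
  # expectation for a max over 20 features
  expect_lte(max(res$per_feature_ks_after), 0.2)
  expect_lt(max(res$per_feature_ks_after),
            0.6 * max(res$per_feature_ks_before))
})

test_that("the objective trace is nonincreasing and bounded by max_iter", {
  fam <- sample_face_space(20, 8, seed = 4, familiar = TRUE, prefix = "f")
  pool <- sample_face_space(200, 8, seed = 5, prefix = "u")
  res <- match_subsets(fam, pool, k = 15, max_iter = 500, seed = 6)
  expect_true(all(diff(res$objective_trace) <= 0))
  expect_lte(length(res$objective_trace), 501)
  expect_true(res$improved)
  # determinism
  res2 <- match_subsets(fam, pool, k = 15, max_iter = 500, seed = 6)
  expect_identical(res$unfamiliar_idx, res2$unfamiliar_idx)
  expect_identical(res$objective_after, res2$objective_after)
})

test_that("degenerate sizes behave as documented", {
  fam <- sample_face_space(10, 4, seed = 7, familiar = TRUE, prefix = "f")
  pool <- sample_face_space(10, 4, seed = 8, prefix = "u")
  expect_error(match_subsets(fam, pool, k = 11),
               class = "facegeom_invalid_argument")
  # k equal to both set sizes: the subsets are the full sets
  res <- match_subsets(fam, pool, k = 10, max_iter = 50, seed = 9)
  expect_identical(res$familiar_idx, 1:10)
  expect_identical(res$unfamiliar_idx, 1:10)
})

test_that("matching reports recompute stored divergences exactly", {
  fam <- sample_face_space(25, 6, seed = 10, familiar = TRUE, prefix = "f")
  fam$f2 <- fam$f2 * 2
  pool <- sample_face_space(300, 6, seed = 11, prefix = "u")
  res <- match_subsets(fam, pool, k = 20, max_iter = 1000, seed = 12)
  rep <- matching_report(res, fam, pool)
  expect_equal(rep$objective, res$objective_after, tolerance = 1e-12)
  expect_equal(rep$per_feature$ks, res$per_feature_ks_after,
               tolerance = 1e-12)
  # an unmatchable feature (shifted far outside the pool's support) stays
  # divergent and gets flagged
  fam_bad <- fam
  fam_bad$f3 <- fam_bad$f3 + 5
  res0 <- match_subsets(fam_bad, pool, k = 20, max_iter = 200, seed = 13)
  rep0 <- matching_report(res0, fam_bad, pool)
  expect_true(rep0$per_feature$flagged[3])
})
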