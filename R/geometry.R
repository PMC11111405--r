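# Population-level coding analyses: representational similarity, feature
# and familiarity decoding, centroid geometry, d-prime with shuffle nulls,
# per-cell shift distributions, familiarity-axis orthogonality, and
# two-condition contrasts.

#' Representational similarity matrix across categories
#'
#' Pearson correlation between population response vectors, averaged over
#' exemplar pairs within each category pair. Within-category entries use
#' distinct-exemplar pairs only; the exemplar self-correlation diagonal is
#' reported separately.
#'
#' @param rates cells x stimuli matrix (e.g. from [window_response()]).
#' @param categories Character/factor labels, one per stimulus column.
#' @return List with `matrix` (category x category mean correlations; a
#'   within-category entry is `NA` when the category has < 2 exemplars) and
#'   `tidy` (long tibble).
#' @export
rsa_matrix <- function(rates, categories) {
  stopifnot(is.matrix(rates), ncol(rates) == length(categories))
  categories <- as.character(categories)
  cats <- unique(categories)
  C <- stats::cor(rates)
  out <- matrix(NA_real_, length(cats), length(cats),
                dimnames = list(cats, cats))
  for (i in seq_along(cats)) {
    for (j in seq_len(i)) {
      ii <- which(categories == cats[i])
      jj <- which(categories == cats[j])
      block <- C[ii, jj, drop = FALSE]
      if (i == j) {
        if (length(ii) < 2) next                     # masked: needs >= 2 exemplars
        vals <- block[lower.tri(block)]
      } else {
        vals <- as.numeric(block)
      }
      out[i, j] <- out[j, i] <- mean(vals)
    }
  }
  tidy_df <- as_tibble(as.table(out), .name_repair = "minimal")
  names(tidy_df) <- c("category_a", "category_b", "correlation")
  list(matrix = out, tidy = tidy_df)
}

# ridge decoder core: population rates (stimuli x cells, z-scored per cell
# upstream) -> targets. Returns weights (targets x cells) + intercepts.
fit_linear_decoder <- function(A, Y, ridge_rel = 1e-3) {
  Ac <- sweep(A, 2, colMeans(A), "-")
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  lam <- scaled_ridge(Ac, ridge_rel)
  W <- ridge_solve(Ac, Yc, ridge = lam)              # cells x targets
  intercepts <- colMeans(Y) - as.numeric(crossprod(W, colMeans(A)))
  list(weights = t(W), intercepts = intercepts, center = colMeans(A))
}

new_decoder_model <- function(kind, weights, intercepts, center, window,
                              training_tag, training_score) {
  structure(
    list(kind = kind, weights = weights, intercepts = intercepts,
         center = center, window = window, training_tag = training_tag,
         training_score = training_score),
    class = "decoder_model"
  )
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "<decoder_model: %s> %d targets x %d cells, window [%s, %s) ms, training score %.4g\n",
    x$kind, nrow(x$weights), ncol(x$weights), x$window[1], x$window[2],
    x$training_score))
  invisible(x)
}

#' Train a linear feature decoder
#'
#' Ridge regression from population activity to each face feature, trained
#' on a stimulus subset (typically unfamiliar faces) within one response
#' window.
#'
#' @param tensor A `response_tensor` (or cells x faces rate matrix).
#' @param faces Aligned `face_set`.
#' @param train Indices (or logical) of training faces.
#' @param window Response window, ms.
#' @param d_used Number of leading features to decode (default 20).
#' @param ridge_rel Relative ridge penalty.
#' @return A `decoder_model` with `kind = "feature_regressor"`; weights are
#'   targets x cells.
#' @export
fit_feature_decoder <- function(tensor, faces, train, window = c(50, 300),
                                d_used = 20, ridge_rel = 1e-3) {
  R <- rates_matrix(tensor, window)
  faces <- as_face_set(faces)
  Fm <- feature_matrix(faces, d_used = d_used)
  A <- t(R)[train, , drop = FALSE]
  Y <- Fm[train, , drop = FALSE]
  if (nrow(A) < 2 * d_used) {
    abort("need at least 2 * d_used training faces",
          class = "facegeom_insufficient_data")
  }
  dec <- fit_linear_decoder(A, Y, ridge_rel)
  pred <- reconstruct_matrix(dec, A)
  score <- mean((pred - Y)^2)
  new_decoder_model("feature_regressor", dec$weights, dec$intercepts,
                    dec$center, window, "train", score)
}

rates_matrix <- function(tensor, window) {
  if (inherits(tensor, "response_tensor")) {
    window_response(tensor, window[1], window[2])
  } else {
    stopifnot(is.matrix(tensor))
    tensor
  }
}

reconstruct_matrix <- function(dec, A) {
  sweep(A %*% t(dec$weights), 2, dec$intercepts, "+")
}

#' Reconstruct face features from population responses
#'
#' Applies a stored linear feature decoder to population activity and scores
#' the reconstruction against the true features (feature space only).
#'
#' @param model A `decoder_model` of kind `"feature_regressor"`.
#' @param tensor A `response_tensor` (or cells x faces rate matrix); the
#'   model's stored window is used.
#' @param faces Aligned `face_set` with the true features.
#' @param ids Indices (or logical) of faces to reconstruct (default all).
#' @return List with `features` (reconstructed matrix), `per_face` tibble
#'   (`face_id`, `mse`, `correlation`) and overall `mse`.
#' @export
reconstruct_features <- function(model, tensor, faces, ids = NULL) {
  stopifnot(inherits(model, "decoder_model"),
            model$kind == "feature_regressor")
  faces <- as_face_set(faces)
  R <- rates_matrix(tensor, model$window)
  d <- nrow(model$weights)
  Fm <- feature_matrix(faces, d_used = d)
  ids <- ids %||% seq_len(ncol(R))
  A <- t(R)[ids, , drop = FALSE]
  Y <- Fm[ids, , drop = FALSE]
  pred <- reconstruct_matrix(model, A)
  per_face <- tibble(
    face_id = faces$face_id[ids],
    mse = rowMeans((pred - Y)^2),
    correlation = vapply(seq_len(nrow(Y)), function(i) {
      suppressWarnings(stats::cor(pred[i, ], Y[i, ]))
    }, numeric(1))
  )
  list(features = pred, per_face = per_face, mse = mean(per_face$mse))
}

#' Time course of feature-decoding error
#'
#' Per rolling window, trains a ridge feature decoder on the training faces
#' and evaluates mean squared reconstruction error on the test faces. A
#' shuffle null (decoder trained after permuting stimulus identity,
#' `shuffle_repeats` times, averaged) gives the no-information level.
#'
#' @param tensor A `response_tensor`.
#' @param faces Aligned `face_set`.
#' @param train,test Indices (or logical) of training and test faces.
#' @param width_ms,step_ms Rolling window, ms.
#' @param d_used,ridge_rel Decoder parameters.
#' @param shuffle_repeats Identity-shuffle repeats for the null (default 10).
#' @param seed Seed for the shuffles.
#' @return A `geometry_trace` of test MSE with `sem` across faces and
#'   `null_level` from the shuffles.
#' @export
decode_features <- function(tensor, faces, train, test, width_ms = 50,
                            step_ms = 10, d_used = 20, ridge_rel = 1e-3,
                            shuffle_repeats = 10, seed = 1L) {
  stopifnot(inherits(tensor, "response_tensor"))
  faces <- as_face_set(faces)
  Fm <- feature_matrix(faces, d_used = d_used)
  train <- to_indices(train)
  test <- to_indices(test)
  win <- rolling_windows(tensor$t_start_ms, tensor$t_end_ms, width_ms, step_ms)
  rows <- purrr::pmap(win, function(t0, t1, time_ms) {
    A <- t(window_response(tensor, t0, t1))
    dec <- fit_linear_decoder(A[train, , drop = FALSE],
                              Fm[train, , drop = FALSE], ridge_rel)
    pred <- sweep(A[test, , drop = FALSE] %*% t(dec$weights), 2,
                  dec$intercepts, "+")
    err <- rowMeans((pred - Fm[test, , drop = FALSE])^2)
    null_mse <- withr::with_seed(child_seed(seed, time_ms), {
      mean(vapply(seq_len(shuffle_repeats), function(s) {
        perm <- sample(train)
        decs <- fit_linear_decoder(A[train, , drop = FALSE],
                                   Fm[perm, , drop = FALSE], ridge_rel)
        preds <- sweep(A[test, , drop = FALSE] %*% t(decs$weights), 2,
                       decs$intercepts, "+")
        mean((preds - Fm[test, , drop = FALSE])^2)
      }, numeric(1)))
    })
    tibble(time_ms = time_ms, value = mean(err),
           sem = sd(err) / sqrt(length(err)), null_level = null_mse)
  })
  geometry_trace(bind_rows(rows), method_tag = "feature decoding MSE")
}

to_indices <- function(x) {
  if (is.logical(x)) which(x) else as.integer(x)
}

#' Train a familiarity classifier
#'
#' Regularized linear classifier (ridge regression onto +/-1 labels) in the
#' per-cell z-scored population space, with the majority class subsampled
#' (repeated and averaged) so both classes carry equal weight.
#'
#' @param tensor A `response_tensor` (or cells x faces rate matrix).
#' @param familiar Logical over faces (or a `face_set`).
#' @param window Response window, ms.
#' @param n_balance Majority-subsample repeats (default 20).
#' @param ridge_rel Relative ridge penalty.
#' @param seed Seed for the subsampling.
#' @return A `decoder_model` with `kind = "familiarity_classifier"`; weights
#'   are 1 x cells, training score is balanced accuracy on the training data.
#' @export
fit_familiarity_classifier <- function(tensor, familiar, window = c(50, 300),
                                       n_balance = 20, ridge_rel = 1,
                                       seed = 1L) {
  R <- rates_matrix(tensor, window)
  if (inherits(tensor, "response_tensor")) {
    familiar <- familiar_flags(tensor, familiar)
  } else if (is.data.frame(familiar)) {
    familiar <- familiar$familiar
  }
  A <- t(normalize_per_cell(R, "zscore"))
  keep_cells <- colSums(is.na(A)) == 0
  A <- A[, keep_cells, drop = FALSE]
  w <- classifier_weights(A, familiar, n_balance, ridge_rel, seed)
  score <- balanced_accuracy(as.numeric(A %*% w$weights) + w$intercept > 0,
                             familiar)
  W <- matrix(0, 1, length(keep_cells))
  W[1, keep_cells] <- w$weights
  new_decoder_model("familiarity_classifier", W, w$intercept,
                    rep(0, length(keep_cells)), window, "train", score)
}

classifier_weights <- function(A, familiar, n_balance, ridge_rel, seed = NULL) {
  idx_f <- which(familiar); idx_u <- which(!familiar)
  n_min <- min(length(idx_f), length(idx_u))
  one_draw <- function(b) {
    sub <- c(sample(idx_f, n_min), sample(idx_u, n_min))
    y <- ifelse(familiar[sub], 1, -1)
    Ab <- A[sub, , drop = FALSE]
    Ac <- sweep(Ab, 2, colMeans(Ab), "-")
    lam <- scaled_ridge(Ac, ridge_rel)
    as.numeric(ridge_solve(Ac, y, ridge = lam))
  }
  # seed = NULL continues the caller's RNG stream (used inside CV loops)
  draw_all <- function() {
    ws <- vapply(seq_len(n_balance), one_draw, numeric(ncol(A)))
    rowMeans(matrix(ws, nrow = ncol(A)))
  }
  acc <- if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
  # intercept set so the balanced class means are split at 0
  proj <- as.numeric(A %*% acc)
  intercept <- -(mean(proj[idx_f]) + mean(proj[idx_u])) / 2
  list(weights = acc, intercept = intercept)
}

balanced_accuracy <- function(pred_fam, familiar) {
  mean(c(mean(pred_fam[familiar]), mean(!pred_fam[!familiar])))
}

#' Time course of familiarity decoding
#'
#' Per rolling window, a ridge classifier is trained and tested with
#' leave-identities-out cross-validation (no face identity appears in both
#' train and test), class balance enforced by repeated majority-class
#' subsampling. Accuracy is balanced accuracy; the null band comes from
#' identity-level label permutations, and the latency is the trailing edge
#' of the first of two consecutive windows whose accuracy exceeds the
#' permutation-null 99th percentile.
#'
#' @param tensor A `response_tensor`.
#' @param familiar Logical over faces (or a `face_set`).
#' @param width_ms,step_ms Rolling window, ms.
#' @param n_folds Identity folds (default 4).
#' @param n_balance Majority-subsample repeats per fold (default 10).
#' @param n_perm Label permutations for the null (default 100).
#' @param null_quantile Null band quantile (default 0.99).
#' @param ridge_rel Relative ridge penalty.
#' @param seed Seed controlling folds, subsampling and permutations.
#' @return A `geometry_trace` of balanced accuracy with `null_level` and the
#'   detected latency.
#' @export
decode_familiarity <- function(tensor, familiar, width_ms = 50, step_ms = 10,
                               n_folds = 4, n_balance = 10, n_perm = 100,
                               null_quantile = 0.99, ridge_rel = 1,
                               seed = 1L) {
  stopifnot(inherits(tensor, "response_tensor"))
  familiar <- familiar_flags(tensor, familiar)
  if (sum(familiar) < 4 || sum(!familiar) < 4) {
    abort("need at least 4 familiar and 4 unfamiliar identities",
          class = "facegeom_insufficient_data")
  }
  win <- rolling_windows(tensor$t_start_ms, tensor$t_end_ms, width_ms, step_ms)
  folds <- withr::with_seed(child_seed(seed, 0L), make_identity_folds(familiar, n_folds))
  rows <- purrr::pmap(win, function(t0, t1, time_ms) {
    R <- window_response(tensor, t0, t1)
    A <- t(normalize_per_cell(R, "zscore"))
    A <- A[, colSums(is.na(A)) == 0, drop = FALSE]
    res <- withr::with_seed(child_seed(seed, time_ms), {
      acc <- cv_accuracy(A, familiar, folds, n_balance, ridge_rel)
      null_acc <- vapply(seq_len(n_perm), function(p) {
        mean(cv_accuracy(A, sample(familiar), folds, 1L, ridge_rel)$fold_acc)
      }, numeric(1))
      list(acc = acc, null = null_acc)
    })
    tibble(time_ms = time_ms,
           value = mean(res$acc$fold_acc),
           sem = sd(res$acc$fold_acc) / sqrt(length(res$acc$fold_acc)),
           null_level = quantile(res$null, null_quantile, names = FALSE))
  })
  df <- bind_rows(rows)
  lat <- detect_latency(df$time_ms,
                        ifelse(df$value > df$null_level, 0, 1), 0.5,
                        consecutive = 2L)
  geometry_trace(df, latency_ms = lat,
                 method_tag = "familiarity decoding accuracy",
                 alpha = 1 - null_quantile)
}

make_identity_folds <- function(familiar, n_folds) {
  fold <- integer(length(familiar))
  fold[familiar] <- sample(rep_len(seq_len(n_folds), sum(familiar)))
  fold[!familiar] <- sample(rep_len(seq_len(n_folds), sum(!familiar)))
  fold
}

cv_accuracy <- function(A, familiar, folds, n_balance, ridge_rel) {
  accs <- vapply(sort(unique(folds)), function(k) {
    tr <- which(folds != k); te <- which(folds == k)
    if (length(unique(familiar[tr])) < 2 || length(unique(familiar[te])) < 2) {
      return(NA_real_)                                 # degenerate fold skipped
    }
    w <- classifier_weights(A[tr, , drop = FALSE], familiar[tr], n_balance,
                            ridge_rel, seed = NULL)
    pred <- as.numeric(A[te, , drop = FALSE] %*% w$weights) + w$intercept > 0
    balanced_accuracy(pred, familiar[te])
  }, numeric(1))
  list(fold_acc = accs[!is.na(accs)])
}

#' Time course of centroid distance between face classes
#'
#' Euclidean distance between the familiar and unfamiliar response centroids
#' per rolling window, with a control curve from random matched-size
#' unfamiliar subsets versus the remaining unfamiliar faces (averaged over
#' draws). Also reports the noise-floor-debiased excess distance
#' `sqrt(max(d_fam^2 - d_control^2, 0))`, which recovers an injected shift
#' magnitude; note Euclidean distances grow with population size (~sqrt(n)
#' for i.i.d. cells).
#'
#' @param tensor A `response_tensor`.
#' @param familiar Logical over faces (or a `face_set`).
#' @param width_ms,step_ms Rolling window, ms.
#' @param normalize `"zscore"` (default; per-cell normalized population
#'   space) or `"none"` (raw Hz).
#' @param n_control Control subset draws (default 20).
#' @param seed Seed for the control draws.
#' @return A `geometry_trace` with `value` (familiar-unfamiliar distance),
#'   `null_level` (control distance) and `excess` columns.
#' @export
centroid_distance_trace <- function(tensor, familiar, width_ms = 50,
                                    step_ms = 10,
                                    normalize = c("zscore", "none"),
                                    n_control = 20, seed = 1L) {
  stopifnot(inherits(tensor, "response_tensor"))
  normalize <- arg_match(normalize)
  familiar <- familiar_flags(tensor, familiar)
  n_fam <- sum(familiar)
  idx_unf <- which(!familiar)
  win <- rolling_windows(tensor$t_start_ms, tensor$t_end_ms, width_ms, step_ms)
  rows <- purrr::pmap(win, function(t0, t1, time_ms) {
    R <- window_response(tensor, t0, t1)
    if (normalize == "zscore") {
      R <- normalize_per_cell(R, "zscore")
      R <- R[rowSums(is.na(R)) == 0, , drop = FALSE]
    }
    d_fam <- centroid_dist(R, which(familiar), idx_unf)
    d_ctl <- withr::with_seed(child_seed(seed, time_ms), {
      mean(vapply(seq_len(n_control), function(s) {
        sub <- sample(idx_unf, n_fam)
        centroid_dist(R, sub, setdiff(idx_unf, sub))
      }, numeric(1)))
    })
    tibble(time_ms = time_ms, value = d_fam, sem = NA_real_,
           null_level = d_ctl,
           excess = sqrt(max(d_fam^2 - d_ctl^2, 0)))
  })
  geometry_trace(bind_rows(rows), method_tag = "centroid distance")
}

centroid_dist <- function(R, idx_a, idx_b) {
  sqrt(sum((rowMeans(R[, idx_a, drop = FALSE]) -
              rowMeans(R[, idx_b, drop = FALSE]))^2))
}

#' d-prime along the centroid-difference axis
#'
#' The familiar-minus-unfamiliar centroid axis is estimated on a random
#' half of the faces of each class (training split); held-out per-face
#' responses are projected onto it and
#' `d' = |mu_F - mu_U| / sqrt((var_F + var_U) / 2)` is computed, avoiding
#' the selection bias of an uncrossed axis. The null distribution comes
#' from label shuffles.
#'
#' @param tensor A `response_tensor` (or cells x faces rate matrix).
#' @param familiar Logical over faces (or a `face_set`).
#' @param window Response window, ms.
#' @param n_shuffles Label shuffles (default 1000).
#' @param normalize `"zscore"` or `"none"`.
#' @param seed Seed for split and shuffles.
#' @return List with `dprime`, `null_quantiles` (90/95/99%), `p_value`, and
#'   `significant` at p < 0.01.
#' @export
dprime_along_centroid <- function(tensor, familiar, window = c(50, 300),
                                  n_shuffles = 1000,
                                  normalize = c("zscore", "none"),
                                  seed = 1L) {
  normalize <- arg_match(normalize)
  R <- rates_matrix(tensor, window)
  if (inherits(tensor, "response_tensor")) {
    familiar <- familiar_flags(tensor, familiar)
  } else if (is.data.frame(familiar)) familiar <- familiar$familiar
  if (normalize == "zscore") {
    R <- normalize_per_cell(R, "zscore")
    R <- R[rowSums(is.na(R)) == 0, , drop = FALSE]
  }
  if (length(unique(familiar)) < 2) {
    abort("d-prime undefined with a single class",
          class = "facegeom_invalid_argument")
  }
  withr::with_seed(seed, {
    obs <- dprime_crossval(R, familiar)
    null <- vapply(seq_len(n_shuffles), function(s) {
      dprime_crossval(R, sample(familiar))
    }, numeric(1))
  })
  p <- (sum(null >= obs) + 1) / (n_shuffles + 1)
  list(dprime = obs,
       null_quantiles = quantile(null, c(0.9, 0.95, 0.99)),
       p_value = p, significant = p < 0.01)
}

dprime_crossval <- function(R, familiar) {
  idx_f <- which(familiar); idx_u <- which(!familiar)
  # random half-split (caller controls the RNG stream)
  tr_f <- sample(idx_f, floor(length(idx_f) / 2))
  tr_u <- sample(idx_u, floor(length(idx_u) / 2))
  te_f <- setdiff(idx_f, tr_f); te_u <- setdiff(idx_u, tr_u)
  axis <- rowMeans(R[, tr_f, drop = FALSE]) - rowMeans(R[, tr_u, drop = FALSE])
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) return(0)
  axis <- axis / nrm
  pf <- as.numeric(crossprod(R[, te_f, drop = FALSE], axis))
  pu <- as.numeric(crossprod(R[, te_u, drop = FALSE], axis))
  abs(mean(pf) - mean(pu)) / sqrt((var(pf) + var(pu)) / 2)
}

#' Time-resolved d-prime significance
#'
#' Runs [dprime_along_centroid()] per rolling window and reports the
#' trailing edge of the first of two consecutive windows with shuffle
#' p < alpha.
#'
#' @inheritParams dprime_along_centroid
#' @param width_ms,step_ms Rolling window, ms.
#' @param alpha Significance level (default 0.01).
#' @return A `geometry_trace` of d-prime with `null_level` (99% null
#'   quantile) and the significance latency.
#' @export
dprime_trace <- function(tensor, familiar, width_ms = 50, step_ms = 10,
                         n_shuffles = 200, alpha = 0.01,
                         normalize = c("zscore", "none"), seed = 1L) {
  stopifnot(inherits(tensor, "response_tensor"))
  normalize <- arg_match(normalize)
  fam <- familiar_flags(tensor, familiar)
  win <- rolling_windows(tensor$t_start_ms, tensor$t_end_ms, width_ms, step_ms)
  rows <- purrr::pmap(win, function(t0, t1, time_ms) {
    res <- dprime_along_centroid(tensor, fam, window = c(t0, t1),
                                 n_shuffles = n_shuffles,
                                 normalize = normalize,
                                 seed = child_seed(seed, time_ms))
    tibble(time_ms = time_ms, value = res$dprime, sem = NA_real_,
           null_level = unname(res$null_quantiles[["99%"]]),
           p_value = res$p_value)
  })
  df <- bind_rows(rows)
  lat <- detect_latency(df$time_ms, df$p_value, alpha, consecutive = 2L)
  geometry_trace(df, latency_ms = lat, method_tag = "d-prime", alpha = alpha)
}

#' Per-cell familiar-minus-unfamiliar rate differences
#'
#' For each requested window, the per-cell difference between mean rates to
#' familiar and unfamiliar faces, with a per-cell two-tailed t-test across
#' faces and a population-level Wilcoxon signed-rank test.
#'
#' @param tensor A `response_tensor`.
#' @param familiar Logical over faces (or a `face_set`).
#' @param windows List of length-2 windows, ms.
#' @param alpha Per-cell significance level (default 0.01).
#' @return Tibble with one row per cell and window: `cell_id`, `window`,
#'   `diff_hz`, `p_value`, `significant`, plus attributes per window in
#'   `population_tests` (Wilcoxon p-values).
#' @export
rate_shift_distribution <- function(tensor, familiar, windows =
                                      list(c(50, 125), c(125, 200), c(200, 300)),
                                    alpha = 0.01) {
  stopifnot(inherits(tensor, "response_tensor"))
  familiar <- familiar_flags(tensor, familiar)
  out <- map(windows, function(w) {
    R <- window_response(tensor, w[1], w[2])
    fam <- R[, familiar, drop = FALSE]
    unf <- R[, !familiar, drop = FALSE]
    diffs <- rowMeans(fam) - rowMeans(unf)
    pv <- vapply(seq_len(nrow(R)), function(i) {
      if (sd(fam[i, ]) == 0 && sd(unf[i, ]) == 0) return(NA_real_)
      t.test(fam[i, ], unf[i, ])$p.value
    }, numeric(1))
    tibble(cell_id = tensor$cell_ids,
           window = sprintf("[%d,%d)", w[1], w[2]),
           diff_hz = diffs, p_value = pv,
           significant = !is.na(pv) & pv < alpha)
  })
  pop <- map_dbl(out, function(df) {
    suppressWarnings(wilcox.test(df$diff_hz)$p.value)
  })
  names(pop) <- vapply(out, function(df) df$window[1], character(1))
  structure(bind_rows(out), population_tests = pop,
            class = c("tbl_df", "tbl", "data.frame"))
}

#' Orthogonality of the familiarity axis to the feature axes
#'
#' Cosine similarity, in cell space, between the unit-normalized familiarity
#' classifier weights and each unit-normalized feature-decoder row. For an
#' orthogonal subspace shift the cosines concentrate near 0 (at the
#' estimation-noise level ~1/sqrt(n_cells)); a shift inside the feature
#' subspace produces at least one large cosine.
#'
#' @param classifier A `decoder_model` of kind `"familiarity_classifier"`.
#' @param feature_decoder A `decoder_model` of kind `"feature_regressor"`
#'   over the same cells.
#' @return Tibble with `feature`, `cosine`, `abs_cosine`.
#' @export
familiarity_axis_orthogonality <- function(classifier, feature_decoder) {
  stopifnot(inherits(classifier, "decoder_model"),
            classifier$kind == "familiarity_classifier",
            inherits(feature_decoder, "decoder_model"),
            feature_decoder$kind == "feature_regressor")
  w <- unitize(as.numeric(classifier$weights[1, ]))
  Wf <- feature_decoder$weights
  if (ncol(Wf) != length(w)) {
    abort("decoders were trained on different cell sets",
          class = "facegeom_invalid_argument")
  }
  cosines <- vapply(seq_len(nrow(Wf)), function(j) {
    cosine(w, as.numeric(Wf[j, ]))
  }, numeric(1))
  tibble(feature = paste0("f", seq_len(nrow(Wf))),
         cosine = cosines, abs_cosine = abs(cosines))
}

#' Two-condition (inactivation-style) contrast
#'
#' Per-cell normalized rate change `(B - A) / (B + A)` computed separately
#' for familiar and unfamiliar faces, a paired familiar-vs-unfamiliar
#' comparison of the changes, and side-by-side UU/UF axis summaries per
#' condition.
#'
#' @param tensorA,tensorB `response_tensor`s for the two conditions (same
#'   cells and faces).
#' @param faces Aligned `face_set`.
#' @param window Response window, ms.
#' @param ... Passed to [uu_uf_comparison()].
#' @return List with `per_cell` (tibble: `cell_id`, `class`, `change`),
#'   `paired_test` (familiar vs unfamiliar changes), and `axis_summaries`
#'   (glance of the per-condition UU/UF comparisons).
#' @export
condition_contrast <- function(tensorA, tensorB, faces, window = c(50, 300),
                               ...) {
  faces <- as_face_set(faces)
  fam <- familiar_flags(tensorA, faces)
  chg <- function(clazz) {
    a <- rowMeans(window_response(tensorA, window[1], window[2])[, clazz, drop = FALSE])
    b <- rowMeans(window_response(tensorB, window[1], window[2])[, clazz, drop = FALSE])
    (b - a) / (b + a)
  }
  ch_f <- chg(fam); ch_u <- chg(!fam)
  per_cell <- bind_rows(
    tibble(cell_id = tensorA$cell_ids, class = "familiar", change = ch_f),
    tibble(cell_id = tensorA$cell_ids, class = "unfamiliar", change = ch_u)
  )
  tt <- t.test(ch_f, ch_u, paired = TRUE)
  summaries <- bind_rows(
    mutate(glance(uu_uf_comparison(tensorA, faces, window = window, ...)),
           condition = "A"),
    mutate(glance(uu_uf_comparison(tensorB, faces, window = window, ...)),
           condition = "B")
  )
  list(per_cell = per_cell,
       paired_test = tibble(statistic = unname(tt$statistic),
                            p_value = tt$p.value,
                            mean_familiar = mean(ch_f),
                            mean_unfamiliar = mean(ch_u)),
       axis_summaries = summaries)
}
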