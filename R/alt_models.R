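# Restricted models for familiar-face responses, used to falsify simpler
# explanations of apparent axis change: a pure gain change, a sensitivity
# decrease in a subset of features, or a monotone output nonlinearity. Each
# keeps the unfamiliar reference axis and is scored by cross-validated
# variance explained on familiar faces, against a full axis refit.

model_design <- function(faces, ref) {
  F <- feature_matrix(as_face_set(faces), d_used = length(ref$unit))
  X <- standardize_features(F, ref$center, ref$scale)$X
  list(X = X, proj = as.numeric(X %*% ref$unit))
}

#' Gain model for familiar responses
#'
#' `r = alpha * (c . f) + beta`: the reference axis with a fitted gain and
#' offset (2 degrees of freedom).
#'
#' @param responses Per-face responses of one cell (familiar faces).
#' @param faces The familiar `face_set`.
#' @param ref Reference `axis_fit` (fit on unfamiliar faces).
#' @param n_folds,seed Cross-validation folds and seed.
#' @return List with `kind`, `cv_r2`, `cv_se`, `dof`, and the fitted
#'   parameters on the full data.
#' @export
fit_gain_model <- function(responses, faces, ref, n_folds = 5, seed = 1L) {
  des <- model_design(faces, ref)
  fit_fun <- function(x, y) {
    b <- stats::coef(stats::lm.fit(cbind(1, x), y))
    function(xnew) b[1] + b[2] * xnew
  }
  cv <- cv_score_1d(des$proj, responses, fit_fun, n_folds, seed)
  full <- stats::coef(stats::lm.fit(cbind(1, des$proj), responses))
  list(kind = "gain", cv_r2 = cv$r2, cv_se = cv$se, dof = 2,
       alpha = unname(full[2]), beta = unname(full[1]))
}

#' Monotone output-nonlinearity model
#'
#' `r = h(c . f)` with `h` monotone nondecreasing, fit by isotonic
#' regression (the weakest monotone assumption; such a transform preserves
#' the rank ordering of preferred stimuli).
#'
#' @inheritParams fit_gain_model
#' @export
fit_nonlinearity_model <- function(responses, faces, ref, n_folds = 5,
                                   seed = 1L) {
  des <- model_design(faces, ref)
  fit_fun <- function(x, y) {
    # isotonic fit in increasing-x order; piecewise-constant interpolation
    o <- order(x)
    iso <- isoreg(x[o], y[o])
    xs <- x[o]; ys <- iso$yf
    function(xnew) stats::approx(xs, ys, xout = xnew, rule = 2,
                                 ties = mean)$y
  }
  cv <- cv_score_1d(des$proj, responses, fit_fun, n_folds, seed)
  list(kind = "nonlinearity", cv_r2 = cv$r2, cv_se = cv$se,
       dof = length(responses) / 2)
}

#' Feature-subset sensitivity model
#'
#' `r = (c * m) . f + beta` with a per-feature sensitivity vector
#' `m` in [0, 1] (a sensitivity decrease in a subset of features),
#' sparsity-penalized (bounded nonnegative lasso on the design whose
#' j-th column is `c_j * f_j`).
#'
#' @inheritParams fit_gain_model
#' @export
fit_subset_model <- function(responses, faces, ref, n_folds = 5, seed = 1L) {
  des <- model_design(faces, ref)
  Z <- sweep(des$X, 2, ref$unit, "*")
  if (length(responses) < 4) {
    abort("too few familiar faces for the subset model",
          class = "facegeom_insufficient_data")
  }
  cvfit <- withr::with_seed(seed, glmnet::cv.glmnet(
    Z, responses, alpha = 1, lower.limits = 0, upper.limits = 1,
    nfolds = n_folds, standardize = FALSE))
  pred <- as.numeric(predict(cvfit, newx = Z, s = "lambda.min"))
  # honest CV score: refit per fold at lambda.min
  fit_fun <- function(idx_train) {
    f <- glmnet::glmnet(Z[idx_train, , drop = FALSE], responses[idx_train],
                        alpha = 1, lower.limits = 0, upper.limits = 1,
                        standardize = FALSE, lambda = cvfit$lambda.min)
    function(idx_test) as.numeric(predict(f, newx = Z[idx_test, , drop = FALSE]))
  }
  cv <- cv_score_idx(length(responses), responses, fit_fun, n_folds, seed)
  m <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
  list(kind = "subset", cv_r2 = cv$r2, cv_se = cv$se,
       dof = sum(m > 1e-8) + 1, m = m)
}

#' Full axis refit model
#'
#' Ridge refit of the whole axis on familiar faces (the model implied by
#' genuine axis change).
#'
#' @inheritParams fit_gain_model
#' @param ridge Relative ridge penalty.
#' @export
fit_refit_model <- function(responses, faces, ref, n_folds = 5, seed = 1L,
                            ridge = 1e-3) {
  des <- model_design(faces, ref)
  X <- des$X
  fit_fun <- function(idx_train) {
    Xi <- X[idx_train, , drop = FALSE]
    yi <- responses[idx_train]
    lam <- scaled_ridge(Xi, ridge)
    b <- ridge_solve(Xi, yi - mean(yi), ridge = lam)
    mu <- mean(yi)
    function(idx_test) as.numeric(X[idx_test, , drop = FALSE] %*% b) + mu
  }
  cv <- cv_score_idx(length(responses), responses, fit_fun, n_folds, seed)
  list(kind = "refit", cv_r2 = cv$r2, cv_se = cv$se, dof = ncol(X) + 1)
}

# K-fold CV variance explained for models of a scalar predictor
cv_score_1d <- function(x, y, fit_fun, n_folds, seed) {
  fit_wrap <- function(idx_train) {
    f <- fit_fun(x[idx_train], y[idx_train])
    function(idx_test) f(x[idx_test])
  }
  cv_score_idx(length(y), y, fit_wrap, n_folds, seed)
}

cv_score_idx <- function(n, y, fit_fun, n_folds, seed) {
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  r2 <- vapply(seq_len(n_folds), function(k) {
    te <- which(folds == k); tr <- which(folds != k)
    pred <- fit_fun(tr)(te)
    1 - mean((y[te] - pred)^2) / var(y)
  }, numeric(1))
  list(r2 = mean(r2), se = sd(r2) / sqrt(n_folds))
}

#' Compare restricted models against a full axis refit for one cell
#'
#' Fits the gain, nonlinearity and subset models plus the full refit, and
#' selects a family by the one-standard-error rule on cross-validated
#' variance explained: the least complex model whose CV score is within one
#' standard error of the best score. Complexity order: gain < nonlinearity <
#' subset < refit.
#'
#' @inheritParams fit_gain_model
#' @return Tibble with one row per model (`model`, `cv_r2`, `cv_se`,
#'   `selected`).
#' @export
compare_axis_models <- function(responses, faces, ref, n_folds = 5, seed = 1L) {
  if (length(responses) < 6) {
    abort("too few familiar faces to compare models",
          class = "facegeom_insufficient_data")
  }
  fits <- list(
    gain = fit_gain_model(responses, faces, ref, n_folds, seed),
    nonlinearity = fit_nonlinearity_model(responses, faces, ref, n_folds, seed),
    subset = fit_subset_model(responses, faces, ref, n_folds, seed),
    refit = fit_refit_model(responses, faces, ref, n_folds, seed)
  )
  tb <- tibble(
    model = names(fits),
    cv_r2 = map_dbl(fits, "cv_r2"),
    cv_se = map_dbl(fits, "cv_se")
  )
  best <- which.max(tb$cv_r2)
  threshold <- tb$cv_r2[best] - tb$cv_se[best]
  tb$selected <- FALSE
  tb$selected[which(tb$cv_r2 >= threshold)[1]] <- TRUE   # rows are in complexity order
  tb
}

#' Population-level model comparison
#'
#' Runs [compare_axis_models()] for every cell and tallies which family is
#' selected.
#'
#' @param tensor A `response_tensor` (or cells x faces rate matrix).
#' @param faces Aligned `face_set`; axes are referenced on unfamiliar faces
#'   and models are scored on familiar faces.
#' @param window Response window, ms.
#' @param d_used,ridge Reference-axis fit parameters.
#' @param n_folds,seed Cross-validation controls.
#' @return List with `per_cell` (tibble: cell, model scores, selected) and
#'   `counts` (selected-family tally).
#' @export
model_comparison <- function(tensor, faces, window = c(50, 300), d_used = 20,
                             ridge = 1e-6, n_folds = 5, seed = 1L) {
  R <- if (inherits(tensor, "response_tensor")) {
    window_response(tensor, window[1], window[2])
  } else tensor
  faces <- as_face_set(faces)
  fam <- faces$familiar
  ref_set <- fit_axes(R, faces, window = window, d_used = d_used,
                      ridge = ridge, subset = !fam)
  fam_faces <- faces[fam, ]
  per_cell <- imap(seq_len(nrow(R)), function(i, nm) {
    ref <- list(unit = ref_set$unit[, i], coef = ref_set$coef[, i],
                center = ref_set$center, scale = ref_set$scale)
    cmp <- compare_axis_models(R[i, fam], fam_faces, ref,
                               n_folds = n_folds, seed = child_seed(seed, i))
    cmp$cell_id <- rownames(R)[i] %||% sprintf("cell_%03d", i)
    cmp
  })
  per_cell <- bind_rows(per_cell)
  counts <- per_cell |>
    filter(.data$selected) |>
    dplyr::count(.data$model, name = "n_cells")
  list(per_cell = per_cell, counts = counts)
}
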