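# Core estimator: per-cell preferred axes of the linear encoding model
# r = c . f + c0, fit by (optionally ridge-regularized) least squares on
# trial-averaged window rates. Features are column-standardized on the
# fitting set only; the standardization is stored and re-applied to
# evaluation sets (no leakage).

standardize_features <- function(F, center = NULL, scale = NULL) {
  center <- center %||% colMeans(F)
  scale <- scale %||% apply(F, 2, sd)
  scale[scale == 0] <- 1
  X <- sweep(sweep(F, 2, center, "-"), 2, scale, "/")
  list(X = X, center = center, scale = scale)
}

# batched fit: R is a faces x cells response matrix, F faces x d features.
# Returns an axis_fit_set.
fit_axes_matrix <- function(R, F, ridge = 1e-6, cell_ids = NULL,
                            window = c(NA, NA)) {
  stopifnot(is.matrix(R), is.matrix(F), nrow(R) == nrow(F))
  if (nrow(F) < ncol(F) + 2) {
    abort(sprintf("need at least d + 2 = %d faces to fit axes, got %d",
                  ncol(F) + 2, nrow(F)),
          class = "facegeom_insufficient_data")
  }
  std <- standardize_features(F)
  X <- std$X
  Yc <- sweep(R, 2, colMeans(R), "-")
  lam <- scaled_ridge(X, ridge)
  C <- ridge_solve(X, Yc, ridge = lam)                   # d x cells
  pred <- X %*% C
  ss_res <- colSums((Yc - pred)^2)
  ss_tot <- colSums(Yc^2)
  r2 <- ifelse(ss_tot > 0, pmax(0, 1 - ss_res / ss_tot), NA_real_)
  norms <- sqrt(colSums(C^2))
  unit <- sweep(C, 2, ifelse(norms > 0, norms, 1), "/")
  structure(
    list(coef = C, unit = unit, c0 = colMeans(R), r_squared = r2,
         cell_ids = cell_ids %||% colnames(R) %||%
           sprintf("cell_%03d", seq_len(ncol(R))),
         n_faces_fit = nrow(F), ridge = ridge, lambda = lam,
         center = std$center, scale = std$scale, window = window),
    class = "axis_fit_set"
  )
}

#' @export
print.axis_fit_set <- function(x, ...) {
  cat(sprintf("<axis_fit_set> %d cells, %d features, %d faces, median R^2 = %.3f\n",
              ncol(x$coef), nrow(x$coef), x$n_faces_fit,
              median(x$r_squared, na.rm = TRUE)))
  invisible(x)
}

#' Fit preferred axes for every cell
#'
#' Estimates each cell's preferred axis `c` and offset `c0` of the linear
#' encoding model `r = c . f + c0` from trial-averaged rates in a response
#' window, using the first `d_used` features (the top shape/appearance
#' coordinates).
#'
#' @param tensor A `response_tensor` (or a cells x faces rate matrix).
#' @param faces A `face_set` aligned with the tensor's faces.
#' @param window Length-2 response window in ms, default the full 50-300 ms
#'   response window.
#' @param d_used Number of leading features to fit (default 20).
#' @param ridge Relative ridge penalty (`lambda * trace(X'X)/d` added to the
#'   normal equations); `0` gives ordinary least squares and errors on
#'   rank-deficient designs.
#' @param subset Optional face indices (or logical) restricting the fitting
#'   set.
#' @return An `axis_fit_set`: raw and unit-normalized coefficient matrices
#'   (`d_used` x cells), offsets, per-cell R^2, and the feature
#'   standardization of the fitting set.
#' @export
fit_axes <- function(tensor, faces, window = c(50, 300), d_used = 20,
                     ridge = 1e-6, subset = NULL) {
  R <- if (inherits(tensor, "response_tensor")) {
    window_response(tensor, window[1], window[2])
  } else {
    stopifnot(is.matrix(tensor))
    tensor
  }
  faces <- as_face_set(faces)
  F <- feature_matrix(faces, d_used = min(d_used, length(feature_cols(faces))))
  if (!is.null(subset)) {
    R <- R[, subset, drop = FALSE]
    F <- F[subset, , drop = FALSE]
  }
  fit_axes_matrix(t(R), F, ridge = ridge,
                  cell_ids = rownames(R), window = window)
}

#' Fit a single cell's preferred axis
#'
#' @param responses Per-face mean rates (Hz) for one cell.
#' @param faces A `face_set` with matching rows.
#' @param ridge Relative ridge penalty; `0` for OLS.
#' @param d_used Number of leading features.
#' @return An `axis_fit` list: `coef`, `unit`, `c0`, `r_squared`,
#'   `n_faces_fit`, and the standardization used.
#' @export
fit_axis <- function(responses, faces, ridge = 1e-6, d_used = 20) {
  faces <- as_face_set(faces)
  stopifnot(length(responses) == nrow(faces))
  fs <- fit_axes_matrix(
    matrix(responses, ncol = 1),
    feature_matrix(faces, d_used = min(d_used, length(feature_cols(faces)))),
    ridge = ridge, cell_ids = "cell"
  )
  structure(
    list(coef = fs$coef[, 1], unit = fs$unit[, 1], c0 = fs$c0[1],
         r_squared = fs$r_squared[1], n_faces_fit = fs$n_faces_fit,
         center = fs$center, scale = fs$scale, ridge = ridge),
    class = "axis_fit"
  )
}

#' @exportS3Method generics::tidy
tidy.axis_fit_set <- function(x, ...) {
  tibble(
    cell_id = x$cell_ids,
    c0 = x$c0,
    r_squared = x$r_squared,
    n_faces_fit = x$n_faces_fit,
    coef = lapply(seq_len(ncol(x$coef)), function(i) x$coef[, i]),
    unit = lapply(seq_len(ncol(x$unit)), function(i) x$unit[, i])
  )
}

#' @exportS3Method generics::glance
glance.axis_fit_set <- function(x, ...) {
  tibble(
    n_cells = ncol(x$coef), d = nrow(x$coef), n_faces_fit = x$n_faces_fit,
    median_r_squared = median(x$r_squared, na.rm = TRUE),
    ridge = x$ridge
  )
}

#' Split-half consistency of preferred axes
#'
#' Trials are split at random into two halves; axes are fit on each half and
#' the per-cell cosine similarity between half-axes summarizes tuning
#' reliability (the split-half noise ceiling).
#'
#' @param tensor A `response_tensor` with at least 2 trials per face.
#' @param faces Aligned `face_set`.
#' @param n_splits Number of random splits to average.
#' @param seed Seed for the splits.
#' @inheritParams fit_axes
#' @return Tibble with one row per cell: `cell_id`, `mean_cosine`,
#'   `ci_lo`/`ci_hi` (2.5/97.5% quantiles over splits).
#' @export
split_half_axis_consistency <- function(tensor, faces, n_splits = 10, seed = 1L,
                                        window = c(50, 300), d_used = 20,
                                        ridge = 1e-6) {
  stopifnot(inherits(tensor, "response_tensor"))
  nt <- dim(tensor$counts)[3]
  if (nt < 2) {
    abort("split-half consistency needs at least 2 trials per face",
          class = "facegeom_insufficient_data")
  }
  faces <- as_face_set(faces)
  cos_mat <- withr::with_seed(seed, {
    vapply(seq_len(n_splits), function(s) {
      half <- sample(nt, floor(nt / 2))
      fit1 <- fit_axes(subset_trials(tensor, half), faces,
                       window = window, d_used = d_used, ridge = ridge)
      fit2 <- fit_axes(subset_trials(tensor, setdiff(seq_len(nt), half)), faces,
                       window = window, d_used = d_used, ridge = ridge)
      col_cosines(fit1$unit, fit2$unit)
    }, numeric(length(tensor$cell_ids)))
  })
  cos_mat <- matrix(cos_mat, nrow = length(tensor$cell_ids))
  tibble(
    cell_id = tensor$cell_ids,
    mean_cosine = rowMeans(cos_mat),
    ci_lo = apply(cos_mat, 1, quantile, 0.025),
    ci_hi = apply(cos_mat, 1, quantile, 0.975)
  )
}

subset_trials <- function(tensor, trials) {
  response_tensor(tensor$counts[, , trials, , drop = FALSE],
                  tensor$bin_ms, tensor$t_start_ms, tensor$t_end_ms,
                  cell_ids = tensor$cell_ids, face_ids = tensor$face_ids,
                  mask = tensor$mask[, trials, drop = FALSE],
                  region_tag = tensor$region_tag,
                  normalized = tensor$normalized)
}

#' Ramp tuning curve along the preferred axis
#'
#' Projects faces onto a fitted axis, bins the projections, and reports the
#' mean response per bin, plus each face's coordinate on the principal
#' (longest) orthogonal axis — the first principal direction of the features
#' after removing the component along `c`.
#'
#' @param fit An `axis_fit` or single-cell column of an `axis_fit_set`
#'   (anything with `unit`, `center`, `scale`).
#' @param faces A `face_set`.
#' @param responses Per-face responses for the cell.
#' @param n_points Number of projection bins (>= 2).
#' @return List with `points` (tibble: `face_id`, `projection`,
#'   `orthogonal`, `response`) and `curve` (tibble: `bin_center`,
#'   `mean_response`, `sem`, `n`).
#' @export
tuning_curve <- function(fit, faces, responses, n_points = 10) {
  if (n_points < 2) {
    abort("`n_points` must be at least 2", class = "facegeom_invalid_argument")
  }
  faces <- as_face_set(faces)
  d <- length(fit$unit)
  F <- feature_matrix(faces, d_used = d)
  X <- standardize_features(F, fit$center, fit$scale)$X
  proj <- as.numeric(X %*% fit$unit)
  resid <- X - outer(proj, fit$unit)
  pc1 <- svd(resid, nu = 0, nv = 1)$v[, 1]
  orth <- as.numeric(resid %*% pc1)
  pts <- tibble(face_id = faces$face_id, projection = proj,
                orthogonal = orth, response = responses)
  brks <- seq(min(proj), max(proj), length.out = n_points + 1)
  bin <- cut(proj, brks, include.lowest = TRUE)
  curve <- pts |>
    mutate(bin = bin) |>
    group_by(.data$bin) |>
    summarise(mean_response = mean(.data$response),
              sem = sd(.data$response) / sqrt(dplyr::n()),
              n = dplyr::n(), .groups = "drop") |>
    mutate(bin_center = (brks[-length(brks)] + brks[-1])[as.integer(.data$bin)]) |>
    select("bin_center", "mean_response", "sem", "n")
  list(points = pts, curve = curve)
}
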