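#' Build a synthetic axis-coding population
#'
#' Realizes a population of linear axis-coding cells: each cell `i` responds
#' to a face with features `f` at rate `c0_i + g_i * (c_i . f)` (Hz), where
#' `c_i` is a unit preferred axis drawn uniformly on the sphere in `d_used`
#' dimensions. Familiarity effects are built in but only expressed by the
#' simulator when their onsets/magnitudes say so:
#'
#' * a rotated axis `c_i'`, obtained by rotating `c_i` by
#'   `rotation_angle_deg` in the 2-plane spanned by `c_i` and a per-cell
#'   random direction orthogonal to `c_i`;
#' * a population shift vector `s` (one loading per cell) orthogonalized
#'   against the feature-encoding subspace (the column space of the
#'   cells-by-features coefficient matrix) and rescaled to norm
#'   `shift_magnitude`. The loadings are in units of the population signal
#'   (the norm of the per-cell signal-s.d. vector,
#'   `sigma_pop = gain_hz * sqrt(sum(g_rel^2))`); the simulator multiplies by
#'   `sigma_pop` to convert to Hz, so per-cell shift loadings are comparable
#'   to per-cell tuning range.
#'
#' @param config A [sim_config()].
#' @param shift_mode `"orthogonal"` (default) removes the projection of the
#'   shift onto the feature-encoding subspace; `"in_subspace"` instead places
#'   the shift along the encoding direction of the first feature (a negative
#'   control for orthogonality analyses).
#' @return A `population_model`: list with unit axis matrices `axes` and
#'   `axes_rotated` (d_used x n_cells), offsets `c0` (Hz), relative gains
#'   `g_rel`, the Hz-per-feature-s.d. scale `gain_hz`, `sigma_signal`, and the
#'   shift loadings `shift`.
#' @export
make_population <- function(config, shift_mode = c("orthogonal", "in_subspace")) {
  stopifnot(inherits(config, "sim_config"))
  shift_mode <- arg_match(shift_mode)
  d <- config$d_used
  nc <- config$n_cells
  withr::with_seed(child_seed(config$seed, 1L), {
    # axes uniform on the unit sphere
    A <- matrix(rnorm(d * nc), nrow = d)
    A <- sweep(A, 2, sqrt(colSums(A^2)), "/")

    # rotate each axis toward a random orthogonal direction
    theta <- config$rotation_angle_deg * pi / 180
    U <- matrix(rnorm(d * nc), nrow = d)
    U <- U - sweep(A, 2, colSums(U * A), "*")      # remove component along axis
    U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
    Arot <- cos(theta) * A + sin(theta) * U

    g_rel <- runif(nc, 0.8, 1.2)
    gain_hz <- (config$peak_hz - config$baseline_hz) / 3
    sigma_signal <- gain_hz * sqrt(mean(g_rel^2))      # per-cell signal s.d., Hz
    sigma_pop <- gain_hz * sqrt(sum(g_rel^2))          # norm of the signal-s.d. vector
    c0 <- rep(config$peak_hz, nc)

    shift <- rep(0, nc)
    if (config$shift_magnitude > 0) {
      enc <- t(A)                                  # n_cells x d_used columns span
      if (shift_mode == "in_subspace") {
        # negative control: along the response-space encoding direction of
        # feature 1 (gain-weighted), squarely inside the feature subspace
        shift <- unitize(g_rel * enc[, 1]) * config$shift_magnitude
      } else if (nc <= d) {
        warn(paste("feature-encoding subspace spans the whole population space;",
                   "shift magnitude reduced to 0"))
      } else {
        s0 <- rnorm(nc)
        # remove projections onto both the raw and the gain-weighted
        # encoding columns: decoders read the population through
        # diag(g) %*% C, so zero leakage needs orthogonality to both spans
        q <- qr.Q(qr(cbind(enc, g_rel * enc)))
        s0 <- s0 - q %*% crossprod(q, s0)
        if (sqrt(sum(s0^2)) < 1e-8) {
          warn(paste("feature-encoding subspace spans the whole population",
                     "space; shift magnitude reduced to 0"))
        } else {
          shift <- as.numeric(unitize(s0)) * config$shift_magnitude
        }
      }
    }
  })
  structure(
    list(
      axes = A, axes_rotated = Arot, c0 = c0, g_rel = g_rel,
      gain_hz = gain_hz, sigma_signal = sigma_signal, sigma_pop = sigma_pop,
      shift = shift,
      cell_ids = sprintf("cell_%03d", seq_len(nc)),
      config = config, shift_mode = shift_mode
    ),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "<population_model> %d cells, %d-d axes, rotation %.1f deg, |shift| = %.3g (%s)\n",
    length(x$c0), nrow(x$axes), x$config$rotation_angle_deg,
    sqrt(sum(x$shift^2)), x$shift_mode
  ))
  invisible(x)
}

#' Tidy a population model into one row per cell
#'
#' @param x A `population_model`.
#' @param ... Unused.
#' @return Tibble with `cell_id`, `c0_hz`, `g_rel`, `shift_loading`, the
#'   axis-rotation cosine, and list-columns `axis`, `axis_rotated`.
#' @exportS3Method generics::tidy
tidy.population_model <- function(x, ...) {
  tibble(
    cell_id = x$cell_ids,
    c0_hz = x$c0,
    g_rel = x$g_rel,
    shift_loading = x$shift,
    rotation_cos = col_cosines(x$axes, x$axes_rotated),
    axis = lapply(seq_along(x$c0), function(i) x$axes[, i]),
    axis_rotated = lapply(seq_along(x$c0), function(i) x$axes_rotated[, i])
  )
}
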