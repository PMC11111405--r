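# Expected rate matrices (cells x faces, Hz) per temporal regime.
# A regime is (visual, shift_active, rotation_active). face_gain multiplies
# the evoked component per face (context/expectation effects).
regime_rates <- function(pop, F, familiar, config,
                         visual, shift_active, rotation_active,
                         face_gain = NULL) {
  nc <- length(pop$c0); nf <- nrow(F)
  if (!visual) {
    return(matrix(config$baseline_hz, nc, nf))
  }
  face_gain <- face_gain %||% rep(1, nf)
  drive_u <- crossprod(pop$axes, t(F))                 # d x nc -> nc x nf
  gains <- pop$g_rel * pop$gain_hz
  evoked <- pop$c0 + gains * drive_u                   # column-recycled by cell
  if (any(familiar)) {
    if (rotation_active) {
      drive_f <- crossprod(pop$axes_rotated, t(F[familiar, , drop = FALSE]))
      if (config$familiar_transform == "saturating") {
        L <- config$saturation_level
        drive_f <- L * tanh(drive_f / L)
      }
      evoked_f <- config$familiar_gain * (pop$c0 + gains * drive_f)
      evoked[, familiar] <- evoked_f
    }
    if (shift_active) {
      evoked[, familiar] <- evoked[, familiar, drop = FALSE] +
        pop$shift * pop$sigma_pop
    }
  }
  rate <- config$baseline_hz + sweep(evoked - config$baseline_hz, 2, face_gain, "*")
  pmax(rate, 0)                                        # rectify: rates are nonnegative
}

draw_counts <- function(rate_hz, n_draws_per_entry, config, n_bins_regime) {
  lambda <- rate_hz * config$bin_ms / 1000
  lam <- rep(as.numeric(lambda), times = n_draws_per_entry * n_bins_regime)
  n <- length(lam)
  if (config$noise_model == "poisson") {
    rpois(n, lam)
  } else {
    sdv <- if (is.null(config$noise_sd)) sqrt(lam) else rep(config$noise_sd, n)
    lam + rnorm(n, 0, sdv)
  }
}

#' Simulate binned population responses
#'
#' Generates spike counts for every cell, face, trial and time bin. Expected
#' rates follow the axis code `r = c0 + g * (c . f)` with sharp temporal
#' epochs: baseline before `visual_onset_ms`; from `shift_onset_ms` familiar
#' faces gain the orthogonal population shift; from `rotation_onset_ms`
#' familiar faces are driven through the rotated axes with `familiar_gain`
#' applied to their evoked response. Rates are rectified at 0 before the
#' Poisson draw; counts per bin are Poisson(rate * bin / 1000) (or Gaussian
#' with matched variance when configured). Deterministic for a given config
#' seed.
#'
#' @param pop A [make_population()] model.
#' @param faces A `face_set`; its first `d_used` feature columns drive
#'   responses (extra columns are ignored).
#' @param config A [sim_config()].
#' @param face_gain Optional per-face multiplicative gain on the evoked
#'   component (used by [make_context_experiment()]).
#' @param seed Seed for the noise draw; defaults to a stream derived from
#'   `config$seed`.
#' @return A `response_tensor` (cells x faces x trials x bins).
#' @export
simulate_responses <- function(pop, faces, config, face_gain = NULL, seed = NULL) {
  stopifnot(inherits(pop, "population_model"), inherits(config, "sim_config"))
  faces <- as_face_set(faces)
  d <- nrow(pop$axes)
  if (length(feature_cols(faces)) < d) {
    abort(sprintf("faces have %d features but the population uses %d",
                  length(feature_cols(faces)), d),
          class = "facegeom_invalid_argument")
  }
  F <- feature_matrix(faces, d_used = d)
  familiar <- faces$familiar
  nc <- length(pop$c0); nf <- nrow(F)
  nt <- config$n_trials; nb <- n_bins(config)
  starts <- bin_starts(config)

  regime_of <- cbind(
    visual = starts >= config$visual_onset_ms,
    shift = starts >= config$shift_onset_ms & config$shift_magnitude > 0,
    rot = starts >= config$rotation_onset_ms
  )
  regime_key <- apply(regime_of, 1, paste, collapse = "")

  counts <- array(NA_real_, dim = c(nc, nf, nt, nb))
  withr::with_seed(seed %||% child_seed(config$seed, 2L), {
    for (key in unique(regime_key)) {
      bins_k <- which(regime_key == key)
      r <- regime_of[bins_k[1], ]
      rate <- regime_rates(pop, F, familiar, config,
                           visual = r[["visual"]], shift_active = r[["shift"]],
                           rotation_active = r[["rot"]], face_gain = face_gain)
      x <- draw_counts(rate, nt, config, length(bins_k))
      counts[, , , bins_k] <- x
    }
  })
  if (config$noise_model == "poisson") storage.mode(counts) <- "integer"
  response_tensor(counts, config$bin_ms, config$t_start_ms, config$t_end_ms,
                  cell_ids = pop$cell_ids, face_ids = faces$face_id,
                  region_tag = "sim")
}

#' Simulate a temporal-context experiment
#'
#' Builds a stimulus set with the stated familiar:unfamiliar composition and
#' applies `context_gain_rare` multiplicatively to the evoked response of the
#' minority familiarity class, emulating expectation-dependent response
#' magnitudes (unexpected stimuli respond more strongly). With `ratio =
#' c(1, 1)` and `context_gain_rare = 1` the statistics equal
#' [simulate_responses()].
#'
#' @param pop A `population_model`.
#' @param faces_fam,faces_unfam Familiar and unfamiliar `face_set`s to draw
#'   the composition from (the first `ratio[1]` / `ratio[2]` faces are used;
#'   components are capped at the available counts).
#' @param ratio Integer pair, familiar:unfamiliar face counts (both >= 1).
#' @param config A [sim_config()].
#' @param seed Optional seed for the noise draw.
#' @return List with elements `tensor` (a `response_tensor`) and `faces`
#'   (the combined `face_set` actually presented).
#' @export
make_context_experiment <- function(pop, faces_fam, faces_unfam, ratio, config,
                                    seed = NULL) {
  if (length(ratio) != 2 || any(ratio < 1)) {
    abort("`ratio` must be two integers >= 1", class = "facegeom_invalid_argument")
  }
  faces_fam <- as_face_set(faces_fam)
  faces_unfam <- as_face_set(faces_unfam)
  n_f <- min(ratio[1], nrow(faces_fam))
  n_u <- min(ratio[2], nrow(faces_unfam))
  fam <- dplyr::slice_head(faces_fam, n = n_f)
  unf <- dplyr::slice_head(faces_unfam, n = n_u)
  fam$familiar <- TRUE
  unf$familiar <- FALSE
  faces <- as_face_set(bind_rows(fam, unf))
  face_gain <- rep(1, nrow(faces))
  if (n_f != n_u) {
    minority_familiar <- n_f < n_u
    face_gain[faces$familiar == minority_familiar] <- config$context_gain_rare
  }
  tensor <- simulate_responses(pop, faces, config, face_gain = face_gain,
                               seed = seed)
  list(tensor = tensor, faces = faces)
}

#' One-call synthetic experiment
#'
#' Convenience wrapper: samples the face space (1,000 unfamiliar + 36
#' familiar by default), builds the population, simulates responses.
#'
#' @param config A [sim_config()].
#' @param shift_mode Passed to [make_population()].
#' @return List with `faces`, `pop`, `tensor`.
#' @export
simulate_experiment <- function(config = sim_config(), shift_mode = "orthogonal") {
  unfam <- sample_face_space(config$n_unfamiliar, config$d_total,
                             seed = child_seed(config$seed, 3L),
                             familiar = FALSE, subset_tag = "pool1000",
                             prefix = "unfam")
  fam <- sample_face_space(config$n_familiar, config$d_total,
                           seed = child_seed(config$seed, 4L),
                           familiar = TRUE, subset_tag = "fam36",
                           prefix = "fam")
  faces <- as_face_set(bind_rows(unfam, fam))
  pop <- make_population(config, shift_mode = shift_mode)
  tensor <- simulate_responses(pop, faces, config)
  list(faces = faces, pop = pop, tensor = tensor)
}
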