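#' Simulation configuration
#'
#' Full generative specification of a synthetic face-patch experiment.
#' Defaults describe the study conditions emulated throughout the package:
#' a 120-dimensional face space of which the first 20 coordinates (top ten
#' shape + top ten appearance features) drive responses, 1,000 unfamiliar and
#' 36 familiar faces, 10-ms bins over \[-50, 300) ms around stimulus onset,
#' a visual response from 90 ms, an orthogonal familiar-subspace shift from
#' 100 ms, a 60-degree axis rotation for familiar faces from 200 ms with mild
#' response suppression, and expectation-dependent gain for the rarer
#' familiarity class.
#'
#' @param n_cells Number of cells.
#' @param d_total Face-space dimensionality (features stored per face).
#' @param d_used Number of leading features that drive responses (`<= d_total`).
#' @param n_unfamiliar,n_familiar Face counts (`n_familiar <= n_unfamiliar`).
#' @param bin_ms Bin width in ms.
#' @param t_start_ms,t_end_ms Span of the peristimulus window, ms relative to
#'   stimulus onset; `bin_ms` must divide the span.
#' @param visual_onset_ms Latency of the visual response.
#' @param shift_onset_ms Onset of the familiar-subspace shift
#'   (`>= visual_onset_ms`).
#' @param shift_magnitude Norm of the population shift vector, in units of the
#'   population signal s.d. (see [make_population()]).
#' @param rotation_onset_ms Onset of the familiar-axis rotation
#'   (`>= visual_onset_ms`).
#' @param rotation_angle_deg Per-cell rotation angle, degrees in \[0, 90\].
#' @param familiar_gain Multiplicative gain on the evoked response to familiar
#'   faces at long latency (values < 1 model familiarity suppression).
#' @param context_gain_rare Gain applied to the rarer familiarity class in a
#'   context experiment (models stronger responses to unexpected stimuli).
#' @param baseline_hz,peak_hz Baseline and mean evoked firing rate, Hz. The
#'   per-cell signal scale is `(peak_hz - baseline_hz) / 3` Hz per feature s.d.
#' @param familiar_transform `"none"`, or `"saturating"` for a monotone
#'   saturating output nonlinearity applied to the familiar axis drive at long
#'   latency (a control generator that preserves rank order).
#' @param saturation_level Saturation level of the `"saturating"` transform,
#'   in feature-s.d. units of axis drive.
#' @param noise_model `"poisson"` (counts) or `"gaussian"` (variance-matched
#'   to Poisson unless `noise_sd` is given).
#' @param noise_sd For `noise_model = "gaussian"`: s.d. of the additive count
#'   noise per bin; `NULL` matches the Poisson variance; `0` gives noiseless
#'   expected counts.
#' @param n_trials Trials per face.
#' @param seed Integer master seed; all generator randomness derives from it.
#'
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(n_cells = 150L,
                       d_total = 120L,
                       d_used = 20L,
                       n_unfamiliar = 1000L,
                       n_familiar = 36L,
                       bin_ms = 10L,
                       t_start_ms = -50L,
                       t_end_ms = 300L,
                       visual_onset_ms = 90L,
                       shift_onset_ms = 100L,
                       shift_magnitude = 2,
                       rotation_onset_ms = 200L,
                       rotation_angle_deg = 60,
                       familiar_gain = 0.8,
                       context_gain_rare = 1.3,
                       baseline_hz = 10,
                       peak_hz = 50,
                       familiar_transform = "none",
                       saturation_level = 1,
                       noise_model = "poisson",
                       noise_sd = NULL,
                       n_trials = 6L,
                       seed = 1L) {
  cfg <- list(
    n_cells = check_count(n_cells, "n_cells"),
    d_total = check_count(d_total, "d_total", min = 2L),
    d_used = check_count(d_used, "d_used", min = 1L),
    n_unfamiliar = check_count(n_unfamiliar, "n_unfamiliar"),
    n_familiar = check_count(n_familiar, "n_familiar"),
    bin_ms = check_count(bin_ms, "bin_ms"),
    t_start_ms = check_count(t_start_ms, "t_start_ms", min = -1e6),
    t_end_ms = check_count(t_end_ms, "t_end_ms", min = -1e6),
    visual_onset_ms = check_count(visual_onset_ms, "visual_onset_ms", min = -1e6),
    shift_onset_ms = check_count(shift_onset_ms, "shift_onset_ms", min = -1e6),
    shift_magnitude = check_number(shift_magnitude, "shift_magnitude", min = 0),
    rotation_onset_ms = check_count(rotation_onset_ms, "rotation_onset_ms", min = -1e6),
    rotation_angle_deg = check_number(rotation_angle_deg, "rotation_angle_deg",
                                      min = 0, max = 90),
    familiar_gain = check_number(familiar_gain, "familiar_gain", min = 1e-12),
    context_gain_rare = check_number(context_gain_rare, "context_gain_rare",
                                     min = 1e-12),
    baseline_hz = check_number(baseline_hz, "baseline_hz", min = 1e-12),
    peak_hz = check_number(peak_hz, "peak_hz", min = 1e-12),
    familiar_transform = arg_match(familiar_transform, c("none", "saturating")),
    saturation_level = check_number(saturation_level, "saturation_level", min = 1e-12),
    noise_model = arg_match(noise_model, c("poisson", "gaussian")),
    noise_sd = if (is.null(noise_sd)) NULL else check_number(noise_sd, "noise_sd", min = 0),
    n_trials = check_count(n_trials, "n_trials"),
    seed = check_count(seed, "seed", min = -2^31)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$d_used > cfg$d_total) {
    abort("`d_used` must not exceed `d_total`", class = "facegeom_invalid_argument")
  }
  if (cfg$n_familiar > cfg$n_unfamiliar) {
    abort("`n_familiar` must not exceed `n_unfamiliar`",
          class = "facegeom_invalid_argument")
  }
  if (cfg$t_end_ms <= cfg$t_start_ms ||
      (cfg$t_end_ms - cfg$t_start_ms) %% cfg$bin_ms != 0) {
    abort("`bin_ms` must evenly divide the span [t_start_ms, t_end_ms)",
          class = "facegeom_invalid_argument")
  }
  if (cfg$shift_onset_ms < cfg$visual_onset_ms) {
    abort("`shift_onset_ms` must be >= `visual_onset_ms`",
          class = "facegeom_invalid_argument")
  }
  if (cfg$rotation_onset_ms < cfg$visual_onset_ms) {
    abort("`rotation_onset_ms` must be >= `visual_onset_ms`",
          class = "facegeom_invalid_argument")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flat <- purrr::map_chr(x, function(v) if (is.null(v)) "auto" else paste(v, collapse = ","))
  cat(paste0("  ", format(names(flat)), " : ", flat, collapse = "\n"), "\n")
  invisible(x)
}

#' Read or write a simulation configuration
#'
#' Round-trips losslessly: `read_sim_config(write_sim_config(cfg, path))`
#' equals `cfg`. Format is chosen from the file extension (`.json`, `.yaml` /
#' `.yml`).
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(sim_config, x)
}

# number of time bins implied by a config
n_bins <- function(cfg) (cfg$t_end_ms - cfg$t_start_ms) %/% cfg$bin_ms

# left edges of the bins, ms
bin_starts <- function(cfg) seq(cfg$t_start_ms, cfg$t_end_ms - cfg$bin_ms, by = cfg$bin_ms)
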