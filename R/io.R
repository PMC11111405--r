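# Plain-text readers/writers for the exchange formats: features.tsv,
# spikes.tsv, meta.json, and flat tensor files with a JSON sidecar.

#' Read and write face-feature tables
#'
#' Tab-separated with columns `face_id`, `familiar`, `category`,
#' `subset_tag`, `f1..fd`.
#'
#' @param faces A `face_set`.
#' @param path File path.
#' @return `read_face_set` returns a `face_set`; writers return `path`
#'   invisibly.
#' @export
write_face_set <- function(faces, path) {
  utils::write.table(as.data.frame(faces), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_face_set
#' @export
read_face_set <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  as_face_set(df)
}

#' Read and write spike tables
#'
#' Tab-separated with columns `cell_id`, `trial_id`, `face_id`,
#' `spike_time_ms` (one row per spike).
#'
#' @param spikes Data frame of spikes.
#' @param path File path.
#' @export
write_spike_table <- function(spikes, path) {
  utils::write.table(as.data.frame(spikes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' Read and write response tensors
#'
#' Counts are stored as a flat whitespace-separated text file (column-major,
#' `NA` for masked trials) next to a JSON sidecar `<path>.json` holding the
#' shape, labels, bin metadata and mask.
#'
#' @param tensor A `response_tensor`.
#' @param path Path of the flat counts file.
#' @export
write_response_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "response_tensor"))
  writeLines(paste(as.vector(tensor$counts), collapse = " "), path)
  meta <- list(
    dim = dim(tensor$counts), bin_ms = tensor$bin_ms,
    t_start_ms = tensor$t_start_ms, t_end_ms = tensor$t_end_ms,
    cell_ids = tensor$cell_ids, face_ids = tensor$face_ids,
    mask = as.vector(tensor$mask), region_tag = tensor$region_tag,
    normalized = tensor$normalized
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_response_tensor
#' @export
read_response_tensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- scan(path, what = double(), quiet = TRUE, na.strings = "NA")
  counts <- array(vals, dim = meta$dim)
  if (!isTRUE(meta$normalized) && all(counts[!is.na(counts)] == round(counts[!is.na(counts)]))) {
    storage.mode(counts) <- "integer"
  }
  response_tensor(counts, meta$bin_ms, meta$t_start_ms, meta$t_end_ms,
                  cell_ids = meta$cell_ids, face_ids = meta$face_ids,
                  mask = matrix(meta$mask, nrow = meta$dim[2]),
                  region_tag = meta$region_tag,
                  normalized = isTRUE(meta$normalized))
}

#' Write a full synthetic experiment to a directory
#'
#' Writes `features.tsv`, `spikes.tsv` (reconstructed spike times placed at
#' bin centers, one row per spike), and `meta.json` with bin/epoch metadata,
#' the seed, and the ground-truth generator parameters for test harnesses.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_face_set(sim$faces, file.path(dir, "features.tsv"))
  write_spike_table(tensor_to_spikes(sim$tensor), file.path(dir, "spikes.tsv"))
  cfg <- unclass(sim$pop$config)
  meta <- list(
    config = cfg,
    sigma_signal = sim$pop$sigma_signal,
    shift_norm = sqrt(sum(sim$pop$shift^2)),
    rotation_angle_deg = cfg$rotation_angle_deg,
    bin_ms = sim$tensor$bin_ms,
    t_start_ms = sim$tensor$t_start_ms,
    t_end_ms = sim$tensor$t_end_ms
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Expand a binned tensor into a spike table
#'
#' Inverse-direction convenience for text interchange: each count of `k` in a
#' bin becomes `k` rows with `spike_time_ms` at the bin center. Binning the
#' result with the same grid reproduces the counts exactly.
#'
#' @param tensor A `response_tensor` with integer counts.
#' @return Tibble with `cell_id`, `trial_id`, `face_id`, `spike_time_ms`.
#' @export
tensor_to_spikes <- function(tensor) {
  stopifnot(inherits(tensor, "response_tensor"), !tensor$normalized)
  idx <- which(tensor$counts > 0, arr.ind = TRUE)
  reps <- tensor$counts[idx]
  starts <- tensor_bin_starts(tensor)
  tibble(
    cell_id = rep(tensor$cell_ids[idx[, 1]], reps),
    trial_id = rep(idx[, 3], reps),
    face_id = rep(tensor$face_ids[idx[, 2]], reps),
    spike_time_ms = rep(starts[idx[, 4]] + tensor$bin_ms / 2, reps)
  )
}
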