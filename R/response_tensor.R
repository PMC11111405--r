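#' Response tensor: cells x faces x trials x bins spike counts
#'
#' Container for binned population responses. Counts are nonnegative integers
#' (or reals after normalization, flagged via `normalized`). Missing trials
#' are encoded explicitly through a faces x trials logical `mask`, never as
#' zero counts. Bins are half-open `[t, t + bin_ms)` in ms relative to
#' stimulus onset at 0.
#'
#' @param counts 4-d array, cells x faces x trials x bins. `NA` entries must
#'   agree with `mask`.
#' @param bin_ms Bin width, ms.
#' @param t_start_ms,t_end_ms Span; `(t_end_ms - t_start_ms) / bin_ms` must
#'   equal `dim(counts)[4]`.
#' @param cell_ids,face_ids Label vectors.
#' @param mask faces x trials logical; `TRUE` where the trial was recorded.
#' @param region_tag Free label (e.g. `"AM"`).
#' @param normalized Logical flag set by [normalize_per_cell()].
#' @return A `response_tensor`.
#' @export
response_tensor <- function(counts, bin_ms, t_start_ms, t_end_ms,
                            cell_ids = NULL, face_ids = NULL,
                            mask = NULL, region_tag = "sim",
                            normalized = FALSE) {
  stopifnot(is.array(counts), length(dim(counts)) == 4L)
  dn <- dim(counts)
  expected_bins <- (t_end_ms - t_start_ms) / bin_ms
  if (expected_bins != dn[4]) {
    abort(sprintf("span/bin metadata implies %s bins but counts has %d",
                  format(expected_bins), dn[4]),
          class = "facegeom_invalid_argument")
  }
  cell_ids <- cell_ids %||% sprintf("cell_%03d", seq_len(dn[1]))
  face_ids <- face_ids %||% sprintf("face_%04d", seq_len(dn[2]))
  mask <- mask %||% matrix(TRUE, dn[2], dn[3])
  stopifnot(length(cell_ids) == dn[1], length(face_ids) == dn[2],
            nrow(mask) == dn[2], ncol(mask) == dn[3])
  if (!normalized && is.integer(counts) && any(counts[!is.na(counts)] < 0)) {
    abort("raw counts must be nonnegative", class = "facegeom_invalid_argument")
  }
  structure(
    list(counts = counts, bin_ms = as.integer(bin_ms),
         t_start_ms = as.integer(t_start_ms), t_end_ms = as.integer(t_end_ms),
         cell_ids = cell_ids, face_ids = face_ids, mask = mask,
         region_tag = region_tag, normalized = normalized),
    class = "response_tensor"
  )
}

#' @export
print.response_tensor <- function(x, ...) {
  dn <- dim(x$counts)
  cat(sprintf(
    "<response_tensor> %d cells x %d faces x %d trials x %d bins (%d ms), [%d, %d) ms, region %s%s\n",
    dn[1], dn[2], dn[3], dn[4], x$bin_ms, x$t_start_ms, x$t_end_ms,
    x$region_tag, if (x$normalized) ", normalized" else ""
  ))
  invisible(x)
}

#' @export
dim.response_tensor <- function(x) dim(x$counts)

tensor_bin_starts <- function(tensor) {
  seq(tensor$t_start_ms, tensor$t_end_ms - tensor$bin_ms, by = tensor$bin_ms)
}

#' Bin a spike table into a response tensor
#'
#' @param spikes Data frame with columns `cell_id`, `trial_id`, `face_id`,
#'   `spike_time_ms` (times in ms relative to stimulus onset). `trial_id`
#'   indexes repeats of a face. Rows with times outside the span are dropped;
#'   kept + dropped equals the input row count.
#' @param bin_ms Bin width; must divide the span.
#' @param t_start_ms,t_end_ms Span, half-open `[t_start_ms, t_end_ms)`.
#' @param region_tag Carried into the tensor.
#' @return A `response_tensor`; trials absent for a face are masked.
#' @export
bin_spikes <- function(spikes, bin_ms, t_start_ms, t_end_ms, region_tag = "data") {
  spikes <- as_tibble(spikes)
  need <- c("cell_id", "trial_id", "face_id", "spike_time_ms")
  if (!all(need %in% names(spikes))) {
    abort(paste("spike table needs columns", paste(need, collapse = ", ")),
          class = "facegeom_format_error")
  }
  if (!is.numeric(spikes$spike_time_ms)) {
    abort("`spike_time_ms` must be numeric", class = "facegeom_format_error")
  }
  span <- t_end_ms - t_start_ms
  if (span <= 0 || span %% bin_ms != 0) {
    abort("`bin_ms` must divide the span", class = "facegeom_invalid_argument")
  }
  nb <- span %/% bin_ms
  cell_ids <- sort(unique(as.character(spikes$cell_id)))
  face_ids <- sort(unique(as.character(spikes$face_id)))
  trial_ids <- sort(unique(spikes$trial_id))
  nc <- length(cell_ids); nf <- length(face_ids); nt <- length(trial_ids)

  keep <- spikes$spike_time_ms >= t_start_ms & spikes$spike_time_ms < t_end_ms
  sk <- spikes[keep, ]
  ci <- match(as.character(sk$cell_id), cell_ids)
  fi <- match(as.character(sk$face_id), face_ids)
  ti <- match(sk$trial_id, trial_ids)
  bi <- floor((sk$spike_time_ms - t_start_ms) / bin_ms) + 1L

  counts <- array(0L, dim = c(nc, nf, nt, nb))
  idx <- ((bi - 1L) * nt * nf * nc) + ((ti - 1L) * nf * nc) + ((fi - 1L) * nc) + ci
  tab <- tabulate(idx, nbins = nc * nf * nt * nb)
  counts[] <- tab

  # a trial exists for a face if any cell has a row for it (presentation-level
  # bookkeeping comes from the table itself)
  mask <- matrix(FALSE, nf, nt)
  seen <- unique(spikes[c("face_id", "trial_id")])
  mask[cbind(match(as.character(seen$face_id), face_ids),
             match(seen$trial_id, trial_ids))] <- TRUE
  for (tr in seq_len(nt)) {
    absent <- !mask[, tr]
    if (any(absent)) counts[, absent, tr, ] <- NA_integer_
  }
  response_tensor(counts, bin_ms, t_start_ms, t_end_ms,
                  cell_ids = cell_ids, face_ids = face_ids,
                  mask = mask, region_tag = region_tag)
}

#' Window-averaged response matrix
#'
#' Mean firing rate per cell and face over the half-open window
#' `[t0_ms, t1_ms)`, in Hz, averaged across (unmasked) trials.
#'
#' @param tensor A `response_tensor`.
#' @param t0_ms,t1_ms Window, must lie on bin boundaries within the span.
#' @return cells x faces numeric matrix, dimnames set.
#' @export
window_response <- function(tensor, t0_ms, t1_ms) {
  stopifnot(inherits(tensor, "response_tensor"))
  if (t1_ms <= t0_ms) {
    abort("empty window", class = "facegeom_invalid_argument")
  }
  starts <- tensor_bin_starts(tensor)
  sel <- which(starts >= t0_ms & starts < t1_ms)
  if (length(sel) == 0 || t0_ms < tensor$t_start_ms || t1_ms > tensor$t_end_ms) {
    abort("window must lie within the tensor span",
          class = "facegeom_invalid_argument")
  }
  dn <- dim(tensor$counts)
  x <- tensor$counts[, , , sel, drop = FALSE]
  # sum over bins then average over unmasked trials
  tot <- rowSums(x, dims = 3L)                          # cells x faces x trials
  ntr <- matrix(rowSums(tensor$mask[, , drop = FALSE]), dn[2])  # faces x 1
  tot[is.na(tot)] <- 0
  per_trial_sum <- rowSums(tot, dims = 2L)              # cells x faces
  secs <- length(sel) * tensor$bin_ms / 1000
  rate <- sweep(per_trial_sum, 2, pmax(ntr[, 1], 1) * secs, "/")
  rate[, ntr[, 1] == 0] <- NA_real_
  dimnames(rate) <- list(tensor$cell_ids, tensor$face_ids)
  rate
}

#' Per-cell normalization
#'
#' @param x A cells x faces matrix (rows = cells) or a `response_tensor`.
#' @param method `"zscore"` (per-cell mean 0, s.d. 1 across all its values),
#'   `"max"` (divide by the per-cell maximum), or `"none"`.
#' @return Same shape as the input. Cells with zero variance under `"zscore"`
#'   are flagged (attribute `"excluded_cells"`) and returned as `NA` rather
#'   than propagating `NaN` silently.
#' @export
normalize_per_cell <- function(x, method = c("zscore", "max", "none")) {
  method <- arg_match(method)
  if (inherits(x, "response_tensor")) {
    dn <- dim(x$counts)
    flat <- matrix(aperm(x$counts, c(1, 2, 3, 4)), nrow = dn[1])
    norm <- normalize_per_cell(flat, method)
    out <- x
    out$counts <- array(norm, dim = dn)
    out$normalized <- method != "none"
    attr(out, "excluded_cells") <- attr(norm, "excluded_cells")
    return(out)
  }
  stopifnot(is.matrix(x))
  if (method == "none") return(x)
  if (method == "max") {
    mx <- apply(abs(x), 1, max, na.rm = TRUE)
    mx[mx == 0] <- 1
    return(structure(sweep(x, 1, mx, "/"), excluded_cells = character(0),
                     dimnames = dimnames(x)))
  }
  mu <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1, sd, na.rm = TRUE)
  bad <- !is.finite(s) | s == 0
  s[bad] <- 1
  out <- sweep(sweep(x, 1, mu, "-"), 1, s, "/")
  out[bad, ] <- NA_real_
  if (any(bad)) {
    inform(sprintf("normalize_per_cell: excluded %d zero-variance cell(s)",
                   sum(bad)))
  }
  structure(out, excluded_cells = rownames(x)[bad] %||% which(bad),
            dimnames = dimnames(x))
}
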