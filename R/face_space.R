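#' Sample a synthetic face space
#'
#' Draws `n` faces from a `d`-dimensional parametric face space. Coordinates
#' are i.i.d. standard normal, i.e. the shape/appearance features are treated
#' as whitened face-space coordinates. The first `d/2` columns are labelled
#' shape features and the rest appearance features, mirroring the convention
#' of parametric face models (landmark geometry vs. shape-free texture).
#'
#' @param n Number of faces (>= 1).
#' @param d Face-space dimensionality (>= 2).
#' @param seed Integer seed; the draw is deterministic given `(n, d, seed)`.
#' @param familiar Logical, recycled to length `n`; familiarity labels.
#' @param category One of `"human_face"`, `"monkey_face"`, `"object"`,
#'   recycled to length `n`.
#' @param subset_tag Free-text tag recorded on every row (e.g. `"pool1000"`).
#' @param prefix Prefix for generated `face_id`s.
#'
#' @return A `face_set` tibble with columns `face_id`, `familiar`, `category`,
#'   `subset_tag` and feature columns `f1..fd`.
#' @export
#' @examples
#' faces <- sample_face_space(20, d = 4, seed = 1)
#' feature_matrix(faces)[1:3, ]
sample_face_space <- function(n, d, seed = 1L,
                              familiar = FALSE,
                              category = "monkey_face",
                              subset_tag = "pool",
                              prefix = "face") {
  n <- check_count(n, "n", min = 1L)
  d <- check_count(d, "d", min = 2L)
  seed <- check_count(seed, "seed", min = -2^31)
  category <- arg_match(category, c("human_face", "monkey_face", "object"),
                        multiple = TRUE)
  feats <- withr::with_seed(seed, matrix(rnorm(n * d), nrow = n, ncol = d))
  colnames(feats) <- paste0("f", seq_len(d))
  out <- tibble(
    face_id = sprintf("%s_%0*d", prefix, nchar(as.character(n)), seq_len(n)),
    familiar = rep_len(as.logical(familiar), n),
    category = rep_len(category, n),
    subset_tag = rep_len(subset_tag, n)
  )
  out <- dplyr::bind_cols(out, as_tibble(feats))
  new_face_set(out)
}

new_face_set <- function(x) {
  stopifnot(is.data.frame(x))
  class(x) <- unique(c("face_set", class(tibble())))
  x
}

#' Coerce a data frame of faces to a face set
#'
#' @param x A data frame with `face_id` and feature columns `f1..fd`;
#'   `familiar`, `category` and `subset_tag` are filled with defaults when
#'   absent.
#' @return A `face_set` tibble.
#' @export
as_face_set <- function(x) {
  x <- as_tibble(x)
  if (!"face_id" %in% names(x)) {
    abort("a face set needs a `face_id` column", class = "facegeom_format_error")
  }
  if (anyDuplicated(x$face_id)) {
    abort("`face_id` values must be unique within a face set",
          class = "facegeom_format_error")
  }
  if (!"familiar" %in% names(x)) x$familiar <- FALSE
  if (!"category" %in% names(x)) x$category <- "monkey_face"
  if (!"subset_tag" %in% names(x)) x$subset_tag <- ""
  d <- length(feature_cols(x))
  if (d < 2) {
    abort("a face set needs at least two feature columns `f1`, `f2`, ...",
          class = "facegeom_format_error")
  }
  new_face_set(x[c("face_id", "familiar", "category", "subset_tag",
                   feature_cols(x))])
}

feature_cols <- function(faces) {
  grep("^f[0-9]+$", names(faces), value = TRUE)
}

#' Extract the faces-by-features matrix from a face set
#'
#' @param faces A `face_set` tibble.
#' @param d_used Optionally keep only the first `d_used` feature columns
#'   (e.g. the top ten shape plus top ten appearance features).
#' @return Numeric matrix, faces x features, rownames set to `face_id`.
#' @export
feature_matrix <- function(faces, d_used = NULL) {
  cols <- feature_cols(faces)
  if (!is.null(d_used)) {
    d_used <- check_count(d_used, "d_used")
    if (d_used > length(cols)) {
      abort(sprintf("`d_used` = %d exceeds the %d available features",
                    d_used, length(cols)),
            class = "facegeom_invalid_argument")
    }
    cols <- cols[seq_len(d_used)]
  }
  m <- as.matrix(faces[cols])
  rownames(m) <- faces$face_id
  storage.mode(m) <- "double"
  m
}
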