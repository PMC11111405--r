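# Internal helpers shared across modules.

# scalar checks ---------------------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(
      sprintf("`%s` must be a single integer >= %d, got %s.", name, min, deparse(x)),
      class = "facegeom_invalid_argument"
    )
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(
      sprintf("`%s` must be a single number in [%s, %s].", name, min, max),
      class = "facegeom_invalid_argument"
    )
  }
  as.numeric(x)
}

# linear algebra --------------------------------------------------------------

#' @noRd
unitize <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) {
    abort("cannot normalize a zero vector", class = "facegeom_undefined_similarity")
  }
  x / n
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cosine similarity undefined for a zero vector",
          class = "facegeom_undefined_similarity")
  }
  sum(a * b) / (na * nb)
}

# columnwise cosine between two d x k coefficient matrices
col_cosines <- function(A, B) {
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2)) * sqrt(colSums(B^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# ridge normal-equations solve for multi-target regression.
# X: n x p (already centered/standardized as the caller requires),
# Y: n x k. Returns p x k coefficients. ridge is the absolute penalty
# added to the diagonal of X'X.
ridge_solve <- function(X, Y, ridge = 0) {
  XtX <- crossprod(X)
  if (ridge > 0) {
    XtX <- XtX + diag(ridge, ncol(X))
  } else if (rcond(XtX) < 1e-12) {
    abort(
      "design matrix is rank deficient; refit with `ridge > 0`",
      class = "facegeom_rank_deficient"
    )
  }
  ok <- tryCatch({
    R <- chol(XtX)
    backsolve(R, backsolve(R, crossprod(X, Y), transpose = TRUE))
  }, error = function(e) NULL)
  if (is.null(ok)) {
    abort(
      "design matrix is rank deficient; refit with `ridge > 0`",
      class = "facegeom_rank_deficient"
    )
  }
  ok
}

# default ridge scaling: lambda * trace(X'X)/p (0 disables)
scaled_ridge <- function(X, ridge_rel) {
  if (ridge_rel <= 0) return(0)
  ridge_rel * sum(X^2) / ncol(X)
}

# two-sample Kolmogorov-Smirnov statistic (sort-based; fast enough for the
# matching swap loop where it is evaluated tens of thousands of times)
ks_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  o <- order(z)
  steps <- ifelse(o <= nx, 1 / nx, -1 / ny)
  cs <- cumsum(steps)
  zo <- z[o]
  # evaluate the ecdf gap only after each tie group, so identical samples
  # give D = 0
  last_of_group <- c(zo[-1] != zo[-length(zo)], TRUE)
  max(abs(cs[last_of_group]))
}

# seed helper: derive a child seed stream from a base seed, kept < 2^31
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9973) %% 2147483647)
}
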