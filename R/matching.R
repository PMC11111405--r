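# Distribution-matched stimulus subset selection: pick k familiar and k
# unfamiliar faces whose per-feature distributions and pairwise-distance
# distributions agree, by greedy single-member swaps minimizing a summed
# Kolmogorov-Smirnov objective.

match_objective <- function(Ff, Fu, lambda = 1) {
  per_feature <- vapply(seq_len(ncol(Ff)), function(j) {
    ks_stat(Ff[, j], Fu[, j])
  }, numeric(1))
  dist_ks <- ks_stat(as.numeric(stats::dist(Ff)), as.numeric(stats::dist(Fu)))
  list(objective = sum(per_feature) + lambda * dist_ks,
       per_feature = per_feature, dist_ks = dist_ks)
}

#' Select feature-matched familiar/unfamiliar subsets
#'
#' Searches for `k` familiar and `k` unfamiliar faces matched in the
#' distribution of every feature and in the distribution of pairwise face
#' distances. The objective is the sum over features of the two-sample KS
#' statistic between the subsets plus `lambda` times the KS statistic
#' between their pairwise Euclidean distance distributions, minimized by
#' greedy coordinate descent: each step proposes swapping one subset member
#' for a non-member (alternating sides, random proposals) and accepts the
#' swap only if the objective decreases. Deterministic for a given seed.
#'
#' @param fam_set Familiar `face_set`.
#' @param unfam_pool Unfamiliar pool `face_set` (common standardization with
#'   `fam_set` assumed).
#' @param k Subset size (default 30; `k <= min(|fam|, |unfam|)`).
#' @param max_iter Maximum proposals (default 2000).
#' @param seed Seed for initialization and proposals.
#' @param lambda Weight of the pairwise-distance term (default 1).
#' @param d_used Leading features to match (default all shared features).
#' @return A `match_result`: list with `familiar_idx`, `unfamiliar_idx`,
#'   `objective_trace` (nonincreasing over accepted steps),
#'   `per_feature_ks_before`/`_after`, `dist_ks_before`/`_after`,
#'   `improved` flag, and `seed`.
#' @export
match_subsets <- function(fam_set, unfam_pool, k = 30, max_iter = 2000,
                          seed = 1L, lambda = 1, d_used = NULL) {
  fam_set <- as_face_set(fam_set)
  unfam_pool <- as_face_set(unfam_pool)
  if (k > min(nrow(fam_set), nrow(unfam_pool))) {
    abort("`k` exceeds an available set size",
          class = "facegeom_invalid_argument")
  }
  d_used <- d_used %||% min(length(feature_cols(fam_set)),
                            length(feature_cols(unfam_pool)))
  Ff_all <- feature_matrix(fam_set, d_used = d_used)
  Fu_all <- feature_matrix(unfam_pool, d_used = d_used)
  # cross-distances guide half the unfamiliar-side proposals: swapping in
  # the pool face nearest to a familiar member is the move most likely to
  # tighten per-feature and pairwise-distance matches
  cross <- outer(rowSums(Ff_all^2), rep(1, nrow(Fu_all))) +
    outer(rep(1, nrow(Ff_all)), rowSums(Fu_all^2)) -
    2 * Ff_all %*% t(Fu_all)
  nearest <- apply(cross, 1, order)               # pool ranks per familiar face

  # precomputed within-set pairwise distances; subset objective reads slices
  Dff <- as.matrix(stats::dist(Ff_all))
  Duu <- as.matrix(stats::dist(Fu_all))
  obj_of <- function(sf, su) {
    per_feature <- vapply(seq_len(d_used), function(j) {
      ks_stat(Ff_all[sf, j], Fu_all[su, j])
    }, numeric(1))
    dist_ks <- ks_stat(Dff[sf, sf][lower.tri(diag(k))],
                       Duu[su, su][lower.tri(diag(k))])
    list(objective = sum(per_feature) + lambda * dist_ks,
         per_feature = per_feature, dist_ks = dist_ks)
  }

  withr::with_seed(seed, {
    sel_f <- sample(nrow(Ff_all), k)
    # the "before" state is a plain random draw of both subsets
    before <- obj_of(sel_f, sample(nrow(Fu_all), k))
    # initialize the pool side by greedy nearest-neighbour matching: each
    # selected familiar face claims its closest unused pool face, which
    # starts the search near distribution equality
    sel_u <- integer(0)
    for (i in sample(sel_f)) {
      ranks <- nearest[, i]
      sel_u <- c(sel_u, ranks[!ranks %in% sel_u][1])
    }
    cur <- obj_of(sel_f, sel_u)
    trace <- cur$objective
    best <- list(obj = cur, sel_f = sel_f, sel_u = sel_u)
    improved <- FALSE
    it <- 0L
    while (it < max_iter) {
      swap_fam <- (it %% 2 == 0) && nrow(Ff_all) > k
      it <- it + 1L
      # one member leaves; the best of a candidate shortlist may replace it
      if (swap_fam) {
        open <- setdiff(seq_len(nrow(Ff_all)), sel_f)
        if (length(open) == 0) next
        out_i <- sample(k, 1)
        prop_f <- sel_f; prop_f[out_i] <- sample(open, 1)
        prop_u <- sel_u
      } else {
        open <- setdiff(seq_len(nrow(Fu_all)), sel_u)
        if (length(open) == 0) next
        u <- runif(1)
        if (u < 0.4) {
          out_i <- sample(k, 1)
          cand <- sample(open, 1)
        } else if (u < 0.7) {
          out_i <- sample(k, 1)
          guided <- nearest[, sample(sel_f, 1)]
          cand <- guided[guided %in% open][1]
        } else {
          # target the worst feature: move pool mass across the point of
          # largest ecdf gap, out of the surplus side into the deficit side
          j <- which.max(cur$per_feature)
          xf <- sort(Ff_all[sel_f, j]); xu <- Fu_all[sel_u, j]
          gaps <- vapply(xf, function(z) mean(xu <= z) - mean(xf <= z),
                         numeric(1))
          z_star <- xf[which.max(abs(gaps))]
          surplus <- gaps[which.max(abs(gaps))] > 0   # pool heavy below z*
          out_pool <- if (surplus) which(xu <= z_star) else which(xu > z_star)
          in_pool <- if (surplus) open[Fu_all[open, j] > z_star] else
            open[Fu_all[open, j] <= z_star]
          if (length(out_pool) == 0 || length(in_pool) == 0) next
          out_i <- out_pool[sample(length(out_pool), 1)]
          cand <- in_pool[sample(length(in_pool), 1)]
        }
        prop_u <- sel_u; prop_u[out_i] <- cand
        prop_f <- sel_f
      }
      prop <- obj_of(prop_f, prop_u)
      # strict improvement, or plateau walking: equal objective but a
      # smaller worst-feature divergence (KS values move on a 1/k grid, so
      # exact plateaus are common and hide better-balanced subsets)
      accept <- prop$objective < cur$objective - 1e-12 ||
        (prop$objective < cur$objective + 1e-12 &&
           max(prop$per_feature) < max(cur$per_feature) - 1e-12)
      if (accept) {
        sel_f <- prop_f; sel_u <- prop_u; cur <- prop
        improved <- TRUE
        trace <- c(trace, cur$objective)
        if (cur$objective < best$obj$objective - 1e-12 ||
            (cur$objective < best$obj$objective + 1e-12 &&
               max(cur$per_feature) < max(best$obj$per_feature))) {
          best <- list(obj = cur, sel_f = sel_f, sel_u = sel_u)
        }
      }
    }
  })
  structure(
    list(
      familiar_idx = sort(best$sel_f),
      unfamiliar_idx = sort(best$sel_u),
      familiar_ids = fam_set$face_id[sort(best$sel_f)],
      unfamiliar_ids = unfam_pool$face_id[sort(best$sel_u)],
      objective_trace = trace,
      per_feature_ks_before = before$per_feature,
      per_feature_ks_after = best$obj$per_feature,
      dist_ks_before = before$dist_ks,
      dist_ks_after = best$obj$dist_ks,
      objective_before = before$objective,
      objective_after = best$obj$objective,
      improved = improved, k = k, lambda = lambda, d_used = d_used,
      seed = seed
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> k = %d: objective %.3f -> %.3f (max per-feature KS %.3f -> %.3f)%s\n",
    x$k, x$objective_before, x$objective_after,
    max(x$per_feature_ks_before), max(x$per_feature_ks_after),
    if (!x$improved) " [no improving swap found]" else ""))
  invisible(x)
}

#' Diagnostics for a matching result
#'
#' Recomputes every divergence from scratch on the returned subsets (these
#' must equal the stored values exactly), and summarizes per-feature
#' quantile-quantile agreement plus the pairwise-distance distributions.
#' KS p-values flag features that remain mismatched.
#'
#' @param result A `match_result`.
#' @param fam_set,unfam_pool The face sets passed to [match_subsets()].
#' @param n_quantiles Number of QQ probe quantiles.
#' @return List with `per_feature` tibble (`feature`, `ks`, `ks_p`,
#'   `flagged`, mean QQ gap), `distance` tibble, and the recomputed
#'   `objective`.
#' @export
matching_report <- function(result, fam_set, unfam_pool, n_quantiles = 9) {
  stopifnot(inherits(result, "match_result"))
  fam_set <- as_face_set(fam_set)
  unfam_pool <- as_face_set(unfam_pool)
  Ff <- feature_matrix(fam_set, d_used = result$d_used)[result$familiar_idx, ,
                                                        drop = FALSE]
  Fu <- feature_matrix(unfam_pool, d_used = result$d_used)[result$unfamiliar_idx, ,
                                                           drop = FALSE]
  obj <- match_objective(Ff, Fu, result$lambda)
  probs <- seq(0.1, 0.9, length.out = n_quantiles)
  per_feature <- purrr::map(seq_len(ncol(Ff)), function(j) {
    kt <- suppressWarnings(stats::ks.test(Ff[, j], Fu[, j]))
    tibble(
      feature = paste0("f", j),
      ks = obj$per_feature[j],
      ks_p = kt$p.value,
      flagged = kt$p.value < 0.05,
      mean_qq_gap = mean(abs(quantile(Ff[, j], probs) - quantile(Fu[, j], probs)))
    )
  })
  df <- as.numeric(stats::dist(Ff)); du <- as.numeric(stats::dist(Fu))
  kd <- suppressWarnings(stats::ks.test(df, du))
  list(
    per_feature = bind_rows(per_feature),
    distance = tibble(ks = obj$dist_ks, ks_p = kd$p.value,
                      mean_fam = mean(df), mean_unfam = mean(du)),
    objective = obj$objective
  )
}
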