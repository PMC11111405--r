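# Comparison of preferred axes across stimulus sets and time: the
# unfamiliar-unfamiliar (UU) noise ceiling versus the unfamiliar-familiar
# (UF) similarity, whose deficit is the signature of memory-driven axis
# rotation.

#' Cosine similarity between two fitted axes
#'
#' @param fitA,fitB `axis_fit` objects (or vectors) of equal dimensionality.
#' @return Cosine of the unit-normalized coefficient vectors.
#' @export
axis_similarity <- function(fitA, fitB) {
  a <- if (is.list(fitA)) fitA$coef else fitA
  b <- if (is.list(fitB)) fitB$coef else fitB
  if (length(a) != length(b)) {
    abort("axes have different feature dimensionality",
          class = "facegeom_invalid_argument")
  }
  cosine(a, b)
}

#' Unfamiliar-unfamiliar vs unfamiliar-familiar axis comparison
#'
#' For each cell, a reference axis is fit on the unfamiliar pool minus a
#' held-out subset of `n_heldout` faces. Its cosine similarity is computed
#' against (a) an axis fit on the held-out unfamiliar faces (UU, the
#' matched-n noise ceiling) and (b) an axis fit on `n_heldout` familiar
#' faces (UF). The held-out draw is repeated `n_resamples` times and
#' averaged per cell. The headline p-value comes from a one-tailed set-level
#' exchangeability test (the familiar set's population-mean cosine referred to
#' the distribution of held-out unfamiliar set means, which stays calibrated
#' under the shared-design random effect); the across-cell paired t-test is
#' also reported as `statistic_cells` / `p_value_cells`.
#'
#' @param tensor A `response_tensor` (or cells x faces rate matrix).
#' @param faces Aligned `face_set` (`familiar` column splits the sets).
#' @param window Response window, ms.
#' @param n_heldout Matched set size (default 36).
#' @param n_resamples Held-out redraws to average (default 20).
#' @param seed Seed for the redraws.
#' @param d_used,ridge Passed to the axis fits.
#' @param familiar Optional logical over faces overriding `faces$familiar`
#'   (used by [contrast_control()] to compare arbitrary set pairs).
#' @return An `axis_comparison`: tibble of per-cell mean `uu`/`uf` cosines
#'   with attributes `statistic`, `p_value`, `n_cells`, `window`.
#' @export
uu_uf_comparison <- function(tensor, faces, window = c(50, 300),
                             n_heldout = 36, n_resamples = 20, seed = 1L,
                             d_used = 20, ridge = 1e-6, familiar = NULL) {
  R <- if (inherits(tensor, "response_tensor")) {
    window_response(tensor, window[1], window[2])
  } else tensor
  faces <- as_face_set(faces)
  fam <- familiar %||% faces$familiar
  idx_fam <- which(fam)
  idx_unf <- which(!fam)
  if (length(idx_fam) < n_heldout || length(idx_unf) < 2 * n_heldout) {
    abort(sprintf(
      "need >= %d familiar and >= %d unfamiliar faces", n_heldout, 2 * n_heldout),
      class = "facegeom_insufficient_data")
  }
  Rt <- t(R)                                            # faces x cells
  F <- feature_matrix(faces, d_used = min(d_used, length(feature_cols(faces))))
  nc <- ncol(Rt)
  uu <- uf <- matrix(NA_real_, nc, n_resamples)
  tau_u <- tau_f <- rep(NA_real_, n_resamples)
  withr::with_seed(seed, {
    for (s in seq_len(n_resamples)) {
      held <- sample(idx_unf, n_heldout)
      ref_idx <- setdiff(idx_unf, held)
      fam_idx <- if (length(idx_fam) == n_heldout) idx_fam else
        sample(idx_fam, n_heldout)
      ref <- fit_axes_matrix(Rt[ref_idx, , drop = FALSE],
                             F[ref_idx, , drop = FALSE], ridge = ridge)
      fu <- fit_axes_matrix(Rt[held, , drop = FALSE],
                            F[held, , drop = FALSE], ridge = ridge)
      ff <- fit_axes_matrix(Rt[fam_idx, , drop = FALSE],
                            F[fam_idx, , drop = FALSE], ridge = ridge)
      uu[, s] <- col_cosines(ref$unit, fu$unit)
      uf[, s] <- col_cosines(ref$unit, ff$unit)
      tau_u[s] <- design_tau(F[held, , drop = FALSE])
      tau_f[s] <- design_tau(F[fam_idx, , drop = FALSE])
    }
  })
  per_cell <- tibble(
    cell_id = if (inherits(tensor, "response_tensor")) tensor$cell_ids else
      rownames(R) %||% sprintf("cell_%03d", seq_len(nc)),
    uu = rowMeans(uu, na.rm = TRUE),
    uf = rowMeans(uf, na.rm = TRUE)
  )
  keep <- is.finite(per_cell$uu) & is.finite(per_cell$uf)
  tt <- t.test(per_cell$uu[keep], per_cell$uf[keep], paired = TRUE,
               alternative = "greater")
  set_test <- set_level_test(uu[keep, , drop = FALSE], uf[keep, , drop = FALSE],
                             tau_u = tau_u, tau_f = tau_f)
  structure(per_cell, class = c("axis_comparison", class(tibble())),
            statistic = set_test$statistic, p_value = set_test$p_value,
            statistic_cells = unname(tt$statistic),
            p_value_cells = tt$p.value,
            n_cells = sum(keep), window = window,
            mean_uu = mean(per_cell$uu[keep]), mean_uf = mean(per_cell$uf[keep]))
}

# Set-level exchangeability test. The familiar (or control) axis is fit on
# ONE fixed stimulus set, so its estimation error has a component shared by
# all cells (the design of those 36 faces); an across-cell paired t-test
# treats that shared component as signal and is anticonservative. Under the
# no-rotation null the familiar set is exchangeable with any held-out
# unfamiliar set of the same size, so the population-mean UF cosine is
# referred to the distribution of population-mean UU cosines across held-out
# draws (Student-t reference). Most of the set-to-set spread is predictable
# from each set's design conditioning tau = trace((X'X)^-1) (noisier axis
# estimates on ill-conditioned draws attenuate the cosine), so tau is
# regressed out of the reference distribution and the familiar set is
# compared at its own tau — a noise-ceiling adjustment that roughly doubles
# power without sacrificing calibration.
set_level_test <- function(uu_mat, uf_mat, tau_u = NULL, tau_f = NULL) {
  uu_means <- colMeans(uu_mat, na.rm = TRUE)
  uf_means <- colMeans(uf_mat, na.rm = TRUE)
  S <- length(uu_means)
  if (S < 3 || !is.finite(sd(uu_means)) || sd(uu_means) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  if (!is.null(tau_u) && !is.null(tau_f) && all(is.finite(tau_u)) &&
      all(is.finite(tau_f)) && S >= 4 && sd(tau_u) > 0) {
    fit <- stats::lm(uu_means ~ tau_u)
    pred_uf <- mean(stats::coef(fit)[1] + stats::coef(fit)[2] * tau_f)
    resid_sd <- summary(fit)$sigma
    lev <- (mean(tau_f) - mean(tau_u))^2 / sum((tau_u - mean(tau_u))^2)
    z <- (pred_uf - mean(uf_means)) /
      (resid_sd * sqrt(1 + 1 / S + lev))
    df <- S - 2
  } else {
    z <- (mean(uu_means) - mean(uf_means)) /
      (sd(uu_means) * sqrt(1 + 1 / S))
    df <- S - 1
  }
  list(statistic = z, p_value = stats::pt(z, df = df, lower.tail = FALSE))
}

# design-conditioning score of a fitting set: trace((X'X)^-1) of its
# standardized feature design (larger = noisier axis estimate)
design_tau <- function(F_sub) {
  X <- scale(F_sub)
  tryCatch(sum(diag(solve(crossprod(X)))), error = function(e) NA_real_)
}

#' @export
print.axis_comparison <- function(x, ...) {
  cat(sprintf(
    "<axis_comparison> %d cells, window [%s, %s) ms: mean UU = %.3f, mean UF = %.3f, t = %.2f, p = %.3g\n",
    attr(x, "n_cells"), attr(x, "window")[1], attr(x, "window")[2],
    attr(x, "mean_uu"), attr(x, "mean_uf"),
    attr(x, "statistic"), attr(x, "p_value")))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.axis_comparison <- function(x, ...) {
  tibble(mean_uu = attr(x, "mean_uu"), mean_uf = attr(x, "mean_uf"),
         statistic = attr(x, "statistic"), p_value = attr(x, "p_value"),
         statistic_cells = attr(x, "statistic_cells"),
         p_value_cells = attr(x, "p_value_cells"),
         n_cells = attr(x, "n_cells"))
}

#' Time course of UU and UF axis similarity
#'
#' Runs [uu_uf_comparison()] in rolling windows and detects the axis-
#' divergence latency: the trailing edge of the first of two consecutive
#' windows with one-tailed `p < alpha`.
#'
#' @inheritParams uu_uf_comparison
#' @param width_ms,step_ms Rolling window width and step (default 50/10 ms).
#' @param alpha Detection level (default 0.001).
#' @param n_resamples Held-out redraws per window (default 10).
#' @return List with `uu` and `uf` `geometry_trace`s, `p_values`, and
#'   `latency_ms`.
#' @export
time_resolved_axis_similarity <- function(tensor, faces, width_ms = 50,
                                          step_ms = 10, alpha = 0.001,
                                          n_heldout = 36, n_resamples = 10,
                                          seed = 1L, d_used = 20,
                                          ridge = 1e-6) {
  stopifnot(inherits(tensor, "response_tensor"))
  win <- rolling_windows(tensor$t_start_ms, tensor$t_end_ms, width_ms, step_ms)
  rows <- purrr::pmap(win, function(t0, t1, time_ms) {
    cmp <- uu_uf_comparison(tensor, faces, window = c(t0, t1),
                            n_heldout = n_heldout, n_resamples = n_resamples,
                            seed = child_seed(seed, time_ms),
                            d_used = d_used, ridge = ridge)
    n <- attr(cmp, "n_cells")
    tibble(
      time_ms = time_ms,
      uu = attr(cmp, "mean_uu"), uu_sem = sd(cmp$uu, na.rm = TRUE) / sqrt(n),
      uf = attr(cmp, "mean_uf"), uf_sem = sd(cmp$uf, na.rm = TRUE) / sqrt(n),
      p_value = attr(cmp, "p_value")
    )
  })
  df <- bind_rows(rows)
  lat <- detect_latency(df$time_ms, df$p_value, alpha, consecutive = 2L)
  list(
    uu = geometry_trace(
      tibble(time_ms = df$time_ms, value = df$uu, sem = df$uu_sem),
      method_tag = "UU axis similarity"),
    uf = geometry_trace(
      tibble(time_ms = df$time_ms, value = df$uf, sem = df$uf_sem,
             p_value = df$p_value),
      latency_ms = lat, method_tag = "UF axis similarity", alpha = alpha),
    p_values = df$p_value,
    latency_ms = lat
  )
}

#' Contrast (gain) control comparison
#'
#' Asks whether a control set (e.g. low-contrast faces) is encoded by a
#' genuinely different axis, or merely at a different signal-to-noise ratio.
#' A gain change (or any monotone output transform preserving the rank order
#' of preferred stimuli) attenuates the cosine between the reference axis
#' and an axis fit on the control set simply because the estimate is
#' noisier, so the observed cosine is compared per cell against an
#' SNR-matched null: responses of the control set are re-simulated under the
#' no-rotation hypothesis (reference axis scaled to the control set's fitted
#' gain, Gaussian noise at its fitted residual s.d.), axes refit, and the
#' null cosine distribution built. The paired t-test across cells then asks
#' whether observed cosines fall below the null mean — a deficit beyond what
#' the control set's own SNR predicts.
#'
#' @inheritParams uu_uf_comparison
#' @param control Logical over faces marking the control (e.g. low-contrast)
#'   set; remaining non-control, non-familiar faces form the reference pool.
#' @param n_null Null re-simulations per cell (default 20).
#' @return Tibble with per-cell `observed` and `null_mean` cosines, and
#'   attributes `statistic`, `p_value` (one-tailed, observed < null),
#'   `n_cells`, `window`.
#' @export
contrast_control <- function(tensor, faces, control, window = c(50, 300),
                             n_heldout = 36, n_resamples = 20, n_null = 20,
                             seed = 1L, d_used = 20, ridge = 1e-6) {
  R <- if (inherits(tensor, "response_tensor")) {
    window_response(tensor, window[1], window[2])
  } else tensor
  faces <- as_face_set(faces)
  control <- as.logical(control)
  idx_ctl <- which(control)
  idx_pool <- which(!control & !faces$familiar)
  if (length(idx_pool) < 2 * length(idx_ctl)) {
    abort("reference pool must hold at least twice the control set",
          class = "facegeom_insufficient_data")
  }
  Rt <- t(R)
  F <- feature_matrix(faces, d_used = min(d_used, length(feature_cols(faces))))
  nc <- ncol(Rt)
  withr::with_seed(seed, {
    ref <- fit_axes_matrix(Rt[idx_pool, , drop = FALSE],
                           F[idx_pool, , drop = FALSE], ridge = ridge)
    ctl <- fit_axes_matrix(Rt[idx_ctl, , drop = FALSE],
                           F[idx_ctl, , drop = FALSE], ridge = ridge)
    observed <- col_cosines(ref$unit, ctl$unit)

    # SNR-matched null: control responses re-simulated with the reference
    # axis at the control set's own per-cell gain and residual noise
    Xc <- standardize_features(F[idx_ctl, , drop = FALSE])$X
    proj <- Xc %*% ref$unit                       # faces x cells
    Yc <- Rt[idx_ctl, , drop = FALSE]
    Yc <- sweep(Yc, 2, colMeans(Yc), "-")
    alpha <- colSums(proj * Yc) / pmax(colSums(proj^2), 1e-12)
    resid_sd <- sqrt(pmax(colMeans((Yc - sweep(proj, 2, alpha, "*"))^2), 0))
    null_cos <- matrix(NA_real_, nc, n_null)
    for (b in seq_len(n_null)) {
      Ystar <- sweep(proj, 2, alpha, "*") +
        sweep(matrix(rnorm(length(Yc)), nrow(Yc)), 2, resid_sd, "*")
      refit <- fit_axes_matrix(Ystar, F[idx_ctl, , drop = FALSE],
                               ridge = ridge)
      null_cos[, b] <- col_cosines(ref$unit, refit$unit)
    }
  })
  null_mean <- rowMeans(null_cos)
  keep <- is.finite(observed) & is.finite(null_mean)
  tt <- t.test(null_mean[keep], observed[keep], paired = TRUE,
               alternative = "greater")
  structure(
    tibble(cell_id = if (inherits(tensor, "response_tensor"))
      tensor$cell_ids else rownames(R) %||% sprintf("cell_%03d", seq_len(nc)),
      observed = observed, null_mean = null_mean),
    class = c("contrast_control", class(tibble())),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    n_cells = sum(keep), window = window,
    mean_observed = mean(observed[keep]),
    mean_null = mean(null_mean[keep])
  )
}

#' @export
print.contrast_control <- function(x, ...) {
  cat(sprintf(
    "<contrast_control> %d cells: observed cosine %.3f vs SNR-matched null %.3f, t = %.2f, p = %.3g\n",
    attr(x, "n_cells"), attr(x, "mean_observed"), attr(x, "mean_null"),
    attr(x, "statistic"), attr(x, "p_value")))
  invisible(x)
}

#' Axis-change stability across temporal contexts
#'
#' Compares the familiar-axis deficit measured in two context datasets (e.g.
#' familiar-majority 34:16 and familiar-minority 36:1,000 compositions). The
#' unfamiliar reference axis is fit on the larger unfamiliar pool of the two
#' datasets (a minority-unfamiliar context has too few unfamiliar faces to
#' fit d-dimensional axes); the familiar axis is fit within each context.
#' Also reports the per-context familiar-minus-unfamiliar mean rate
#' difference, whose sign is expected to track the minority class, and the
#' cross-context stability cosine between the two familiar axes.
#'
#' @param expA,expB Lists with `tensor` and `faces` (as returned by
#'   [make_context_experiment()]).
#' @param window Response window, ms.
#' @param n_resamples,seed,d_used,ridge As in [uu_uf_comparison()].
#' @return List with per-context tibbles `comparison` (UU/UF t-tests),
#'   `rate_diff_hz` (familiar minus unfamiliar population mean rate), and
#'   `stability` (per-cell cosine between the familiar axes of A and B, plus
#'   its mean).
#' @export
cross_context_axis_stability <- function(expA, expB, window = c(50, 300),
                                         n_resamples = 20, seed = 1L,
                                         d_used = 20, ridge = 1e-6) {
  ctx <- list(A = expA, B = expB)
  n_unf <- vapply(ctx, function(e) sum(!e$faces$familiar), numeric(1))
  ref_ctx <- names(ctx)[which.max(n_unf)]
  ref_exp <- ctx[[ref_ctx]]
  Rref <- window_response(ref_exp$tensor, window[1], window[2])
  Fref <- feature_matrix(ref_exp$faces, d_used = d_used)
  unf_ref <- which(!ref_exp$faces$familiar)

  fam_fit <- function(e) {
    R <- window_response(e$tensor, window[1], window[2])
    idx <- which(e$faces$familiar)
    fit_axes_matrix(t(R)[idx, , drop = FALSE],
                    feature_matrix(e$faces, d_used = d_used)[idx, , drop = FALSE],
                    ridge = ridge)
  }
  fits <- lapply(ctx, fam_fit)

  per_context <- imap(ctx, function(e, nm) {
    n_fam <- sum(e$faces$familiar)
    n_held <- min(n_fam, floor(length(unf_ref) / 2))
    uu <- uf <- matrix(NA_real_, ncol(fits[[nm]]$unit), n_resamples)
    tau_u <- rep(NA_real_, n_resamples)
    fam_idx_e <- which(e$faces$familiar)
    tau_f <- design_tau(
      feature_matrix(e$faces, d_used = d_used)[fam_idx_e, , drop = FALSE])
    withr::with_seed(child_seed(seed, match(nm, names(ctx))), {
      for (s in seq_len(n_resamples)) {
        held <- sample(unf_ref, n_held)
        ref <- fit_axes_matrix(t(Rref)[setdiff(unf_ref, held), , drop = FALSE],
                               Fref[setdiff(unf_ref, held), , drop = FALSE],
                               ridge = ridge)
        fu <- fit_axes_matrix(t(Rref)[held, , drop = FALSE],
                              Fref[held, , drop = FALSE], ridge = ridge)
        uu[, s] <- col_cosines(ref$unit, fu$unit)
        uf[, s] <- col_cosines(ref$unit, fits[[nm]]$unit)
        tau_u[s] <- design_tau(Fref[held, , drop = FALSE])
      }
    })
    muu <- rowMeans(uu); muf <- rowMeans(uf)
    keep <- is.finite(muu) & is.finite(muf)
    st <- set_level_test(uu[keep, , drop = FALSE], uf[keep, , drop = FALSE],
                         tau_u = tau_u, tau_f = tau_f)
    R <- window_response(e$tensor, window[1], window[2])
    fam <- e$faces$familiar
    tibble(context = nm,
           mean_uu = mean(muu[keep]), mean_uf = mean(muf[keep]),
           statistic = st$statistic, p_value = st$p_value,
           rate_diff_hz = mean(R[, fam, drop = FALSE]) -
             mean(R[, !fam, drop = FALSE]))
  })
  stab <- col_cosines(fits$A$unit, fits$B$unit)
  list(
    comparison = bind_rows(per_context),
    stability = tibble(cell_id = ref_exp$tensor$cell_ids,
                       cosine = stab),
    mean_stability = mean(stab, na.rm = TRUE)
  )
}
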