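#' Time-resolved statistic with uncertainty, null level and latency
#'
#' A `geometry_trace` is a tibble with columns `time_ms` (window trailing
#' edges, strictly increasing), `value`, `sem`, and where applicable
#' `null_level` and `p_value`, carrying attributes `latency_ms` (a member of
#' `time_ms`, or `NA` when nothing was detected) and `method_tag`.
#'
#' Windows are half-open `[t, t + width)` and labeled by their trailing edge:
#' evidence reported at time `t` can only reflect divergence that had
#' occurred by `t`, which keeps latency estimates onset-consistent (a
#' center-labeled window overlapping an onset would report evidence before
#' the onset).
#'
#' @param df Data frame with at least `time_ms`, `value`, `sem`.
#' @param latency_ms Detected latency (window trailing edge) or `NA`.
#' @param method_tag Short label of the statistic.
#' @param alpha Significance level used for detection, if any.
#' @return A `geometry_trace` tibble.
#' @export
geometry_trace <- function(df, latency_ms = NA_real_, method_tag = "",
                           alpha = NA_real_) {
  df <- as_tibble(df)
  stopifnot(all(c("time_ms", "value") %in% names(df)))
  if (is.unsorted(df$time_ms, strictly = TRUE)) {
    abort("trace times must be strictly increasing",
          class = "facegeom_invalid_argument")
  }
  if (!"sem" %in% names(df)) df$sem <- NA_real_
  if (any(df$sem < 0, na.rm = TRUE)) {
    abort("sem must be nonnegative", class = "facegeom_invalid_argument")
  }
  if (!is.na(latency_ms) && !latency_ms %in% df$time_ms) {
    abort("latency must be one of the trace times",
          class = "facegeom_invalid_argument")
  }
  structure(df, class = c("geometry_trace", class(tibble())),
            latency_ms = latency_ms, method_tag = method_tag, alpha = alpha)
}

#' @export
print.geometry_trace <- function(x, ...) {
  lat <- attr(x, "latency_ms")
  cat(sprintf("<geometry_trace: %s> %d windows, latency %s ms\n",
              attr(x, "method_tag"), nrow(x),
              if (is.na(lat)) "none" else format(lat)))
  NextMethod()
}

#' Detected latency of a trace
#' @param trace A `geometry_trace`.
#' @return Latency in ms, or `NA` if none was detected.
#' @export
latency_ms <- function(trace) attr(trace, "latency_ms")

# rolling half-open windows [start, start+width) covering the span
rolling_windows <- function(t_start, t_end, width_ms, step_ms) {
  starts <- seq(t_start, t_end - width_ms, by = step_ms)
  tibble(t0 = starts, t1 = starts + width_ms, time_ms = starts + width_ms)
}

# first trailing-edge time with `consecutive` p-values below alpha in a row
detect_latency <- function(times, p, alpha, consecutive = 2L) {
  sig <- !is.na(p) & p < alpha
  if (consecutive <= 1L) {
    hit <- which(sig)
  } else {
    run <- sig
    for (k in seq_len(consecutive - 1L)) {
      run <- run & c(sig[-seq_len(k)], rep(FALSE, k))
    }
    hit <- which(run)
  }
  if (length(hit) == 0) NA_real_ else times[hit[1]]
}

# shared engine for latency statistics: per window, per-cell mean rates in
# two conditions, paired t-test across cells
latency_engine <- function(tensor, rates_fun, alternative, baseline = NULL,
                           width_ms = 10, step_ms = 10, alpha = 0.001,
                           consecutive = 2L, method_tag = "latency") {
  if (length(tensor$cell_ids) < 3) {
    abort("need at least 3 cells", class = "facegeom_insufficient_data")
  }
  win <- rolling_windows(tensor$t_start_ms, tensor$t_end_ms, width_ms, step_ms)
  rows <- purrr::pmap(win, function(t0, t1, time_ms) {
    ab <- rates_fun(t0, t1)
    diffs <- ab$a - ab$b
    keep <- is.finite(diffs)
    p <- if (sum(keep) >= 3 && sd(diffs[keep]) > 0) {
      t.test(ab$a[keep], ab$b[keep], paired = TRUE,
             alternative = alternative)$p.value
    } else NA_real_
    tibble(time_ms = time_ms, value = mean(diffs[keep]),
           sem = sd(diffs[keep]) / sqrt(sum(keep)), p_value = p)
  })
  df <- bind_rows(rows)
  lat <- detect_latency(df$time_ms, df$p_value, alpha, consecutive)
  geometry_trace(df, latency_ms = lat, method_tag = method_tag, alpha = alpha)
}

#' Visual response latency
#'
#' Rolling-window one-tailed paired t-test, across cells, of window firing
#' rate against each cell's baseline rate. The latency is the trailing edge
#' of the first of `consecutive` consecutive windows with `p < alpha`.
#'
#' @param tensor A `response_tensor`.
#' @param baseline_window Length-2 window (ms) preceding stimulus onset.
#' @param width_ms,step_ms Rolling-window width and step, ms.
#' @param alpha Significance level.
#' @param consecutive Required run length of significant windows.
#' @return A `geometry_trace` of rate-above-baseline (Hz) with p-values.
#' @export
response_latency <- function(tensor, baseline_window = c(-50, 0),
                             width_ms = 10, step_ms = 10,
                             alpha = 0.001, consecutive = 2L) {
  if (baseline_window[2] > 0) {
    abort("baseline window must precede stimulus onset",
          class = "facegeom_invalid_argument")
  }
  base <- rowMeans(window_response(tensor, baseline_window[1], baseline_window[2]),
                   na.rm = TRUE)
  latency_engine(
    tensor,
    rates_fun = function(t0, t1) {
      list(a = rowMeans(window_response(tensor, t0, t1), na.rm = TRUE), b = base)
    },
    alternative = "greater",
    width_ms = width_ms, step_ms = step_ms, alpha = alpha,
    consecutive = consecutive, method_tag = "response_latency"
  )
}

#' Familiar-vs-unfamiliar divergence latency
#'
#' As [response_latency()] but comparing, per cell, the mean rate over
#' familiar faces against the mean over unfamiliar faces (two-tailed paired
#' t-test across cells).
#'
#' @param tensor A `response_tensor`.
#' @param familiar Logical vector over faces (or a `face_set`).
#' @inheritParams response_latency
#' @return A `geometry_trace` of the familiar-minus-unfamiliar rate (Hz).
#' @export
divergence_latency <- function(tensor, familiar, width_ms = 10, step_ms = 10,
                               alpha = 0.001, consecutive = 2L) {
  familiar <- familiar_flags(tensor, familiar)
  latency_engine(
    tensor,
    rates_fun = function(t0, t1) {
      r <- window_response(tensor, t0, t1)
      list(a = rowMeans(r[, familiar, drop = FALSE], na.rm = TRUE),
           b = rowMeans(r[, !familiar, drop = FALSE], na.rm = TRUE))
    },
    alternative = "two.sided",
    width_ms = width_ms, step_ms = step_ms, alpha = alpha,
    consecutive = consecutive, method_tag = "divergence_latency"
  )
}

familiar_flags <- function(tensor, familiar) {
  if (inherits(familiar, "face_set") || is.data.frame(familiar)) {
    familiar <- familiar$familiar[match(tensor$face_ids, familiar$face_id)]
  }
  if (length(familiar) != length(tensor$face_ids) || anyNA(familiar)) {
    abort("familiarity labels do not match the tensor's faces",
          class = "facegeom_invalid_argument")
  }
  as.logical(familiar)
}

#' Plot a geometry trace
#'
#' @param object A `geometry_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.geometry_trace <- function(object, ...) {
  lat <- attr(object, "latency_ms")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sem,
                                      ymax = .data$value + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = attr(object, "method_tag"))
  if ("null_level" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$null_level),
                                linetype = "dashed", colour = "grey40")
  }
  if (!is.na(lat)) {
    p <- p + ggplot2::geom_vline(xintercept = lat, linetype = "dotted",
                                 colour = "red")
  }
  p
}
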