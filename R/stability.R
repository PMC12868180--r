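#' Detect the stability point of a metric curve
#'
#' The stability point is the earliest curve point after which the curve
#' stays within `tolerance` of its final value: the smallest support point
#' i such that every defined point j >= i satisfies
#' `|value(j) - value(last)| < tolerance`. The tolerance is absolute, in
#' percentage points on the metric's own percent scale. The point must
#' precede the last point (a curve that only "stabilises" at its final
#' value has no stability point), the final value must be defined, and any
#' undefined value in the qualifying tail vetoes the candidate (an
#' empty-sweet-spot tail is evidence of instability, not stability).
#'
#' @param n_pat Increasing integer support of the curve.
#' @param value Metric values (percent); `NA` marks undefined points.
#' @param tolerance Stability tolerance in percentage points (default 5).
#' @return The stability point as an element of `n_pat`, or
#'   `NA_integer_` ("not existing").
#' @examples
#' find_stability_point(seq(4, 14, 2), c(40, 20, 10, 6, 5, 4)) # 10
#' @export
find_stability_point <- function(n_pat, value, tolerance = 5) {
  stopifnot(length(n_pat) == length(value), !is.unsorted(n_pat))
  k <- length(value)
  if (sum(!is.na(value)) < 2L) {
    warn("fewer than 2 defined curve points; no stability point")
    return(NA_integer_)
  }
  final <- value[k]
  if (is.na(final)) return(NA_integer_)
  ok <- rep(FALSE, k)
  all_within <- TRUE
  for (i in rev(seq_len(k))) {
    if (is.na(value[i])) all_within <- FALSE # undefined tail vetoes
    else all_within <- all_within && abs(value[i] - final) < tolerance
    ok[i] <- all_within
  }
  cand <- which(ok[-k]) # must precede the final point
  if (length(cand) == 0L) NA_integer_ else as.integer(n_pat[min(cand)])
}

#' Stability points for every curve in a set
#'
#' @param curves A `metric_curves` tibble (see
#'   [successive_comparisons()]).
#' @param tolerance Stability tolerance in percentage points (default 5).
#' @return Tibble with columns `method`, `metric`, `n_stim`,
#'   `n_pat_stable` (`NA` = not existing).
#' @export
stability_points <- function(curves, tolerance = 5) {
  curves |>
    dplyr::group_by(.data$method, .data$metric, .data$n_stim) |>
    dplyr::arrange(.data$n_pat, .by_group = TRUE) |>
    dplyr::summarise(
      n_pat_stable = suppressWarnings(
        find_stability_point(.data$n_pat, .data$mean, tolerance)
      ),
      .groups = "drop"
    )
}

#' Binary stability records for boundary modelling
#'
#' One record per curve support point: label 1 when `n_pat` is at or past
#' the curve's stability point, 0 otherwise (all 0 when the stability
#' point does not exist). `total_stims = n_pat * n_stim` is the summary
#' feature for the boundary model.
#'
#' @param points Output of [stability_points()].
#' @param curves The `metric_curves` the points were detected on.
#' @return Tibble of class `stability_records` with columns `method`,
#'   `metric`, `n_pat`, `n_stim`, `total_stims`, `label`.
#' @export
build_stability_dataset <- function(points, curves) {
  out <- curves |>
    dplyr::select("method", "metric", "n_stim", "n_pat") |>
    dplyr::left_join(points, by = c("method", "metric", "n_stim")) |>
    dplyr::mutate(
      total_stims = .data$n_pat * .data$n_stim,
      label = as.integer(!is.na(.data$n_pat_stable) &
                           .data$n_pat >= .data$n_pat_stable)
    ) |>
    dplyr::select("method", "metric", "n_pat", "n_stim", "total_stims",
                  "label")
  class(out) <- c("stability_records", class(out))
  out
}

#' Pool stability records across metrics
#'
#' Concatenates per-metric record sets of one statistical method,
#' retaining metric provenance, for training the aggregated-metrics
#' boundary model.
#'
#' @param ... `stability_records` tibbles (or a single list of them)
#'   sharing the same method.
#' @return A pooled `stability_records` tibble.
#' @export
assemble_all_metrics <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "data.frame")) {
    parts <- parts[[1]]
  }
  out <- dplyr::bind_rows(parts)
  if (length(unique(out$method)) > 1L) {
    abort("records to pool must share one statistical method")
  }
  class(out) <- unique(c("stability_records", class(out)))
  out
}
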