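#' Geometric descriptors of a sweet-spot volume
#'
#' `volume_mm3()` is voxel count times voxel volume (0 when empty).
#' `centroid_mm()` is the unweighted mean of the member voxel-center world
#' coordinates (`NA` triple when empty). `diameter_mm()` is the
#' equivalent-sphere diameter `(6 V / pi)^(1/3)`, a rotation-invariant
#' notion of "largest diameter" that is stable for ragged voxel sets; set
#' `type = "feret"` for the maximal voxel-center extent instead.
#'
#' @param pss A `pss_volume`.
#' @param type For `diameter_mm()`: `"equivalent_sphere"` (default) or
#'   `"feret"`.
#' @return `volume_mm3()` and `diameter_mm()` a scalar; `centroid_mm()` a
#'   length-3 numeric vector.
#' @name pss-geometry
NULL

#' @rdname pss-geometry
#' @export
volume_mm3 <- function(pss) length(pss$mask) * voxel_volume(pss$grid)

#' @rdname pss-geometry
#' @export
centroid_mm <- function(pss) {
  if (length(pss$mask) == 0L) {
    warn("empty volume has no centroid")
    return(rep(NA_real_, 3))
  }
  colMeans(voxel_centers(pss$grid, pss$mask))
}

#' @rdname pss-geometry
#' @export
diameter_mm <- function(pss, type = c("equivalent_sphere", "feret")) {
  type <- match.arg(type)
  if (length(pss$mask) == 0L) return(NA_real_)
  if (type == "equivalent_sphere") {
    (6 * volume_mm3(pss) / pi)^(1 / 3)
  } else {
    xyz <- voxel_centers(pss$grid, pss$mask)
    if (nrow(xyz) == 1L) return(0)
    max(stats::dist(xyz))
  }
}

#' Pairwise geometric variability metrics between two sweet spots
#'
#' All three pairwise metrics are expressed in percent and are symmetric
#' in their arguments. Undefined values are returned as `NA` (never an
#' arbitrary number).
#'
#' * `vol_diff()`: volume difference normalized by the largest volume in
#'   the pair, `100 |Va - Vb| / max(Va, Vb)`. Both empty: 0; exactly one
#'   empty: 100.
#' * `dice_coef()`: `100 * 2|A n B| / (|A| + |B|)`. Both empty: `NA`; one
#'   empty: 0.
#' * `centroid_dist()`: centroid distance normalized by the largest
#'   diameter in the pair, `100 ||ca - cb|| / max(da, db)`; may exceed
#'   100. `NA` if either volume is empty.
#'
#' @param a,b `pss_volume` objects on the same grid.
#' @param diameter_type Passed to [diameter_mm()] for `centroid_dist()`.
#' @return Scalar percent value (or `NA` when undefined).
#' @name pss-metrics
NULL

#' @rdname pss-metrics
#' @export
vol_diff <- function(a, b) {
  va <- volume_mm3(a); vb <- volume_mm3(b)
  if (va == 0 && vb == 0) return(0)
  100 * abs(va - vb) / max(va, vb)
}

#' @rdname pss-metrics
#' @export
dice_coef <- function(a, b) {
  na <- length(a$mask); nb <- length(b$mask)
  if (na == 0L && nb == 0L) return(NA_real_)
  100 * 2 * length(intersect(a$mask, b$mask)) / (na + nb)
}

#' @rdname pss-metrics
#' @export
centroid_dist <- function(a, b, diameter_type = "equivalent_sphere") {
  if (length(a$mask) == 0L || length(b$mask) == 0L) return(NA_real_)
  d <- sqrt(sum((centroid_mm(a) - centroid_mm(b))^2))
  100 * d / max(diameter_mm(a, diameter_type), diameter_mm(b, diameter_type))
}

pairwise_metrics <- function(a, b) {
  c(vol_diff = vol_diff(a, b), dice = dice_coef(a, b),
    centr_dist = centroid_dist(a, b))
}

#' Metric curves from successive-size sweet-spot comparisons
#'
#' For each statistical method, stimulation count and patient chain, every
#' pair of successive dataset sizes (e.g. 4 vs 6 patients, 6 vs 8, and the
#' largest subgroup vs the full cohort) is compared across all
#' stimulation-sampling replicates (`n_stim_reps^2` cross pairs). Pair
#' values are averaged within a chain, then across chains, yielding one
#' curve per (method, metric, nStim) indexed at the larger size of each
#' pair. Undefined pair values (see [dice_coef()]) are dropped from the
#' averages; a point where no pair is defined has `mean = NA`.
#'
#' @param pss_tbl Tibble with columns `method`, `chain` (integer, or `NA`
#'   for the shared full-cohort datasets), `n_pat`, `n_stim`, `stim_rep`
#'   and a list column `pss` of `pss_volume` objects, as produced by
#'   [compute_pss_grid()].
#' @return A tibble of class `metric_curves` with columns `method`,
#'   `metric`, `n_stim`, `n_pat`, `mean`, `sd` (across chains), `n_chains`
#'   and `n_pairs` (defined cross pairs contributing).
#' @export
successive_comparisons <- function(pss_tbl) {
  chains <- sort(unique(pss_tbl$chain[!is.na(pss_tbl$chain)]))
  sizes_sub <- sort(unique(pss_tbl$n_pat[!is.na(pss_tbl$chain)]))
  full_size <- unique(pss_tbl$n_pat[is.na(pss_tbl$chain)])
  sizes <- c(sizes_sub, full_size)
  rows <- list()
  for (m in unique(pss_tbl$method)) {
    for (ns in sort(unique(pss_tbl$n_stim))) {
      sub <- pss_tbl[pss_tbl$method == m & pss_tbl$n_stim == ns, ]
      for (ch in chains) {
        for (s_i in seq_len(length(sizes) - 1L)) {
          s_small <- sizes[s_i]; s_large <- sizes[s_i + 1L]
          pa <- sub[!is.na(sub$chain) & sub$chain == ch & sub$n_pat == s_small, ]
          pb <- if (s_large %in% sizes_sub) {
            sub[!is.na(sub$chain) & sub$chain == ch & sub$n_pat == s_large, ]
          } else {
            sub[is.na(sub$chain) & sub$n_pat == s_large, ]
          }
          if (nrow(pa) == 0L || nrow(pb) == 0L) next
          vals <- purrr::map(seq_len(nrow(pa)), function(i) {
            purrr::map(seq_len(nrow(pb)), function(j) {
              pairwise_metrics(pa$pss[[i]], pb$pss[[j]])
            })
          })
          vals <- do.call(rbind, unlist(vals, recursive = FALSE))
          rows[[length(rows) + 1L]] <- tibble(
            method = m, n_stim = ns, chain = ch, n_pat = s_large,
            metric = colnames(vals),
            value = colMeans(vals, na.rm = TRUE),
            n_pairs = colSums(!is.na(vals))
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value)) |>
    dplyr::group_by(.data$method, .data$metric, .data$n_stim, .data$n_pat) |>
    dplyr::summarise(
      mean = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE)
             else NA_real_,
      sd = stats::sd(.data$value[!is.na(.data$value)]),
      n_chains = sum(!is.na(.data$value)),
      n_pairs = sum(.data$n_pairs),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$method, .data$metric, .data$n_stim, .data$n_pat)
  class(out) <- c("metric_curves", class(out))
  out
}

#' Combined geometric-variability metric
#'
#' Point-wise unweighted mean of the `vol_diff`, `dice` and `centr_dist`
#' curves (`m_comb`). A point where any component is undefined is
#' undefined.
#'
#' @param curves A `metric_curves` tibble containing the three component
#'   metrics.
#' @return A `metric_curves` tibble with `metric = "m_comb"` rows.
#' @export
combined_metric <- function(curves) {
  out <- curves |>
    dplyr::filter(.data$metric %in% c("vol_diff", "dice", "centr_dist")) |>
    dplyr::group_by(.data$method, .data$n_stim, .data$n_pat) |>
    dplyr::summarise(
      mean = if (dplyr::n() == 3L && !any(is.na(.data$mean)))
               mean(.data$mean) else NA_real_,
      sd = NA_real_,
      n_chains = min(.data$n_chains),
      n_pairs = min(.data$n_pairs),
      .groups = "drop"
    ) |>
    dplyr::mutate(metric = "m_comb", .after = "method")
  class(out) <- c("metric_curves", class(out))
  out
}
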