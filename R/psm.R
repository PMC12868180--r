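#' Configure the voxel-wise statistical mapping
#'
#' @param method One of `"BAYES"`, `"WFDR"`, `"WPERM"`.
#' @param improvement_threshold Threshold `theta` in percent tested
#'   against (H0: improvement < theta, H1: improvement >= theta); 50 is a
#'   typical rigidity threshold, 75 a typical tremor threshold.
#' @param alpha Significance level for corrected p-values (default 0.05).
#' @param n_permutations Number of permutations for WPERM (default 200).
#' @param bf_threshold Bayes-factor threshold for BAYES (default 10).
#' @param prior Prior for BAYES: list with `mu0` (default
#'   `improvement_threshold`, making the prior odds 1), `tau` (default
#'   25), `sigma_scale` (default 25), optional `sigma_fixed`.
#' @param mcmc List with `num_samples` (2000) and `warmup_steps` (1000).
#' @param min_observations Minimum per-voxel sample size for a voxel to be
#'   tested (default 5; for the Wilcoxon methods this counts non-zero
#'   differences).
#' @param connectivity Cluster connectivity: 6, 18 or 26 (default 6).
#' @param min_cluster_volume Minimum surviving cluster volume in mm^3
#'   (default 1; clusters strictly smaller are removed).
#' @param min_patient_frac Occurrence filter: minimum fraction of patients
#'   stimulating a voxel (default 0.25).
#' @param min_stim_frac Occurrence filter: minimum stimulation count as a
#'   fraction of the maximum nMap value (default 0.10).
#' @param seed Integer seed for the stochastic methods.
#' @return A list of class `test_config`.
#' @export
test_config <- function(method = c("BAYES", "WFDR", "WPERM"),
                        improvement_threshold = 50,
                        alpha = 0.05,
                        n_permutations = 200L,
                        bf_threshold = 10,
                        prior = NULL,
                        mcmc = list(num_samples = 2000L, warmup_steps = 1000L),
                        min_observations = 5L,
                        connectivity = 6L,
                        min_cluster_volume = 1,
                        min_patient_frac = 0.25,
                        min_stim_frac = 0.10,
                        seed = 1L) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (improvement_threshold <= 0 || improvement_threshold >= 100) {
    abort("`improvement_threshold` must lie in (0, 100)")
  }
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  if (bf_threshold <= 1) abort("`bf_threshold` must be > 1")
  prior <- utils::modifyList(
    list(mu0 = improvement_threshold, tau = 25, sigma_scale = 25),
    prior %||% list()
  )
  structure(
    list(method = method, improvement_threshold = improvement_threshold,
         alpha = alpha, n_permutations = as.integer(n_permutations),
         bf_threshold = bf_threshold, prior = prior, mcmc = mcmc,
         min_observations = as.integer(min_observations),
         connectivity = as.integer(connectivity),
         min_cluster_volume = min_cluster_volume,
         min_patient_frac = min_patient_frac,
         min_stim_frac = min_stim_frac, seed = as.integer(seed)),
    class = "test_config"
  )
}

#' Stimulation and patient occurrence maps
#'
#' `nMap` counts, per voxel, the stimulations whose VTA covers it; `nPatMap`
#' counts the distinct patients with at least one covering stimulation.
#'
#' @param dataset A `stim_dataset`.
#' @return List of class `occurrence_maps` with integer vectors `nmap` and
#'   `npatmap` over all grid voxels, plus the `grid`.
#' @export
compute_occurrence_maps <- function(dataset) {
  nv <- n_voxels_total(dataset$grid)
  nmap <- tabulate(unlist(dataset$stims$mask), nbins = nv)
  pat_vox <- dataset$stims |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_map(~ unique(unlist(.x$mask)))
  npatmap <- tabulate(unlist(pat_vox), nbins = nv)
  structure(list(nmap = nmap, npatmap = npatmap, grid = dataset$grid),
            class = "occurrence_maps")
}

# coverage: named list voxel index -> integer vector of stimulation rows
voxel_coverage <- function(dataset) {
  masks <- dataset$stims$mask
  all_idx <- unlist(masks)
  stim_of <- rep.int(seq_along(masks), lengths(masks))
  split(stim_of, all_idx)
}

#' Improvement scores of the stimulations covering a voxel
#'
#' @param dataset A `stim_dataset`.
#' @param voxel Linear voxel index (1-based) on the dataset grid.
#' @return Numeric vector of scores in stimulation-table order (empty if
#'   the voxel is uncovered).
#' @export
voxel_scores <- function(dataset, voxel) {
  if (voxel < 1 || voxel > n_voxels_total(dataset$grid)) {
    abort("`voxel` outside the grid")
  }
  covered <- vapply(dataset$stims$mask, function(m) voxel %in% m, logical(1))
  dataset$stims$score[covered]
}

# tested-voxel family: voxels whose per-voxel sample passes min_observations
# (Wilcoxon methods count non-zero differences from theta)
tested_voxels <- function(dataset, coverage, config) {
  scores <- dataset$stims$score
  n_eff <- if (config$method == "BAYES") {
    lengths(coverage)
  } else {
    vapply(coverage, function(s) sum(scores[s] != config$improvement_threshold),
           integer(1))
  }
  as.integer(names(coverage))[n_eff >= config$min_observations]
}

new_stat_map <- function(grid, voxels, statistic, method, significant,
                         extra = list()) {
  structure(
    c(list(grid = grid, voxels = voxels, statistic = statistic,
           method = method, significant = significant), extra),
    class = "voxel_stat_map"
  )
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat("<voxel_stat_map> ", x$method, ": ", length(x$voxels),
      " tested voxels, ", sum(x$significant), " significant\n", sep = "")
  invisible(x)
}

#' Voxel-wise Wilcoxon test with Benjamini-Hochberg FDR correction
#'
#' Computes a raw one-sided signed-rank p-value per tested voxel and
#' applies the BH step-up over the family of tested voxels; a voxel is
#' significant when its corrected p-value is below `config$alpha`.
#'
#' @param dataset A `stim_dataset`.
#' @param config A [test_config()] with `method = "WFDR"`.
#' @return A `voxel_stat_map` whose `statistic` holds the BH-corrected
#'   p-values (raw p-values in `$raw_p`).
#' @export
psm_wfdr <- function(dataset, config) {
  stopifnot(config$method == "WFDR")
  cov <- voxel_coverage(dataset)
  vox <- tested_voxels(dataset, cov, config)
  scores <- dataset$stims$score
  theta <- config$improvement_threshold
  raw <- vapply(as.character(vox),
                function(v) wilcoxon_one_sided(scores[cov[[v]]], theta),
                numeric(1), USE.NAMES = FALSE)
  adj <- p.adjust(raw, method = "BH")
  new_stat_map(dataset$grid, vox, adj, "WFDR", adj < config$alpha,
               extra = list(raw_p = raw))
}

#' Voxel-wise Wilcoxon test with permutation-based family-wise correction
#'
#' Improvement scores are shuffled across all stimulations (masks fixed)
#' and the standardized signed-rank statistic recomputed per voxel. The
#' corrected p-value of a voxel is the proportion of permutations --
#' including the observed arrangement -- whose family-maximum statistic is
#' at least the voxel's observed statistic (max-statistic family-wise
#' correction).
#'
#' @param dataset A `stim_dataset`.
#' @param config A [test_config()] with `method = "WPERM"`.
#' @return A `voxel_stat_map` whose `statistic` holds the corrected
#'   p-values (observed z statistics in `$z_obs`).
#' @export
psm_wperm <- function(dataset, config) {
  stopifnot(config$method == "WPERM")
  cov <- voxel_coverage(dataset)
  vox <- tested_voxels(dataset, cov, config)
  scores <- dataset$stims$score
  theta <- config$improvement_threshold
  cov_t <- cov[as.character(vox)]
  z_of <- function(s) vapply(cov_t, function(ix) signed_rank_z(s[ix], theta),
                             numeric(1), USE.NAMES = FALSE)
  z_obs <- z_of(scores)
  if (length(vox) == 0L) {
    return(new_stat_map(dataset$grid, vox, numeric(0), "WPERM", logical(0),
                        extra = list(z_obs = z_obs)))
  }
  B <- config$n_permutations
  max_z <- withr::with_seed(config$seed, {
    vapply(seq_len(B), function(b) max(z_of(sample(scores))), numeric(1))
  })
  p_corr <- vapply(z_obs, function(z) (1 + sum(max_z >= z)) / (B + 1),
                   numeric(1))
  new_stat_map(dataset$grid, vox, p_corr, "WPERM", p_corr < config$alpha,
               extra = list(z_obs = z_obs))
}

#' Voxel-wise directional Bayesian one-sample test
#'
#' Samples the posterior of the mean improvement at every tested voxel
#' (see [bayes_posterior()]; chains are run vectorised across voxels) and
#' converts the posterior mass above `theta` into a directional Bayes
#' factor (see [bayes_factor_directional()]). A voxel is significant when
#' `BF >= config$bf_threshold`. Voxels whose sampler returns non-finite
#' draws are flagged and treated as not significant.
#'
#' @param dataset A `stim_dataset`.
#' @param config A [test_config()] with `method = "BAYES"`.
#' @return A `voxel_stat_map` whose `statistic` holds the Bayes factors
#'   (posterior means in `$posterior_mean`).
#' @export
psm_bayes <- function(dataset, config) {
  stopifnot(config$method == "BAYES")
  cov <- voxel_coverage(dataset)
  vox <- tested_voxels(dataset, cov, config)
  scores <- dataset$stims$score
  theta <- config$improvement_threshold
  if (length(vox) == 0L) {
    return(new_stat_map(dataset$grid, vox, numeric(0), "BAYES", logical(0)))
  }
  cov_t <- cov[as.character(vox)]
  n <- lengths(cov_t)
  sum_x <- vapply(cov_t, function(ix) sum(scores[ix]), numeric(1))
  sum_x2 <- vapply(cov_t, function(ix) sum(scores[ix]^2), numeric(1))
  res <- withr::with_seed(config$seed, {
    bayes_sample_batch(n, sum_x, sum_x2, config$prior, config$mcmc,
                       theta = theta)
  })
  prior_ge <- pnorm(theta, config$prior$mu0, config$prior$tau,
                    lower.tail = FALSE)
  bf <- bf_from_counts(res$count_ge, res$num, prior_ge)
  ok <- is.finite(bf) & is.finite(res$mean_mu)
  new_stat_map(dataset$grid, vox, bf, "BAYES",
               ok & bf >= config$bf_threshold,
               extra = list(posterior_mean = res$mean_mu))
}

#' Occurrence filters on a significance mask
#'
#' Keeps a voxel only if it is significant AND was stimulated in at least
#' `min_patient_frac` of the patients AND its stimulation count is at
#' least `min_stim_frac` of the maximum nMap value. Comparisons use `>=`
#' on the exact fractional thresholds.
#'
#' @param mask Integer voxel indices of the significant voxels.
#' @param occ An `occurrence_maps` object.
#' @param n_pat Number of patients in the dataset.
#' @param min_patient_frac,min_stim_frac Filter fractions (defaults 0.25
#'   and 0.10).
#' @return Filtered integer voxel indices (subset of `mask`).
#' @export
apply_occurrence_filters <- function(mask, occ, n_pat,
                                     min_patient_frac = 0.25,
                                     min_stim_frac = 0.10) {
  if (length(mask) == 0L) return(integer(0))
  keep <- occ$npatmap[mask] >= min_patient_frac * n_pat &
    occ$nmap[mask] >= min_stim_frac * max(occ$nmap)
  mask[keep]
}

#' Remove clusters below a minimum volume
#'
#' Labels connected components of the mask (6-, 18- or 26-connectivity)
#' and removes components whose volume is strictly below
#' `min_volume` mm^3.
#'
#' @param mask Integer voxel indices.
#' @param grid The [voxel_grid()] the mask lives on.
#' @param min_volume Minimum cluster volume in mm^3 (default 1).
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full).
#' @return Filtered integer voxel indices.
#' @export
remove_small_clusters <- function(mask, grid, min_volume = 1,
                                  connectivity = 6L) {
  if (length(mask) == 0L) return(integer(0))
  comp <- cluster_labels(mask, grid, connectivity)
  sizes <- tabulate(comp)
  keep <- sizes[comp] * voxel_volume(grid) >= min_volume
  mask[keep]
}

# component label per mask voxel via igraph on the voxel adjacency graph
cluster_labels <- function(mask, grid, connectivity = 6L) {
  offsets <- switch(as.character(connectivity),
    "6" = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    "18" = , "26" = {
      all_off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      all_off <- all_off[rowSums(abs(all_off)) > 0, , drop = FALSE]
      if (connectivity == 18L) {
        all_off <- all_off[rowSums(abs(all_off)) <= 2, , drop = FALSE]
      }
      # keep one direction per pair (first nonzero positive)
      first_nz <- apply(all_off, 1, function(o) o[which(o != 0)[1]])
      all_off[first_nz > 0, , drop = FALSE]
    },
    abort("`connectivity` must be 6, 18 or 26")
  )
  ijk <- linear_to_ijk(grid, mask)
  pos <- match(mask, mask) # identity; mask assumed unique
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(ijk, 2, offsets[r, ], `+`)
    ok <- nb[, 1] >= 0 & nb[, 1] < grid$shape[1] &
      nb[, 2] >= 0 & nb[, 2] < grid$shape[2] &
      nb[, 3] >= 0 & nb[, 3] < grid$shape[3]
    nb_lin <- ijk_to_linear(grid, nb[ok, , drop = FALSE])
    hit <- match(nb_lin, mask)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    if (length(src)) edges[[length(edges) + 1L]] <- cbind(src, dst)
  }
  if (length(edges) == 0L) return(seq_along(mask))
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(mask) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(mask)]
}

#' Extract the probabilistic sweet spot of a dataset
#'
#' Runs the full mapping workflow: occurrence maps, the configured
#' voxel-wise test (BAYES / WFDR / WPERM), significance thresholding
#' (corrected p < alpha, or BF >= threshold), the patient/stimulation
#' occurrence filters, and small-cluster removal.
#'
#' @param dataset A `stim_dataset`.
#' @param config A [test_config()].
#' @return A `pss_volume`: list with `grid`, sorted voxel `mask` indices,
#'   `method`, `volume` (mm^3), `centroid` (mm, `NULL` when empty), and a
#'   `provenance` list with per-stage voxel counts and settings.
#' @export
extract_pss <- function(dataset, config) {
  occ <- compute_occurrence_maps(dataset)
  stat_map <- switch(config$method,
    WFDR = psm_wfdr(dataset, config),
    WPERM = psm_wperm(dataset, config),
    BAYES = psm_bayes(dataset, config)
  )
  sig <- stat_map$voxels[stat_map$significant]
  filt <- apply_occurrence_filters(sig, occ, n_patients(dataset),
                                   config$min_patient_frac,
                                   config$min_stim_frac)
  final <- remove_small_clusters(filt, dataset$grid,
                                 config$min_cluster_volume,
                                 config$connectivity)
  new_pss_volume(
    sort(final), dataset$grid, config$method,
    provenance = list(
      n_pat = n_patients(dataset), n_stims = nrow(dataset$stims),
      theta = config$improvement_threshold, seed = config$seed,
      n_tested = length(stat_map$voxels), n_significant = length(sig),
      n_after_occurrence = length(filt), n_final = length(final)
    )
  )
}

new_pss_volume <- function(mask, grid, method, provenance = list()) {
  mask <- as.integer(mask)
  structure(
    list(mask = mask, grid = grid, method = method,
         volume = length(mask) * voxel_volume(grid),
         centroid = if (length(mask)) colMeans(voxel_centers(grid, mask)),
         provenance = provenance),
    class = "pss_volume"
  )
}

#' Construct a sweet-spot volume from voxel indices
#'
#' Mostly useful for tests and for importing masks computed elsewhere.
#'
#' @param mask Integer linear voxel indices.
#' @param grid The [voxel_grid()].
#' @param method Optional method tag.
#' @return A `pss_volume`.
#' @export
pss_volume <- function(mask, grid, method = "manual") {
  new_pss_volume(sort(unique(as.integer(mask))), grid, method)
}

#' @export
print.pss_volume <- function(x, ...) {
  cat("<pss_volume> ", x$method, ": ", length(x$mask), " voxels, ",
      signif(x$volume, 5), " mm^3", sep = "")
  if (!is.null(x$centroid)) {
    cat(", centroid (", paste(signif(x$centroid, 4), collapse = ", "), ") mm",
        sep = "")
  }
  cat("\n")
  invisible(x)
}
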