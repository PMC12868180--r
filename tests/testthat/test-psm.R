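test_that("occurrence maps count stimulations and distinct patients", {
  g <- tiny_grid(4)
  v <- function(...) pssmapr:::ijk_to_linear(g, rbind(c(...)))
  ds <- manual_dataset(
    g,
    masks = list(c(v(0, 0, 0), v(1, 0, 0)), c(v(0, 0, 0)), c(v(2, 2, 2))),
    scores = c(50, 75, 100),
    patients = c("A", "A", "B")
  )
  occ <- compute_occurrence_maps(ds)
  expect_equal(occ$nmap[v(0, 0, 0)], 2) # two stimulations of one patient
  expect_equal(occ$npatmap[v(0, 0, 0)], 1)
  expect_equal(occ$nmap[v(2, 2, 2)], 1)
  expect_equal(occ$npatmap[v(2, 2, 2)], 1)
  expect_true(all(occ$npatmap <= occ$nmap))
})

test_that("occurrence maps equal a brute-force double loop", {
  ds <- strong_signal_cohort(n_patients = 5, seed = 13, noise_sd = 10,
                             grid_n = 16)
  occ <- compute_occurrence_maps(ds)
  nv <- prod(ds$grid$shape)
  nmap_bf <- integer(nv)
  npat_bf <- integer(nv)
  for (v in seq_len(nv)) {
    covering <- vapply(ds$stims$mask, function(m) v %in% m, logical(1))
    nmap_bf[v] <- sum(covering)
    npat_bf[v] <- length(unique(ds$stims$patient_id[covering]))
  }
  expect_identical(occ$nmap, nmap_bf)
  expect_identical(occ$npatmap, npat_bf)
})

test_that("voxel score assembly is order-stable and conserves mass", {
  g <- tiny_grid(4)
  v <- pssmapr:::ijk_to_linear(g, rbind(c(1, 1, 1)))
  ds <- manual_dataset(
    g,
    masks = list(v, v, v, v + 1L),
    scores = c(25, 50, 100, 75)
  )
  expect_equal(voxel_scores(ds, v), c(25, 50, 100))
  expect_equal(voxel_scores(ds, pssmapr:::ijk_to_linear(g, rbind(c(3, 3, 3)))),
               numeric(0))
  # conservation: sum of per-voxel list lengths = sum of mask sizes
  cov <- pssmapr:::voxel_coverage(ds)
  expect_equal(sum(lengths(cov)), sum(lengths(ds$stims$mask)))
})

test_that("BH correction matches the hand step-up and a reference", {
  g <- tiny_grid(6)
  # three voxels with p = .01, .02, .04 at m = 3 -> all significant at .05
  vox <- pssmapr:::ijk_to_linear(g, rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)))
  # craft per-voxel scores giving distinct raw p (5 obs each, no zeros)
  expect_equal(bh_adjust_reference(c(0.01, 0.02, 0.04)),
               p.adjust(c(0.01, 0.02, 0.04), "BH"))
  expect_true(all(p.adjust(c(0.01, 0.02, 0.04), "BH") < 0.05))
  # oracle equivalence on 1000 random p-values
  withr::with_seed(31, {
    p <- runif(1000)^1.5
  })
  expect_equal(p.adjust(p, "BH"), bh_adjust_reference(p), tolerance = 1e-12)
})

test_that("WFDR maps raw p through BH over the tested family", {
  ds <- strong_signal_cohort(n_patients = 8, seed = 17, noise_sd = 10,
                             grid_n = 16)
  cfg <- test_config("WFDR")
  map <- psm_wfdr(ds, cfg)
  expect_equal(map$statistic, bh_adjust_reference(map$raw_p),
               tolerance = 1e-12)
  expect_identical(map$significant, map$statistic < cfg$alpha)
  # all scores zero -> every raw p is 1 -> nothing significant
  ds0 <- ds
  ds0$stims$score <- rep(0, nrow(ds0$stims))
  map0 <- psm_wfdr(ds0, cfg)
  expect_false(any(map0$significant))
})

test_that("single tested voxel: WFDR equals raw-p thresholding", {
  g <- tiny_grid(4)
  v <- pssmapr:::ijk_to_linear(g, rbind(c(1, 1, 1)))
  ds <- manual_dataset(g, masks = rep(list(v), 6),
                       scores = c(75, 87.5, 100, 75, 62.5, 87.5))
  cfg <- test_config("WFDR")
  map <- psm_wfdr(ds, cfg)
  expect_length(map$voxels, 1L)
  expect_equal(map$statistic, wilcoxon_one_sided(ds$stims$score, 50))
})

test_that("WPERM corrected p agrees with exhaustive permutation enumeration", {
  g <- tiny_grid(4)
  v <- function(...) pssmapr:::ijk_to_linear(g, rbind(c(...)))
  vox <- c(v(0, 0, 0), v(1, 1, 1), v(2, 2, 2))
  # 6 stimulations; each covers a different subset of the 3 voxels
  masks <- list(
    vox[c(1, 2)], vox[c(1, 2, 3)], vox[c(1, 3)],
    vox[c(1, 2, 3)], vox[c(2, 3)], vox[c(1, 2, 3)]
  )
  scores <- c(100, 87.5, 25, 75, 62.5, 100)
  ds <- manual_dataset(g, masks, scores)
  cfg <- test_config("WPERM", n_permutations = 9999,
                     min_observations = 4L, seed = 3)
  map <- psm_wperm(ds, cfg)

  # exhaustive oracle over all 6! orderings
  theta <- 50
  cov <- lapply(vox, function(vv) which(vapply(masks, function(m) vv %in% m,
                                               logical(1))))
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  z_obs <- vapply(cov, function(ix) pssmapr:::signed_rank_z(scores[ix], theta),
                  numeric(1))
  max_z <- apply(perms, 1, function(ord) {
    s <- scores[ord]
    max(vapply(cov, function(ix) pssmapr:::signed_rank_z(s[ix], theta),
               numeric(1)))
  })
  p_exact <- vapply(z_obs, function(z) mean(max_z >= z), numeric(1))
  ord <- match(map$voxels, vox)
  se <- sqrt(p_exact * (1 - p_exact) / cfg$n_permutations)
  expect_true(all(abs(map$statistic[order(ord)] - p_exact) <= 3 * se + 1e-9))
})

test_that("WPERM degenerate cases", {
  g <- tiny_grid(4)
  v <- pssmapr:::ijk_to_linear(g, rbind(c(1, 1, 1)))
  # constant scores: permutations change nothing, nothing is significant
  ds <- manual_dataset(g, masks = rep(list(v), 6), scores = rep(75, 6))
  map <- psm_wperm(ds, test_config("WPERM", n_permutations = 50))
  expect_false(any(map$significant))
  expect_true(all(map$statistic == 1))
  # corrected p is monotone non-increasing in the observed statistic
  ds2 <- strong_signal_cohort(n_patients = 6, seed = 19, noise_sd = 10,
                              grid_n = 16)
  map2 <- psm_wperm(ds2, test_config("WPERM", n_permutations = 100, seed = 2))
  o <- order(map2$z_obs)
  expect_true(all(diff(map2$statistic[o]) <= 1e-12))
  expect_error(test_config("WPERM", n_permutations = 0), "n_permutations")
})

test_that("occurrence filters apply the patient and stimulation rules", {
  g <- tiny_grid(4)
  nv <- prod(g$shape)
  occ <- structure(list(nmap = integer(nv), npatmap = integer(nv), grid = g),
                   class = "occurrence_maps")
  v1 <- 1L; v2 <- 2L; v3 <- 3L
  # v1: 2 of 10 patients (20% < 25%) -> removed despite high nMap
  occ$nmap[v1] <- 20L; occ$npatmap[v1] <- 2L
  # v2: 5% of max nMap -> removed
  occ$nmap[v2] <- 1L; occ$npatmap[v2] <- 5L
  # v3: exactly at both boundaries (ceil(0.25*10)=3 patients, max nMap)
  occ$nmap[v3] <- 20L; occ$npatmap[v3] <- 3L
  kept <- apply_occurrence_filters(c(v1, v2, v3), occ, n_pat = 10)
  expect_identical(kept, v3)
})

test_that("small-cluster removal respects the strict volume threshold", {
  g <- voxel_grid(c(20, 20, 20), 0.5) # 0.125 mm^3 per voxel
  v <- function(...) pssmapr:::ijk_to_linear(g, rbind(c(...)))
  # 7-voxel plus-shaped cluster: 0.875 mm^3 -> removed
  c7 <- c(v(5, 5, 5), v(4, 5, 5), v(6, 5, 5), v(5, 4, 5), v(5, 6, 5),
          v(5, 5, 4), v(5, 5, 6))
  expect_length(remove_small_clusters(c7, g, 1), 0L)
  # 8-voxel 2x2x2 cube: exactly 1.0 mm^3 -> kept ("smaller than" is strict)
  c8 <- pssmapr:::ijk_to_linear(g, as.matrix(expand.grid(12:13, 12:13, 12:13)))
  expect_setequal(remove_small_clusters(c8, g, 1), c8)
  # both present: only the cube survives
  expect_setequal(remove_small_clusters(c(c7, c8), g, 1), c8)
  # 1 mm iso grid: every voxel is 1 mm^3 -> unchanged
  g1 <- tiny_grid(6, 1)
  scattered <- pssmapr:::ijk_to_linear(g1, rbind(c(0, 0, 0), c(3, 3, 3)))
  expect_setequal(remove_small_clusters(scattered, g1, 1), scattered)
})

test_that("connectivity switches change what counts as one cluster", {
  g <- tiny_grid(6, 0.5)
  # two voxels sharing only an edge: separate under 6-conn, joined under 18
  pair <- pssmapr:::ijk_to_linear(g, rbind(c(2, 2, 2), c(3, 3, 2)))
  expect_length(remove_small_clusters(pair, g, 0.2, connectivity = 6L), 0L)
  expect_setequal(remove_small_clusters(pair, g, 0.2, connectivity = 18L),
                  pair)
})

test_that("extract_pss recovers the ground truth on strong signal", {
  cfg_cohort <- pd_cohort_config(n_patients = 10, seed = 3, noise_sd = 0,
                                 grid = voxel_grid(c(24, 24, 24), 1))
  ds <- generate_cohort(cfg_cohort)
  gt <- pss_volume(ground_truth_mask(cfg_cohort), cfg_cohort$grid)
  for (m in c("WFDR", "WPERM", "BAYES")) {
    cfg <- test_config(m, n_permutations = 100,
                       mcmc = list(num_samples = 600, warmup_steps = 300),
                       seed = 5)
    p <- extract_pss(ds, cfg)
    expect_gt(length(p$mask), 0)
    expect_gt(dice_coef(p, gt), 40)
    # centroid lies inside the ground-truth ellipsoid
    rel <- (p$centroid - cfg_cohort$ground_truth$center) /
      cfg_cohort$ground_truth$semi_axes
    expect_lt(sum(rel^2), 1)
    # filtered mask is a subset of the significant voxels
    expect_lte(length(p$mask), p$provenance$n_significant)
  }
})

test_that("extract_pss is deterministic and empty on null data", {
  ds <- strong_signal_cohort(n_patients = 6, seed = 23, noise_sd = 10,
                             grid_n = 16)
  cfg <- test_config("BAYES", mcmc = list(num_samples = 300,
                                          warmup_steps = 150), seed = 7)
  expect_identical(extract_pss(ds, cfg)$mask, extract_pss(ds, cfg)$mask)
  ds0 <- ds
  ds0$stims$score <- rep(0, nrow(ds0$stims))
  for (m in c("WFDR", "WPERM", "BAYES")) {
    cfg0 <- test_config(m, n_permutations = 50,
                        mcmc = list(num_samples = 300, warmup_steps = 150))
    expect_length(extract_pss(ds0, cfg0)$mask, 0L)
  }
})
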