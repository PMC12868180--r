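# Shared fixture builders; everything is generated in code at test time.

tiny_grid <- function(n = 8, size = 1) voxel_grid(rep(n, 3), size)

# a pss_volume from explicit 0-based ijk rows
pss_from_ijk <- function(grid, ijk) {
  pss_volume(pssmapr:::ijk_to_linear(grid, as.matrix(ijk)), grid)
}

# hand-built dataset: list of masks (voxel-index vectors) + scores, one
# patient per stimulation unless patient ids given
manual_dataset <- function(grid, masks, scores,
                           patients = sprintf("P%02d", seq_along(masks))) {
  stims <- tibble::tibble(
    patient_id = patients,
    stim_id = sprintf("%s_S%02d", patients,
                      stats::ave(seq_along(masks), patients, FUN = seq_along)),
    amplitude = 1,
    score = scores,
    mask = lapply(masks, function(m) sort(as.integer(m)))
  )
  pssmapr:::new_stim_dataset(grid, stims)
}

# small strong-signal cohort used across mapping tests
strong_signal_cohort <- function(n_patients = 10, seed = 3, noise_sd = 0,
                                 grid_n = 32) {
  generate_cohort(pd_cohort_config(
    n_patients = n_patients, seed = seed, noise_sd = noise_sd,
    grid = voxel_grid(rep(grid_n, 3), 1)
  ))
}

# brute-force one-sided signed-rank p by full 2^n sign enumeration
enumerate_signed_rank_p <- function(scores, theta) {
  d <- scores - theta
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  mean(w_all >= w_obs - 1e-9)
}

# hand-written BH step-up returning adjusted p-values
bh_adjust_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}
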