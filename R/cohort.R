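#' Configure a synthetic stimulation cohort
#'
#' Builds the configuration for [generate_cohort()]. The generator emulates
#' the statistical structure of intra-/post-operative DBS stimulation test
#' data: every patient carries a small set of binary volumes of tissue
#' activated (VTAs) clustered along one or two parallel electrode
#' trajectories, and each VTA is labeled with a symptom-improvement score
#' in percent that is a monotone, saturating function of the VTA's overlap
#' with a ground-truth "sweet-spot" ellipsoid, plus rating noise.
#'
#' Two modes are provided. `"pd"` mimics an intra-operative Parkinson's
#' cohort: many stimulations per patient explored along two parallel
#' tracks spanning 14 mm in 1 mm steps, with a wide, roughly symmetric
#' score distribution (mean near 50). `"et"` mimics a post-operative
#' essential-tremor screening cohort: exactly 4 contact stimulations per
#' patient on a single track close to the target, with a right-skewed
#' score distribution (mean near 70).
#'
#' @param n_patients Number of patients.
#' @param stims_per_patient Integer range `c(min, max)`; per-patient counts
#'   are drawn uniformly from this range (a scalar fixes the count).
#' @param grid A [voxel_grid()]; default 32^3 at 1 mm isotropic.
#' @param mode `"pd"` or `"et"`; sets placement/score defaults.
#' @param ground_truth List with `center` (mm) and `semi_axes` (mm) of the
#'   ground-truth ellipsoid; must lie inside the grid.
#' @param trajectory List with `span` (mm), `step` (mm), `track_offset`
#'   (mm between the two parallel tracks; ignored for `"et"`), and
#'   `jitter_sd` (mm, per-patient lateral placement sd).
#' @param amplitude_range Stimulation amplitude range `c(lo, hi)`
#'   (arbitrary units); amplitudes are drawn uniformly and rounded to 0.2.
#' @param vta List with `r0` and `k`: VTA radius `r = r0 + k * sqrt(amp)`
#'   in mm, plus `axis_scale` (length-3 relative radii).
#' @param response List with `omega_sat` and `gamma`: the score response
#'   `g(omega) = min(1, omega / omega_sat)^gamma` of the overlap fraction
#'   `omega` of a VTA with the ground truth.
#' @param noise_sd Score noise standard deviation (percentage points).
#' @param quantization Score quantization step in percent (default 12.5,
#'   matching half-steps of a 0/25/50/75/100 rating scale), or `NULL` for
#'   continuous scores.
#' @param seed Integer seed making the cohort reproducible.
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [pd_cohort_config()], [et_cohort_config()]
#' @export
cohort_config <- function(n_patients,
                          stims_per_patient,
                          grid = voxel_grid(c(32, 32, 32), 1),
                          mode = c("pd", "et"),
                          ground_truth = NULL,
                          trajectory = NULL,
                          amplitude_range = c(0.2, 3),
                          vta = NULL,
                          response = NULL,
                          noise_sd = NULL,
                          quantization = 12.5,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (length(stims_per_patient) == 1L) {
    stims_per_patient <- rep(stims_per_patient, 2L)
  }
  stims_per_patient <- as.integer(stims_per_patient)
  if (stims_per_patient[1] < 1L || stims_per_patient[1] > stims_per_patient[2]) {
    abort("`stims_per_patient` must satisfy 1 <= min <= max")
  }
  defaults <- if (mode == "pd") {
    list(
      trajectory = list(span = 14, step = 1, track_offset = 2, jitter_sd = 1.5),
      response = list(omega_sat = 0.30, gamma = 0.80),
      noise_sd = 14
    )
  } else {
    list(
      trajectory = list(span = 6, step = 2, track_offset = 0, jitter_sd = 1),
      response = list(omega_sat = 0.80, gamma = 1.10),
      noise_sd = 10
    )
  }
  ground_truth <- ground_truth %||%
    list(center = grid$origin + (grid$shape - 1) / 2 * grid$voxel_size,
         semi_axes = c(3, 3, 4))
  trajectory <- utils::modifyList(defaults$trajectory, trajectory %||% list())
  response <- utils::modifyList(defaults$response, response %||% list())
  noise_sd <- noise_sd %||% defaults$noise_sd
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  vta <- utils::modifyList(
    list(r0 = 0.8, k = 1.4, axis_scale = c(1, 1, 1)), vta %||% list()
  )
  lo <- ground_truth$center - ground_truth$semi_axes
  hi <- ground_truth$center + ground_truth$semi_axes
  if (!point_in_grid(grid, lo) || !point_in_grid(grid, hi)) {
    abort("ground-truth ellipsoid does not lie inside the grid")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      stims_per_patient = stims_per_patient,
      grid = grid, mode = mode,
      ground_truth = ground_truth, trajectory = trajectory,
      amplitude_range = as.numeric(amplitude_range), vta = vta,
      response = response, noise_sd = noise_sd,
      quantization = quantization, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @param ... Overrides passed on to [cohort_config()].
#' @export
pd_cohort_config <- function(n_patients = 36, stims_per_patient = c(12, 22),
                             seed = 1L, ...) {
  cohort_config(n_patients, stims_per_patient, mode = "pd", seed = seed, ...)
}

#' @rdname cohort_config
#' @export
et_cohort_config <- function(n_patients = 61, stims_per_patient = 4,
                             seed = 1L, ...) {
  cohort_config(n_patients, stims_per_patient, mode = "et", seed = seed, ...)
}

#' Voxel mask of the ground-truth sweet spot
#' @param config A [cohort_config()].
#' @return Sorted integer vector of linear voxel indices.
#' @export
ground_truth_mask <- function(config) {
  ellipsoid_mask(config$grid, config$ground_truth$center,
                 config$ground_truth$semi_axes)
}

# voxel centers inside an axis-aligned ellipsoid; sorted linear indices
ellipsoid_mask <- function(grid, center, radii) {
  radii <- rep(radii, length.out = 3L)
  c0 <- (center - grid$origin) / grid$voxel_size # fractional 0-based index
  rv <- radii / grid$voxel_size
  lo <- pmax(ceiling(c0 - rv), 0)
  hi <- pmin(floor(c0 + rv), grid$shape - 1)
  if (any(lo > hi)) return(integer(0))
  box <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  d <- sweep(box, 2, c0, `-`)
  d <- sweep(d, 2, rv, `/`)
  inside <- rowSums(d^2) <= 1 + 1e-12
  sort(ijk_to_linear(grid, box[inside, , drop = FALSE]))
}

#' Generate one synthetic VTA mask
#'
#' The VTA is an axis-aligned ellipsoid around `center` whose radii grow
#' monotonically with amplitude, `r = r0 + k * sqrt(amplitude)` (scaled per
#' axis by `axis_scale`). This emulates the monotone growth of
#' electric-field threshold volumes with stimulation amplitude. If no voxel
#' center falls inside the ellipsoid the nearest voxel to `center` is
#' returned, so the mask is never empty.
#'
#' @param grid A [voxel_grid()].
#' @param center VTA center in world mm; must lie inside the grid.
#' @param amplitude Stimulation amplitude (> 0).
#' @param shape_params List with `r0`, `k`, `axis_scale` (see
#'   [cohort_config()]).
#' @return Sorted integer vector of linear voxel indices.
#' @examples
#' g <- voxel_grid(c(15, 15, 15), 1)
#' length(generate_vta(g, c(0, 0, 0), amplitude = 1))
#' @export
generate_vta <- function(grid, center, amplitude,
                         shape_params = list(r0 = 0.8, k = 1.4,
                                             axis_scale = c(1, 1, 1))) {
  if (!point_in_grid(grid, center)) abort("VTA `center` lies outside the grid")
  if (amplitude <= 0) abort("`amplitude` must be > 0")
  r <- (shape_params$r0 + shape_params$k * sqrt(amplitude)) *
    rep(shape_params$axis_scale %||% c(1, 1, 1), length.out = 3L)
  idx <- ellipsoid_mask(grid, center, r)
  if (length(idx) == 0L) {
    ijk <- pmin(pmax(world_to_ijk(grid, center), 0), grid$shape - 1)
    idx <- ijk_to_linear(grid, matrix(ijk, nrow = 1))
  }
  idx
}

#' Score one stimulation against the ground truth
#'
#' The improvement score (percent) is a saturating monotone response of the
#' overlap fraction `omega = |mask intersect gt| / |mask|`:
#' `score = clip(100 * min(1, omega / omega_sat)^gamma + noise, 0, 100)`,
#' optionally quantized to the configured rating step. Noise is drawn from
#' the caller's RNG stream, so scoring is deterministic under a fixed seed.
#'
#' @param mask Integer voxel indices of the VTA.
#' @param ground_truth Integer voxel indices of the sweet-spot ellipsoid
#'   (same grid as `mask`).
#' @param config A [cohort_config()] providing `response`, `noise_sd` and
#'   `quantization`.
#' @return Scalar score in `[0, 100]`.
#' @export
score_stimulation <- function(mask, ground_truth, config) {
  omega <- length(intersect(mask, ground_truth)) / length(mask)
  g <- pmin(1, omega / config$response$omega_sat)^config$response$gamma
  score <- 100 * g + if (config$noise_sd > 0) rnorm(1, 0, config$noise_sd) else 0
  score <- min(max(score, 0), 100)
  q <- config$quantization
  if (!is.null(q)) score <- round(score / q) * q
  score
}

#' Generate a synthetic stimulation cohort
#'
#' Draws per-patient electrode trajectories jittered around the
#' ground-truth neighborhood, places VTAs at trajectory positions with
#' random amplitudes, and labels each VTA with [score_stimulation()].
#' Identical configs (including seed) give bit-identical datasets.
#'
#' @param config A [cohort_config()].
#' @return A `stim_dataset`: list with `grid` and a tibble `stims`
#'   (columns `patient_id`, `stim_id`, `amplitude`, `score`, and a list
#'   column `mask` of voxel-index vectors).
#' @examples
#' cfg <- et_cohort_config(n_patients = 3, seed = 7)
#' ds <- generate_cohort(cfg)
#' n_patients(ds)
#' @export
generate_cohort <- function(config) {
  grid <- config$grid
  gt <- ground_truth_mask(config)
  traj <- config$trajectory
  gtc <- config$ground_truth$center
  z_rel <- seq(-traj$span / 2, traj$span / 2, by = traj$step)
  tracks_x <- if (config$mode == "pd") {
    c(-traj$track_offset / 2, traj$track_offset / 2)
  } else 0
  # trajectory feasibility at zero jitter: endpoints must fall in the grid
  for (tx in tracks_x) for (zz in range(z_rel)) {
    if (!point_in_grid(grid, gtc + c(tx, 0, zz))) {
      abort("trajectory extends outside the grid; enlarge the grid or shrink the span")
    }
  }
  withr::with_seed(config$seed, {
    rows <- purrr::map(seq_len(config$n_patients), function(p) {
      n_stim <- if (config$mode == "et") {
        length(z_rel)
      } else {
        sp <- config$stims_per_patient
        if (sp[1] == sp[2]) sp[1] else sample(sp[1]:sp[2], 1L)
      }
      jitter <- rnorm(3, 0, traj$jitter_sd)
      zs <- if (config$mode == "et") z_rel else sample(z_rel, n_stim, replace = TRUE)
      txs <- if (config$mode == "et") {
        rep(0, n_stim)
      } else {
        sample(tracks_x, n_stim, replace = TRUE)
      }
      amp <- round(runif(n_stim, config$amplitude_range[1],
                         config$amplitude_range[2]) / 0.2) * 0.2
      amp <- pmax(amp, 0.2)
      masks <- vector("list", n_stim)
      scores <- numeric(n_stim)
      for (s in seq_len(n_stim)) {
        center <- gtc + c(txs[s] + jitter[1], jitter[2], zs[s] + 0.5 * jitter[3])
        center <- pmin(pmax(center, grid$origin),
                       grid$origin + (grid$shape - 1) * grid$voxel_size)
        masks[[s]] <- generate_vta(grid, center, amp[s], config$vta)
        scores[s] <- score_stimulation(masks[[s]], gt, config)
      }
      tibble(
        patient_id = sprintf("P%03d", p),
        stim_id = sprintf("P%03d_S%02d", p, seq_len(n_stim)),
        amplitude = amp, score = scores, mask = masks
      )
    })
    new_stim_dataset(grid, dplyr::bind_rows(rows))
  })
}

new_stim_dataset <- function(grid, stims) {
  stopifnot(inherits(grid, "voxel_grid"))
  structure(list(grid = grid, stims = stims), class = "stim_dataset")
}

#' @export
print.stim_dataset <- function(x, ...) {
  cat("<stim_dataset> ", n_patients(x), " patients, ",
      nrow(x$stims), " stimulations on ",
      paste(x$grid$shape, collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Number of distinct patients in a dataset
#' @param dataset A `stim_dataset`.
#' @return Integer count.
#' @export
n_patients <- function(dataset) length(unique(dataset$stims$patient_id))

#' Write / read a stimulation cohort on disk
#'
#' Masks are stored as one NIfTI-1 file per stimulation (uint8, 0/1) and
#' the table as `stimulations.csv` with columns `patient_id`, `stim_id`,
#' `mask_file`, `amplitude`, `score`. `read_cohort()` inverts
#' `write_cohort()` bit-exactly and fails with the offending file named if
#' a mask is missing or its grid disagrees with the rest.
#'
#' @param dataset A `stim_dataset`.
#' @param directory Directory to write to / read from (created if needed).
#' @return `write_cohort()` returns the directory invisibly;
#'   `read_cohort()` returns a `stim_dataset`.
#' @export
write_cohort <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  grid <- dataset$grid
  affine <- rbind(cbind(diag(grid$voxel_size), grid$origin), c(0, 0, 0, 1))
  files <- character(nrow(dataset$stims))
  for (r in seq_len(nrow(dataset$stims))) {
    arr <- array(0L, dim = grid$shape)
    arr[dataset$stims$mask[[r]]] <- 1L
    img <- RNifti::asNifti(arr, datatype = "uint8")
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    files[r] <- paste0(dataset$stims$stim_id[r], ".nii.gz")
    RNifti::writeNifti(img, file.path(directory, files[r]))
  }
  tbl <- dataset$stims |>
    dplyr::select("patient_id", "stim_id", "amplitude", "score") |>
    dplyr::mutate(mask_file = files, .after = "stim_id")
  readr::write_csv(tbl, file.path(directory, "stimulations.csv"))
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  csv <- file.path(directory, "stimulations.csv")
  if (!file.exists(csv)) abort(paste0("no stimulations.csv in ", directory))
  tbl <- readr::read_csv(csv, show_col_types = FALSE)
  needed <- c("patient_id", "stim_id", "mask_file", "amplitude", "score")
  if (!all(needed %in% names(tbl))) {
    abort(paste0("malformed stimulations.csv: missing column(s) ",
                 paste(setdiff(needed, names(tbl)), collapse = ", ")))
  }
  grid <- NULL
  masks <- vector("list", nrow(tbl))
  for (r in seq_len(nrow(tbl))) {
    f <- file.path(directory, tbl$mask_file[r])
    if (!file.exists(f)) {
      abort(paste0("row ", r, " (", tbl$stim_id[r], "): mask file ",
                   tbl$mask_file[r], " not found"))
    }
    img <- RNifti::readNifti(f)
    xf <- RNifti::xform(img)
    g <- voxel_grid(dim(img), diag(xf[1:3, 1:3]), xf[1:3, 4])
    if (is.null(grid)) {
      grid <- g
    } else if (!grids_equal(grid, g)) {
      abort(paste0("grid mismatch in mask file ", tbl$mask_file[r]))
    }
    masks[[r]] <- which(as.array(img) != 0)
  }
  stims <- tbl |>
    dplyr::select(-"mask_file") |>
    dplyr::mutate(mask = masks)
  new_stim_dataset(grid, stims)
}
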