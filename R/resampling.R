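#' Patient / stimulation sampling plan
#'
#' Defines the additive patient-sampling and fixed-count
#' stimulation-subsampling scheme used to generate the dataset grid for
#' stability analysis: chains start from `start_size` randomly chosen
#' patients and grow by `step` patients drawn without replacement from the
#' remaining pool, repeated `n_patient_reps` times; each resulting dataset
#' is reduced to each of `stim_counts` stimulations per patient,
#' `n_stim_reps` times. With the defaults on a 36-patient cohort this
#' yields 160 subgroup datasets plus the full cohort (161) and
#' 161 x 5 x 3 = 2415 datasets after stimulation subsampling.
#'
#' @param start_size First subgroup size (default 4).
#' @param step Patients added per chain level (default 2).
#' @param n_patient_reps Number of independent patient chains (default 10).
#' @param stim_counts Stimulation counts per patient (default
#'   `c(4, 6, 8, 10, 12)`).
#' @param n_stim_reps Stimulation-sampling repetitions (default 3).
#' @param include_full_cohort Append the full cohort (once, shared across
#'   chains) as the terminal point of every chain (default `TRUE`).
#' @param seed Master seed; every chain and subsample derives a stable
#'   sub-seed from it, so any dataset is regenerable from (seed, key).
#' @return A list of class `sampling_plan`.
#' @export
sampling_plan <- function(start_size = 4L, step = 2L, n_patient_reps = 10L,
                          stim_counts = c(4L, 6L, 8L, 10L, 12L),
                          n_stim_reps = 3L, include_full_cohort = TRUE,
                          seed = 1L) {
  if (start_size < 2) abort("`start_size` must be >= 2")
  if (step < 1) abort("`step` must be >= 1")
  if (any(stim_counts < 1) || n_patient_reps < 1 || n_stim_reps < 1) {
    abort("counts and repetition numbers must be >= 1")
  }
  structure(
    list(start_size = as.integer(start_size), step = as.integer(step),
         n_patient_reps = as.integer(n_patient_reps),
         stim_counts = as.integer(stim_counts),
         n_stim_reps = as.integer(n_stim_reps),
         include_full_cohort = isTRUE(include_full_cohort),
         seed = as.integer(seed)),
    class = "sampling_plan"
  )
}

plan_sizes <- function(plan, n_total) {
  sizes <- seq(plan$start_size, by = plan$step,
               length.out = max(0, (n_total - 1 - plan$start_size) %/% plan$step + 1))
  sizes[sizes < n_total]
}

#' Additive nested patient chains
#'
#' Each chain is one realisation of the additive sampling-without-
#' replacement strategy: a random permutation of the patient ids whose
#' first `start_size`, `start_size + step`, ... elements form the nested
#' subgroups (so smaller subgroups are always subsets of larger ones
#' within a chain). The full cohort, if enabled, is appended once with
#' `chain = NA`.
#'
#' @param patient_ids Character vector of distinct patient ids.
#' @param plan A [sampling_plan()].
#' @return Tibble with columns `chain` (integer, `NA` for the full
#'   cohort), `n_pat`, and list column `patients`.
#' @export
additive_patient_chains <- function(patient_ids, plan) {
  n_total <- length(patient_ids)
  if (n_total < plan$start_size) {
    abort("cohort smaller than the plan's `start_size`")
  }
  sizes <- plan_sizes(plan, n_total)
  rows <- purrr::map(seq_len(plan$n_patient_reps), function(ch) {
    perm <- with_sub_seed(plan$seed, "chain", ch, code = sample(patient_ids))
    tibble(chain = ch, n_pat = as.integer(sizes),
           patients = purrr::map(sizes, ~ perm[seq_len(.x)]))
  })
  out <- dplyr::bind_rows(rows)
  if (plan$include_full_cohort) {
    out <- dplyr::bind_rows(out, tibble(
      chain = NA_integer_, n_pat = n_total, patients = list(patient_ids)
    ))
  }
  out
}

#' Restrict a dataset to a fixed number of stimulations per patient
#'
#' Samples exactly `n_stim` stimulations per patient without replacement;
#' masks and scores are untouched.
#'
#' @param dataset A `stim_dataset`.
#' @param n_stim Stimulations to retain per patient.
#' @param seed Integer seed.
#' @return A `stim_dataset`.
#' @export
subsample_stimulations <- function(dataset, n_stim, seed = 1L) {
  counts <- table(dataset$stims$patient_id)
  short <- names(counts)[counts < n_stim]
  if (length(short)) {
    abort(paste0("patient(s) with fewer than ", n_stim, " stimulations: ",
                 paste(short, collapse = ", ")))
  }
  stims <- withr::with_seed(seed, {
    dataset$stims |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice(sort(sample(dplyr::n(), n_stim))) |>
      dplyr::ungroup()
  })
  new_stim_dataset(dataset$grid, stims)
}

#' Enumerate the dataset grid of a sampling plan
#'
#' Materialises the manifest of every dataset key
#' (chain, nPat) x (nStim) x (stim rep), including the shared full-cohort
#' entry, together with the derived sub-seed that regenerates each
#' dataset. Datasets themselves are realised lazily with
#' [realize_dataset()].
#'
#' @param cohort A `stim_dataset` (the full cohort).
#' @param plan A [sampling_plan()].
#' @return Tibble with columns `chain`, `n_pat`, `n_stim`, `stim_rep`,
#'   `seed` and list column `patients`.
#' @export
enumerate_datasets <- function(cohort, plan) {
  chains <- additive_patient_chains(unique(cohort$stims$patient_id), plan)
  tidyr::expand_grid(chains, n_stim = plan$stim_counts,
                     stim_rep = seq_len(plan$n_stim_reps)) |>
    dplyr::mutate(seed = purrr::pmap_int(
      list(.data$chain, .data$n_pat, .data$n_stim, .data$stim_rep),
      function(ch, np, ns, sr) {
        derive_seed(plan$seed, "stims",
                    ifelse(is.na(ch), "full", ch), np, ns, sr)
      }
    )) |>
    dplyr::select("chain", "n_pat", "n_stim", "stim_rep", "seed", "patients")
}

#' Realise one dataset of the sampling grid
#'
#' @param cohort A `stim_dataset` (the full cohort).
#' @param key One row of the manifest from [enumerate_datasets()].
#' @return A `stim_dataset` with `key$n_pat` patients and `key$n_stim`
#'   stimulations each.
#' @export
realize_dataset <- function(cohort, key) {
  keep <- cohort$stims$patient_id %in% key$patients[[1]]
  sub <- new_stim_dataset(cohort$grid, cohort$stims[keep, ])
  subsample_stimulations(sub, key$n_stim, seed = key$seed)
}
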