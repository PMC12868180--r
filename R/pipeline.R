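#' Assemble a full pipeline configuration
#'
#' Bundles and validates the per-stage configurations for
#' [run_pipeline()]. Every stage validates here, before any computation.
#'
#' @param cohort A [cohort_config()].
#' @param plan A [sampling_plan()].
#' @param methods Statistical methods to map with (subset of
#'   `c("BAYES", "WFDR", "WPERM")`).
#' @param test Named list of overrides passed to [test_config()] (e.g.
#'   `improvement_threshold`, `n_permutations`, `mcmc`).
#' @param tolerance Stability tolerance in percentage points (default 5).
#' @param boundary Named list with `prior_sd`, `mcmc`, `n_pat_range`,
#'   `censor_cap`, `split` for the boundary stage.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = pd_cohort_config(),
                            plan = sampling_plan(),
                            methods = c("BAYES", "WFDR", "WPERM"),
                            test = list(),
                            tolerance = 5,
                            boundary = list(),
                            seed = 1L,
                            out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(inherits(cohort, "cohort_config"), inherits(plan, "sampling_plan"))
  if (tolerance <= 0) abort("`tolerance` must be > 0")
  boundary <- utils::modifyList(
    list(prior_sd = 10, mcmc = list(num_samples = 2000L, warmup_steps = 1000L),
         n_pat_range = 4:100, censor_cap = 100, split = 0.70),
    boundary
  )
  # validate the test overrides once per method up front
  test_cfgs <- lapply(methods, function(m) {
    do.call(test_config, utils::modifyList(list(method = m), test))
  })
  names(test_cfgs) <- methods
  structure(
    list(cohort = cohort, plan = plan, methods = methods, test = test,
         test_cfgs = test_cfgs, tolerance = tolerance, boundary = boundary,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `cohort`, `plan`, `test`, `boundary`, plus `methods`,
#' `tolerance`, `seed`, `out_dir`, are mapped onto the corresponding
#' [pipeline_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$grid)) {
    cohort_args$grid <- do.call(voxel_grid, cohort_args$grid)
  }
  mode <- cohort_args$mode %||% "pd"
  cohort_args$mode <- NULL
  cohort <- do.call(if (mode == "pd") pd_cohort_config else et_cohort_config,
                    cohort_args)
  plan <- do.call(sampling_plan, y$plan %||% list())
  pipeline_config(
    cohort = cohort, plan = plan,
    methods = y$methods %||% c("BAYES", "WFDR", "WPERM"),
    test = y$test %||% list(),
    tolerance = y$tolerance %||% 5,
    boundary = y$boundary %||% list(),
    seed = y$seed %||% 1L,
    out_dir = y$out_dir
  )
}

#' Compute sweet spots over the whole dataset grid
#'
#' Realises every dataset of the sampling plan and extracts its PSS with
#' each configured method. Per-dataset test seeds derive deterministically
#' from the master seed and the dataset key, so any single entry is
#' regenerable in isolation.
#'
#' @param cohort A `stim_dataset`.
#' @param plan A [sampling_plan()].
#' @param test_cfgs Named list of [test_config()]s (one per method).
#' @param progress Print a line per dataset (default `FALSE`).
#' @return Tibble with key columns (`chain`, `n_pat`, `n_stim`,
#'   `stim_rep`), `method` and list column `pss`.
#' @export
compute_pss_grid <- function(cohort, plan, test_cfgs, progress = FALSE) {
  manifest <- enumerate_datasets(cohort, plan)
  rows <- purrr::map(seq_len(nrow(manifest)), function(r) {
    key <- manifest[r, ]
    ds <- realize_dataset(cohort, key)
    purrr::map(names(test_cfgs), function(m) {
      cfg <- test_cfgs[[m]]
      cfg$seed <- derive_seed(plan$seed, "test", m,
                              ifelse(is.na(key$chain), "full", key$chain),
                              key$n_pat, key$n_stim, key$stim_rep)
      p <- extract_pss(ds, cfg)
      if (progress) {
        message(sprintf("[%s] chain=%s nPat=%d nStim=%d rep=%d -> %d voxels",
                        m, ifelse(is.na(key$chain), "full", key$chain),
                        key$n_pat, key$n_stim, key$stim_rep, length(p$mask)))
      }
      tibble(method = m, chain = key$chain, n_pat = key$n_pat,
             n_stim = key$n_stim, stim_rep = key$stim_rep, pss = list(p))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Run the full stability-analysis pipeline
#'
#' Executes simulate -> map -> curves -> stability -> boundary in order:
#' generates the synthetic cohort, computes the PSS for every dataset of
#' the sampling plan and method, builds the successive-comparison metric
#' curves (plus the combined metric), detects stability points, assembles
#' the binary stability records, and fits the boundary model per method
#' for each metric and for all metrics pooled. Identical configurations
#' produce identical results.
#'
#' @param config A [pipeline_config()].
#' @param progress Verbose per-dataset logging (default `FALSE`).
#' @return A list of class `pipeline_result` with elements `cohort`,
#'   `manifest`, `pss`, `curves`, `points`, `records`, `fits` (nested
#'   list by method/metric-set), `boundaries`, `evaluation`, `config`.
#'   When `config$out_dir` is set, tables are also written as CSV plus a
#'   `run.json` provenance file.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$cohort)
  plan <- config$plan
  manifest <- enumerate_datasets(cohort, plan)
  pss_tbl <- compute_pss_grid(cohort, plan, config$test_cfgs, progress)
  curves <- successive_comparisons(pss_tbl)
  curves <- dplyr::bind_rows(curves, combined_metric(curves))
  class(curves) <- unique(c("metric_curves", class(curves)))
  points <- stability_points(curves, config$tolerance)
  records <- build_stability_dataset(points, curves)
  bnd <- config$boundary
  metric_sets <- c("vol_diff", "dice", "centr_dist", "all")
  fits <- list(); boundaries <- list(); evals <- list()
  for (m in config$methods) {
    for (ms in metric_sets) {
      recs <- if (ms == "all") {
        dplyr::filter(records, .data$method == m,
                      .data$metric %in% c("vol_diff", "dice", "centr_dist"))
      } else {
        dplyr::filter(records, .data$method == m, .data$metric == ms)
      }
      if (nrow(recs) == 0L) next
      fit <- fit_boundary_model(
        recs, prior_sd = bnd$prior_sd, mcmc = bnd$mcmc,
        seed = derive_seed(config$seed, "boundary", m, ms)
      )
      fits[[m]][[ms]] <- fit
      boundaries[[length(boundaries) + 1L]] <-
        minimum_stim_boundary(fit, bnd$n_pat_range, bnd$censor_cap) |>
        dplyr::mutate(method = m, metric_set = ms, .before = 1)
      tab <- table(recs$label)
      ev <- if (length(tab) == 2L && min(tab) >= 2L) {
        evaluate_model(recs, split = bnd$split,
                       seed = derive_seed(config$seed, "eval", m, ms),
                       prior_sd = bnd$prior_sd, mcmc = bnd$mcmc)
      } else {
        tibble(accuracy = NA_real_, f1 = NA_real_,
               n_train = NA_integer_, n_test = NA_integer_)
      }
      evals[[length(evals) + 1L]] <- dplyr::mutate(
        ev, method = m, metric_set = ms, .before = 1)
    }
  }
  result <- structure(
    list(cohort = cohort, manifest = manifest, pss = pss_tbl,
         curves = curves, points = points, records = records, fits = fits,
         boundaries = dplyr::bind_rows(boundaries),
         evaluation = dplyr::bind_rows(evals), config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", n_patients(x$cohort), "-patient cohort, ",
      nrow(x$manifest), " datasets x ", length(x$config$methods),
      " method(s); ", nrow(x$curves), " curve points, ",
      nrow(x$records), " stability records\n", sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_flat <- result$manifest |>
    dplyr::mutate(patients = purrr::map_chr(.data$patients, paste,
                                            collapse = ";"))
  readr::write_csv(manifest_flat, file.path(out_dir, "manifest.csv"))
  readr::write_csv(result$curves, file.path(out_dir, "metric_curves.csv"))
  readr::write_csv(result$points, file.path(out_dir, "stability_points.csv"))
  readr::write_csv(result$records, file.path(out_dir, "stability_records.csv"))
  readr::write_csv(result$boundaries, file.path(out_dir, "boundary_curves.csv"))
  readr::write_csv(result$evaluation, file.path(out_dir, "evaluation.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    prov <- list(
      seed = result$config$seed, methods = result$config$methods,
      n_patients = n_patients(result$cohort),
      n_stimulations = nrow(result$cohort$stims),
      n_datasets = nrow(result$manifest),
      tolerance = result$config$tolerance
    )
    jsonlite::write_json(prov, file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out_dir)
}

#' Prior-sensitivity sweep for the Bayesian voxel test
#'
#' Re-extracts the sweet spot of one fixed dataset under a grid of prior
#' settings and summarises how the resulting volume and centroid move;
#' each row also reports the Dice overlap with the sweet spot of the
#' first (reference) prior.
#'
#' @param dataset A `stim_dataset`.
#' @param config A [test_config()] with `method = "BAYES"`.
#' @param prior_grid Tibble/data frame with columns among `mu0`, `tau`,
#'   `sigma_scale`; one row per prior setting (non-empty).
#' @return Tibble with the prior columns plus `n_voxels`, `volume_mm3`,
#'   `centroid_x/y/z`, `dice_vs_ref`.
#' @export
prior_sensitivity_sweep <- function(dataset, config, prior_grid) {
  stopifnot(config$method == "BAYES")
  prior_grid <- as_tibble(prior_grid)
  if (nrow(prior_grid) == 0L) abort("`prior_grid` must have at least one row")
  ref <- NULL
  purrr::map_dfr(seq_len(nrow(prior_grid)), function(r) {
    cfg <- config
    cfg$prior <- utils::modifyList(config$prior, as.list(prior_grid[r, ]))
    p <- extract_pss(dataset, cfg)
    if (r == 1L) ref <<- p
    cen <- if (length(p$mask)) p$centroid else rep(NA_real_, 3)
    dplyr::bind_cols(
      prior_grid[r, ],
      tibble(n_voxels = length(p$mask), volume_mm3 = p$volume,
             centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3],
             dice_vs_ref = dice_coef(p, ref))
    )
  })
}
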