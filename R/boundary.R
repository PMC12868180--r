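#' Fit the Bayesian logistic stability-boundary model
#'
#' Bayesian logistic regression of the binary stability label on the
#' total stimulation count: `P(stable) = logistic(b0 + b1 * total_stims)`.
#' The feature is standardized internally and the posterior is sampled
#' with an adaptive random-walk Metropolis sampler under
#' `Normal(0, prior_sd^2)` priors on the standardized-scale coefficients;
#' draws are mapped back to the raw scale. The proposal is derived from
#' the Laplace approximation (maximum-likelihood fit) when available.
#'
#' @param records A `stability_records` tibble (needs columns
#'   `total_stims` and `label`).
#' @param prior_sd Prior standard deviation of both standardized-scale
#'   coefficients (default 10, weakly informative).
#' @param mcmc List with `num_samples` (default 2000) and `warmup_steps`
#'   (default 1000).
#' @param seed Integer seed.
#' @return An object of class `boundary_fit`: list with a tibble `draws`
#'   (`beta0`, `beta1` on the raw total-stimulation scale), `degenerate`
#'   flag (single-class data), `accept_rate`, standardization constants
#'   and the training data. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] for summaries.
#' @export
fit_boundary_model <- function(records, prior_sd = 10,
                               mcmc = list(num_samples = 2000L,
                                           warmup_steps = 1000L),
                               seed = 1L) {
  x <- records$total_stims
  y <- records$label
  degenerate <- length(unique(y)) < 2L
  ctr <- mean(x)
  scl <- stats::sd(x)
  if (!is.finite(scl) || scl <= 0) scl <- 1
  z <- (x - ctr) / scl
  log_post <- function(b) {
    eta <- b[1] + b[2] * z
    sum(y * eta - log1p(exp(eta))) - sum(b^2) / (2 * prior_sd^2)
  }
  # Laplace-style proposal from the ML fit; fall back to a fixed scale
  prop_chol <- diag(c(0.5, 0.5))
  if (!degenerate) {
    fit <- suppressWarnings(glm(y ~ z, family = binomial()))
    vc <- suppressWarnings(try(vcov(fit), silent = TRUE))
    if (!inherits(vc, "try-error") && all(is.finite(vc)) &&
        all(diag(vc) < 1e4)) {
      prop_chol <- chol(vc * (2.4^2 / 2))
    }
    b <- coef(fit)
    if (!all(is.finite(b)) || any(abs(b) > 50)) b <- c(0, 0)
  } else {
    b <- c(0, 0)
  }
  num <- mcmc$num_samples; warm <- mcmc$warmup_steps
  draws <- matrix(NA_real_, num, 2)
  lp <- log_post(b)
  n_acc <- 0L
  withr::with_seed(seed, {
    for (it in seq_len(warm + num)) {
      b_new <- b + drop(rnorm(2) %*% prop_chol)
      lp_new <- log_post(b_new)
      if (log(runif(1)) < lp_new - lp) {
        b <- b_new; lp <- lp_new
        if (it > warm) n_acc <- n_acc + 1L
      }
      if (it > warm) draws[it - warm, ] <- b
    }
  })
  structure(
    list(
      draws = tibble(beta0 = draws[, 1] - draws[, 2] * ctr / scl,
                     beta1 = draws[, 2] / scl),
      degenerate = degenerate, accept_rate = n_acc / num,
      center = ctr, scale = scl, prior_sd = prior_sd, seed = seed,
      records = records
    ),
    class = "boundary_fit"
  )
}

#' @export
print.boundary_fit <- function(x, ...) {
  cat("<boundary_fit> ", nrow(x$draws), " posterior draws",
      if (x$degenerate) " (degenerate: single-class data)", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_boundary_model
#' @param x A `boundary_fit`.
#' @param ... Unused.
#' @export
tidy.boundary_fit <- function(x, ...) {
  purrr::map_dfr(c(beta0 = "beta0", beta1 = "beta1"), function(term) {
    d <- x$draws[[term]]
    tibble(estimate = mean(d), std.error = stats::sd(d),
           conf.low = unname(quantile(d, 0.025)),
           conf.high = unname(quantile(d, 0.975)))
  }, .id = "term")
}

#' @rdname fit_boundary_model
#' @export
glance.boundary_fit <- function(x, ...) {
  tibble(n_obs = nrow(x$records), n_draws = nrow(x$draws),
         accept_rate = x$accept_rate, degenerate = x$degenerate)
}

#' Per-draw probability of stability at a total stimulation count
#'
#' @param fit A `boundary_fit`.
#' @param total_stims Scalar total stimulation count.
#' @return Numeric vector over posterior draws, values in (0, 1).
#' @export
stability_probability <- function(fit, total_stims) {
  plogis(fit$draws$beta0 + fit$draws$beta1 * total_stims)
}

#' Minimum-stimulation stability boundary with credible band
#'
#' For each posterior draw with positive slope, the stability threshold on
#' the total count is `T = -beta0 / beta1` (the 50% point of the logistic)
#' and the minimum stimulations per patient at a given patient count is
#' `max(1, ceiling(T / n_pat))`. Draws with non-positive slope carry no
#' finite threshold and are censored at `censor_cap` (flagged via
#' `censored_frac`). The curve reports, per patient count, the mean and
#' the 2.5/97.5 posterior percentiles of the per-draw minima, plus
#' `mean_cont`, the mean of the continuous (pre-ceiling) minima
#' `max(1, T / n_pat)` whose convex non-increasing shape is free of
#' ceiling granularity.
#'
#' @param fit A `boundary_fit`.
#' @param n_pat_range Patient counts to probe (default `4:100`).
#' @param censor_cap Reported minimum for censored draws (default 100,
#'   i.e. beyond any probed stimulation count).
#' @return Tibble of class `boundary_curve` with columns `n_pat`, `mean`,
#'   `mean_cont`, `ci_low`, `ci_high`, `censored_frac`; `NULL` attributes
#'   aside, all values are `NA` when every draw is censored (boundary not
#'   existing).
#' @export
minimum_stim_boundary <- function(fit, n_pat_range = 4:100,
                                  censor_cap = 100) {
  b0 <- fit$draws$beta0; b1 <- fit$draws$beta1
  pos <- b1 > 0
  cens_frac <- mean(!pos)
  if (fit$degenerate || !any(pos)) {
    out <- tibble(n_pat = as.integer(n_pat_range), mean = NA_real_,
                  mean_cont = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, censored_frac = cens_frac)
    class(out) <- c("boundary_curve", class(out))
    attr(out, "exists") <- FALSE
    return(out)
  }
  thr <- ifelse(pos, -b0 / b1, Inf)
  rows <- purrr::map_dfr(as.integer(n_pat_range), function(np) {
    cont <- pmax(1, thr / np)
    nstim <- pmin(pmax(1, ceiling(thr / np)), censor_cap)
    tibble(n_pat = np, mean = mean(nstim),
           mean_cont = mean(pmin(cont, censor_cap)),
           ci_low = unname(quantile(nstim, 0.025)),
           ci_high = unname(quantile(nstim, 0.975)),
           censored_frac = cens_frac)
  })
  class(rows) <- c("boundary_curve", class(rows))
  attr(rows, "exists") <- TRUE
  rows
}

#' Train/test evaluation of the boundary model
#'
#' Fits the model on a stratified random `split` fraction of the records
#' and classifies the held-out records by posterior-mean probability of
#' stability >= 0.5; reports accuracy and F1 (positive class = stable).
#'
#' @param records A `stability_records` tibble.
#' @param split Training fraction (default 0.70).
#' @param seed Integer seed (controls the split and the sampler).
#' @param ... Passed to [fit_boundary_model()].
#' @return Tibble with `accuracy`, `f1`, `n_train`, `n_test`.
#' @export
evaluate_model <- function(records, split = 0.70, seed = 1L, ...) {
  if (min(table(records$label)) < 2L) {
    abort("need at least 2 records per class to evaluate")
  }
  idx_train <- withr::with_seed(derive_seed(seed, "split"), {
    unlist(lapply(split(seq_len(nrow(records)), records$label), function(ix) {
      sample(ix, max(1L, round(split * length(ix))))
    }))
  })
  train <- records[idx_train, ]
  test <- records[-idx_train, ]
  fit <- fit_boundary_model(train, seed = seed, ...)
  p <- vapply(test$total_stims,
              function(t) mean(stability_probability(fit, t)), numeric(1))
  pred <- as.integer(p >= 0.5)
  tp <- sum(pred == 1 & test$label == 1)
  fp <- sum(pred == 1 & test$label == 0)
  fn <- sum(pred == 0 & test$label == 1)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  tibble(accuracy = mean(pred == test$label), f1 = f1,
         n_train = nrow(train), n_test = nrow(test))
}
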