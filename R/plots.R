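#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   facet_grid labs theme_bw
#' @export
ggplot2::autoplot

#' Plot metric curves
#'
#' One line per stimulation count, faceted by metric (rows) and method
#' (columns), mirroring the usual presentation of sweet-spot variability
#' against increasing patient count.
#'
#' @param object A `metric_curves` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_curves <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$mean))
  ggplot(dat, aes(x = .data$n_pat, y = .data$mean,
                  colour = factor(.data$n_stim),
                  group = factor(.data$n_stim))) +
    geom_line() +
    geom_point(size = 1) +
    facet_grid(metric ~ method, scales = "free_y") +
    labs(x = "patients (nPat)", y = "metric value [%]",
         colour = "stimulations\nper patient") +
    theme_bw()
}

#' Plot a stability boundary with its credible band
#'
#' @param object A `boundary_curve` tibble (possibly several stacked, with
#'   `method` / `metric_set` columns from [run_pipeline()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boundary_curve <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$mean))
  grouped <- all(c("method", "metric_set") %in% names(dat))
  p <- if (grouped) {
    ggplot(dat, aes(x = .data$n_pat, y = .data$mean,
                    colour = .data$method,
                    fill = .data$method,
                    linetype = .data$metric_set)) +
      geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  alpha = 0.15, colour = NA)
  } else {
    ggplot(dat, aes(x = .data$n_pat, y = .data$mean)) +
      geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  alpha = 0.15)
  }
  p + geom_line() +
    labs(x = "patients (nPat)", y = "minimum stimulations per patient",
         title = "PSS stability boundary (mean and 95% credible interval)") +
    theme_bw()
}
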