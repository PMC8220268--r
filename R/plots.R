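# ggplot2 visualizations for the result objects.

#' Plot methods for package result objects
#'
#' [ggplot2::autoplot()] methods: replicate histograms for resampling
#' distributions (with the observed value marked), rarefaction curves with
#' 95% confidence ribbons, permutation null distributions, subsampling
#' density curves, and Akaike-weight bars for model-selection tables.
#'
#' @param object A package result object.
#' @param bins Histogram bin count where relevant.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pbc_resample
#' @export
autoplot.pbc_resample <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(
      x = "pBC", y = "replicates",
      title = sprintf("%s (%d replicates)", object$label, object$n_reps),
      subtitle = sprintf("observed = %.4f", object$observed)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pbc_resample
#' @method autoplot pbc_rarefaction
#' @export
autoplot.pbc_rarefaction <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$level, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "taxa sampled", y = "pBC",
                  title = "pBC rarefaction curve (95% CI)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pbc_resample
#' @method autoplot pbc_permutation
#' @export
autoplot.pbc_permutation <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(
      x = "pBC under permuted regions", y = "permutations",
      title = "Permutation null distribution",
      subtitle = sprintf("observed = %.4f, p = %.4g (%s)",
                         object$observed, object$p_value, object$alternative)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pbc_resample
#' @method autoplot pbc_subsample
#' @export
autoplot.pbc_subsample <- function(object, ...) {
  ggplot2::ggplot(object$density, ggplot2::aes(x = .data$pbc, y = .data$density)) +
    ggplot2::geom_area(fill = "darkorange", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$distribution$observed,
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(
      x = "pBC", y = "density",
      title = sprintf("pBC after removing %.0f%% of taxa in [%g, %g] degrees",
                      100 * object$removal_fraction,
                      object$lat_band[1], object$lat_band[2])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pbc_resample
#' @method autoplot gls_model_selection
#' @export
autoplot.gls_model_selection <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = rev(tab$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Akaike weight", y = NULL,
                  title = "GLS model selection (AICc)") +
    ggplot2::theme_minimal()
}

#' Occurrence and collection curves across latitude
#'
#' @param series Tibble with columns `bin_floor`, `occurrences`,
#'   `collections` (as in a run report's `latitude_series`).
#' @return A ggplot object.
#' @export
plot_latitude_series <- function(series) {
  long <- tidyr::pivot_longer(series, -"bin_floor",
                              names_to = "series", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_floor, y = .data$count,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "latitude bin (degrees N)", y = "records",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
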