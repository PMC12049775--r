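#' Kaplan-Meier curve plot
#'
#' Step plot of the per-group product-limit estimates of a [km_logrank()]
#' result, annotated with the log-rank p-value.
#'
#' @param object A `km_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.km_result <- function(object, ...) {
  curves <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L,
                     estimate = 1, conf_low = 1, conf_high = 1), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$estimate,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL,
                  subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' ICI score distribution by primary site
#'
#' @param ici ICI table from [compute_ici()].
#' @param sites Tibble with columns `sample`, `site`.
#' @return A ggplot object.
#' @export
plot_ici <- function(ici, sites) {
  df <- dplyr::inner_join(ici, sites, by = "sample")
  ggplot2::ggplot(df, ggplot2::aes(.data$site, .data$ici)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6,
                         ggplot2::aes(colour = .data$ici_group)) +
    ggplot2::labs(x = NULL, y = "ICI score", colour = "infiltration") +
    ggplot2::theme_minimal()
}

#' Spatial plot of a phenotyped cell map
#'
#' Cells coloured by phenotype, vessels as crosses, detected aggregate
#' centroids circled.
#'
#' @param cells Cell map tibble for one or more samples.
#' @param vessels Optional vessel tibble.
#' @param aggregates Optional classified aggregate table.
#' @return A ggplot object, faceted by sample.
#' @export
plot_cell_map <- function(cells, vessels = NULL, aggregates = NULL) {
  p <- ggplot2::ggplot(cells, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phenotype), size = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  if (!is.null(vessels) && nrow(vessels) > 0) {
    p <- p + ggplot2::geom_point(data = vessels, shape = 3, size = 1,
                                 colour = "grey30")
  }
  if (!is.null(aggregates) && nrow(aggregates) > 0) {
    p <- p + ggplot2::geom_point(
      data = aggregates,
      ggplot2::aes(.data$centroid_x_um, .data$centroid_y_um,
                   shape = .data$call),
      size = 4, colour = "black", stroke = 0.8)
  }
  p
}

#' Forest plot of a Cox model
#'
#' @param x A `cox_result`.
#' @return A ggplot object.
#' @export
plot_forest <- function(x) {
  stopifnot(inherits(x, "cox_result"))
  df <- x$table
  ggplot2::ggplot(df, ggplot2::aes(.data$hr, stats::reorder(.data$term, .data$hr))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
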