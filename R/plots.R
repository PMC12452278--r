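# ggplot2 displays for the main result types. Maps are drawn as lat/lon
# rasters; ordinations as correlation/biplot panels.

#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_point geom_segment
#'   geom_text labs scale_fill_viridis_c coord_fixed theme_minimal
NULL

map_plot_data <- function(map, grid) {
  dplyr::left_join(trait_values(map),
    tibble::as_tibble(grid)[, c("cell_id", "lat", "lon")], by = "cell_id")
}

#' Plot a trait-level HSI map
#'
#' @param object A `trait_hsi`.
#' @param grid The `world_grid` it lives on.
#' @param what `"mean"` or `"sd"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trait_hsi <- function(object, grid, what = c("mean", "sd"), ...) {
  what <- match.arg(what)
  d <- dplyr::left_join(object$grid,
    tibble::as_tibble(grid)[, c("cell_id", "lat", "lon")], by = "cell_id")
  ggplot(d, aes(x = .data$lon, y = .data$lat, fill = .data[[what]])) +
    geom_raster() +
    scale_fill_viridis_c(limits = if (what == "mean") c(0, 1) else NULL) +
    coord_fixed() +
    labs(
      title = paste0(object$trait_label, " (", object$n_species, " species)"),
      x = "Longitude", y = "Latitude",
      fill = if (what == "mean") "Mean annual HSI" else "Across-species SD"
    ) +
    theme_minimal()
}

#' Plot a species HSI map
#'
#' @param object An `hsi_map`.
#' @param grid The `world_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hsi_map <- function(object, grid, ...) {
  d <- map_plot_data(object, grid)
  ggplot(d, aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_fixed() +
    labs(title = object$species_id, x = "Longitude", y = "Latitude",
         fill = "Annual HSI") +
    theme_minimal()
}

#' Plot a latitudinal HSI profile
#'
#' @param object A `lat_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lat_profile <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$lat, y = .data$hsi)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "Latitude", y = "Zonal mean HSI") +
    theme_minimal()
}

#' Biplot of an environmental PCA
#'
#' Variable loadings on the first two components; supplementary variables
#' (when present) are drawn from their score correlations in a distinct
#' colour.
#'
#' @param object An `env_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.env_pca <- function(object, ...) {
  ld <- tibble::as_tibble(object$loadings, rownames = "variable")
  p <- ggplot(ld, aes(x = .data$PC1, y = .data$PC2)) +
    geom_segment(aes(xend = 0, yend = 0), linetype = "dashed",
                 colour = "grey40") +
    geom_text(aes(label = .data$variable), size = 3) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])
    ) +
    theme_minimal()
  supp <- object$supplementary_correlations
  if (!is.null(supp)) {
    s2 <- supp |>
      dplyr::filter(.data$component %in% c("PC1", "PC2")) |>
      tidyr::pivot_wider(names_from = "component", values_from = "correlation")
    p <- p +
      geom_segment(data = s2, aes(xend = 0, yend = 0), colour = "firebrick") +
      geom_text(data = s2, aes(label = .data$variable), colour = "firebrick",
                size = 3)
  }
  p
}

#' Occupancy-evenness ubiquity plot
#'
#' Each point is a species, sized by its total read abundance and coloured
#' by ubiquity category when present.
#'
#' @param metrics Output of [species_metrics()] (optionally after
#'   [classify_ubiquity()]).
#' @return A ggplot.
#' @export
plot_ubiquity <- function(metrics) {
  p <- ggplot(metrics, aes(x = .data$occupancy, y = .data$evenness,
                           size = .data$total_abundance))
  if (!is.null(metrics$category)) {
    p <- p + geom_point(aes(colour = .data$category), alpha = 0.7)
  } else {
    p <- p + geom_point(alpha = 0.7)
  }
  p + labs(x = "Occupancy (sites)", y = "Pielou evenness",
           size = "Total reads") +
    theme_minimal()
}
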