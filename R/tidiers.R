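# broom-style tidiers and ggplot2 autoplot methods

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a percept map
#'
#' @param x A `percept_map`.
#' @param ... Unused.
#' @return The per-region color tibble.
#' @method tidy percept_map
#' @export
tidy.percept_map <- function(x, ...) x$region_colors

#' One-row summary of a percept map
#'
#' @param x A `percept_map`.
#' @param ... Unused.
#' @return A tibble with `mode`, `n_regions`, `n_barrier_px`.
#' @method glance percept_map
#' @export
glance.percept_map <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 n_regions = attr(x$labels, "n_regions"),
                 n_barrier_px = sum(x$labels == 0))
}

#' Tidy a clustering of matches
#'
#' @param x A `match_clusters` object.
#' @param ... Unused.
#' @return The assignment tibble (`location`, `x`, `y`, `cluster`).
#' @method tidy match_clusters
#' @export
tidy.match_clusters <- function(x, ...) x$assignments

#' One-row summary of a clustering of matches
#'
#' @param x A `match_clusters` object.
#' @param ... Unused.
#' @return A tibble with `k`, `sizes`, `within_dispersion`,
#'   `between_dispersion`, `cutoff`.
#' @method glance match_clusters
#' @export
glance.match_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, sizes = paste(x$sizes, collapse = ","),
                 within_dispersion = x$within_dispersion,
                 between_dispersion = x$between_dispersion,
                 cutoff = x$cutoff)
}

raster_plot_df <- function(r) {
  d <- as_tibble.raster_stim(r)
  d$hex <- grDevices::rgb(srgb_encode(d$R), srgb_encode(d$G),
                          srgb_encode(d$B))
  d
}

#' Plot a raster stimulus
#'
#' Renders the raster with gamma-encoded display colors on a visual-degree
#' axis.
#'
#' @param object A raster.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raster_stim
#' @export
autoplot.raster_stim <- function(object, ...) {
  d <- raster_plot_df(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_deg, -.data$y_deg)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hex)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "degrees", y = "degrees") +
    ggplot2::theme_minimal()
}

#' Plot a percept map
#'
#' @param object A `percept_map`.
#' @param ... Passed to the raster autoplot.
#' @return A ggplot of the painted percept raster.
#' @method autoplot percept_map
#' @export
autoplot.percept_map <- function(object, ...) {
  autoplot.raster_stim(object$raster, ...)
}

#' Chromaticity scatter of match records
#'
#' CIE xy scatter of per-location mean matches, colored by contour
#' condition -- the analog of the matching experiment's summary plots.
#'
#' @param records A MatchRecord tibble (model or synthetic-observer).
#' @return A ggplot.
#' @export
plot_matches <- function(records) {
  pts <- dplyr::summarise(
    dplyr::group_by(records, .data$condition, .data$location),
    x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y,
                                    color = .data$condition)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$location),
                       nudge_y = 0.004, show.legend = FALSE, size = 3) +
    ggplot2::labs(x = "CIE x", y = "CIE y", color = "contours") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
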