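#' Bull's-eye layout coordinates for the 17 AHA segments
#'
#' Polar wedge coordinates of the standard bull's-eye display: basal ring
#' outermost, apex at the centre. Used by the segment-level plot functions.
#'
#' @return tibble with `segment_id`, `ring`, `start_deg`, `end_deg`,
#'   `r_inner`, `r_outer`.
#' @keywords internal
aha_bullseye_layout <- function() {
  six <- function(ids, r0, r1) {
    # sector boundaries at the septal anchor; display rotated so anterior
    # points up
    tibble::tibble(segment_id = ids, ring = rep(r1, 6L),
                   start_deg = seq(0, 300, 60), end_deg = seq(60, 360, 60),
                   r_inner = r0, r_outer = r1)
  }
  dplyr::bind_rows(
    six(c(2L, 1L, 6L, 5L, 4L, 3L), 0.75, 1),
    six(c(8L, 7L, 12L, 11L, 10L, 9L), 0.5, 0.75),
    tibble::tibble(segment_id = c(14L, 13L, 16L, 15L), ring = 0.5,
                   start_deg = c(-45, 45, 135, 225),
                   end_deg = c(45, 135, 225, 315),
                   r_inner = 0.25, r_outer = 0.5),
    tibble::tibble(segment_id = 17L, ring = 0.25, start_deg = 0,
                   end_deg = 360, r_inner = 0, r_outer = 0.25))
}

#' Bull's-eye plot of a per-segment metric
#'
#' @param summary a `segment_summary` (or any tibble with `segment_id`,
#'   `surface` and the metric column).
#' @param metric column to display (default `"sd_lat"`).
#' @param surface `"EPI"` or `"ENDO"`.
#' @return a ggplot object.
#' @export
plot_segment_bullseye <- function(summary, metric = "sd_lat",
                                  surface = "EPI") {
  surf <- surface
  lay <- aha_bullseye_layout()
  dat <- summary |>
    dplyr::filter(.data$surface == surf) |>
    dplyr::inner_join(lay, by = "segment_id")
  wedges <- dat |>
    dplyr::rowwise() |>
    dplyr::group_map(function(r, key) {
      ang <- seq(r$start_deg, r$end_deg, length.out = 40) * pi / 180
      tibble::tibble(
        segment_id = r$segment_id, value = r[[metric]],
        x = c(r$r_outer * sin(ang), rev(r$r_inner * sin(ang))),
        y = c(r$r_outer * cos(ang), rev(r$r_inner * cos(ang))))
    }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(wedges, ggplot2::aes(.data$x, .data$y,
                                       group = .data$segment_id,
                                       fill = .data$value)) +
    ggplot2::geom_polygon(colour = "grey25", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = metric) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s (%s surface)", metric, surface))
}

#' Activation or voltage map on the heart surface (2-D projection)
#'
#' Displays a per-node map as a front/back pair of orthographic projections
#' coloured by the metric; a quick-look diagnostic rather than full 3-D
#' rendering.
#'
#' @param heart a `heart_geometry`.
#' @param values per-node numeric vector (e.g. `lat_ms` or `vpp_uv`).
#' @param label legend title.
#' @return a ggplot object.
#' @export
plot_heart_map <- function(heart, values, label = "value") {
  v <- heart$mesh$vertices
  dat <- dplyr::bind_rows(
    tibble::tibble(x = v[, 1L], y = v[, 3L], value = values,
                   depth = v[, 2L], view = "front (y-)"),
    tibble::tibble(x = -v[, 1L], y = v[, 3L], value = values,
                   depth = -v[, 2L], view = "back (y+)")) |>
    dplyr::filter(.data$depth <= 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y,
                                    colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~view) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = label) +
    ggplot2::theme_minimal()
}

#' Group comparison of a cohort metric in one segment
#'
#' @param cohort_table tidy table from [cohort_segment_table()].
#' @param metric metric name.
#' @param segment_id,surface segment selector.
#' @return a ggplot object.
#' @export
plot_group_comparison <- function(cohort_table, metric = "sd_lat",
                                  segment_id = 1L, surface = "EPI") {
  metric_name <- metric
  seg_id <- segment_id
  surf <- surface
  dat <- cohort_table |>
    dplyr::filter(.data$metric == metric_name,
                  .data$segment_id == seg_id, .data$surface == surf)
  ggplot2::ggplot(dat, ggplot2::aes(.data$group, .data$value,
                                    colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = metric,
                  title = sprintf("segment %d (%s)", seg_id, surf)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_segment_bullseye
#' @param object a `segment_summary`.
#' @param ... passed to [plot_segment_bullseye()].
#' @export
autoplot.segment_summary <- function(object, ...) {
  plot_segment_bullseye(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
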