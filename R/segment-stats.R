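#' Per-segment summary of activation and voltage maps
#'
#' Aggregates per-node LAT and peak-to-peak voltage into the AHA segment
#' table used throughout the analysis: for every (segment, surface) cell the
#' number of valid nodes, mean and sample standard deviation (n-1
#' denominator) of both metrics. The standard deviations are the two
#' within-segment dispersion measures: activation dispersion (SD of LAT) and
#' voltage dispersion (SD of voltage). Cells with fewer than `min_nodes`
#' valid nodes are reported with `NA` statistics.
#'
#' The endocardial surface summarizes segments 1-16 over LV endocardial
#' nodes; the epicardial surface summarizes segments 1-17, drawing the five
#' septal segments from the RV endocardial surrogate when
#' [apply_rv_septal_substitution()] has been applied.
#'
#' @param activation an `activation_map` tibble (`node_id`, `lat_ms`,
#'   `valid`).
#' @param voltage a `voltage_map` tibble (`node_id`, `vpp_uv`, `valid`).
#' @param seg a `segment_model`.
#' @param min_nodes minimum valid nodes per cell (default 3).
#' @return a `segment_summary` tibble: `segment_id`, `surface`,
#'   `n_valid_nodes`, `mean_lat`, `sd_lat`, `mean_vpp`, `sd_vpp`.
#' @export
summarize_segments <- function(activation, voltage, seg, min_nodes = 3L) {
  stopifnot(nrow(activation) == nrow(seg), nrow(voltage) == nrow(seg))
  per_node <- seg |>
    dplyr::select("node_id", "segment_id", "surface_class") |>
    dplyr::inner_join(dplyr::select(activation, "node_id", "lat_ms",
                                    lat_valid = "valid"),
                      by = "node_id") |>
    dplyr::inner_join(dplyr::select(voltage, "node_id", "vpp_uv",
                                    vpp_valid = "valid"),
                      by = "node_id") |>
    dplyr::filter(!is.na(.data$surface_class)) |>
    dplyr::mutate(surface = dplyr::if_else(.data$surface_class == "ENDO",
                                           "ENDO", "EPI"),
                  valid = .data$lat_valid & .data$vpp_valid)
  grid <- dplyr::bind_rows(
    tibble::tibble(segment_id = 1:16, surface = "ENDO"),
    tibble::tibble(segment_id = 1:17, surface = "EPI")
  )
  out <- per_node |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$segment_id, .data$surface) |>
    dplyr::summarise(n_valid_nodes = dplyr::n(),
                     mean_lat = mean(.data$lat_ms),
                     sd_lat = stats::sd(.data$lat_ms),
                     mean_vpp = mean(.data$vpp_uv),
                     sd_vpp = stats::sd(.data$vpp_uv),
                     .groups = "drop") |>
    dplyr::right_join(grid, by = c("segment_id", "surface")) |>
    dplyr::mutate(n_valid_nodes = dplyr::coalesce(.data$n_valid_nodes, 0L)) |>
    dplyr::arrange(.data$surface, .data$segment_id)
  blank <- out$n_valid_nodes < min_nodes
  out$mean_lat[blank] <- NA_real_
  out$sd_lat[blank] <- NA_real_
  out$mean_vpp[blank] <- NA_real_
  out$sd_vpp[blank] <- NA_real_
  class(out) <- c("segment_summary", class(out))
  out
}

#' Long-format cohort table of segment summaries
#'
#' Stacks per-subject segment summaries into the tidy long table consumed by
#' the group-comparison stage: one row per
#' (subject, segment, surface, metric).
#'
#' @param summaries named list of `segment_summary` tibbles, one per
#'   subject; names are subject ids.
#' @param group_labels character vector (recycled against `summaries`)
#'   giving each subject's group.
#' @return tibble with columns `subject`, `group`, `segment_id`, `surface`,
#'   `metric` (`mean_lat`, `sd_lat`, `mean_vpp`, `sd_vpp`), `value`.
#' @export
cohort_segment_table <- function(summaries, group_labels) {
  if (is.null(names(summaries))) {
    names(summaries) <- sprintf("S%03d", seq_along(summaries))
  }
  if (anyDuplicated(names(summaries))) stop("duplicate subject ids")
  group_labels <- rep_len(group_labels, length(summaries))
  purrr::map2(summaries, group_labels, function(s, g) {
    s |>
      dplyr::select("segment_id", "surface", "mean_lat", "sd_lat",
                    "mean_vpp", "sd_vpp") |>
      tidyr::pivot_longer(cols = c("mean_lat", "sd_lat", "mean_vpp",
                                   "sd_vpp"),
                          names_to = "metric", values_to = "value") |>
      dplyr::mutate(group = g)
  }) |>
    dplyr::bind_rows(.id = "subject") |>
    dplyr::select("subject", "group", "segment_id", "surface", "metric",
                  "value") |>
    dplyr::arrange(.data$subject, .data$surface, .data$segment_id,
                   .data$metric)
}
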