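#' AHA 17-segment assignment
#'
#' Bins every heart node into the standardized 17-segment left-ventricular
#' model: basal / mid / apical thirds of the long axis (equal thirds of the
#' base-to-apex span) plus an apical cap (most apical 5 % by default), with
#' 6 equal 60-degree sectors in the basal and mid rings, 4 equal 90-degree
#' sectors in the apical ring, and segment 17 at the cap. The sector origin
#' is anchored at the geometry's `septal_direction` (the centre of the
#' septum, i.e. the boundary between the anteroseptal and inferoseptal
#' segments), counting counter-clockwise viewed from the base.
#'
#' Segment numbering follows the clinical convention: 1 basal anterior,
#' 2 basal anteroseptal, 3 basal inferoseptal, 4 basal inferior, 5 basal
#' inferolateral, 6 basal anterolateral; 7-12 the corresponding mid-cavity
#' ring; 13 apical anterior, 14 apical septal, 15 apical inferior,
#' 16 apical lateral; 17 apex.
#'
#' @param heart a `heart_geometry`.
#' @param cap_fraction long-axis fraction forming the apical cap
#'   (default 0.05).
#' @return a `segment_model`: tibble with one row per heart node
#'   (`node_id`, `surface_label`, `segment_id`, `surface_class`,
#'   `axis_fraction`, `angle_deg`) plus attribute `substitution_applied`.
#' @export
assign_aha_segments <- function(heart, cap_fraction = 0.05) {
  ax <- heart$long_axis
  sep <- heart$septal_direction
  if (sqrt(sum(ax^2)) < 1e-12 || sqrt(sum(sep^2)) < 1e-12) {
    stop("degenerate axis: `long_axis` and `septal_direction` must be non-zero")
  }
  v <- heart$mesh$vertices
  rel <- sweep(v, 2L, heart$base_center)
  z <- as.vector(rel %*% ax)             # mm toward the apex
  span <- max(z)
  frac <- pmax(0, z / span)
  # angle about the long axis, zero at septal_direction, CCW seen from base.
  # Viewed from the base means looking along +long_axis, so the CCW frame is
  # (septal, long_axis x septal).
  e2 <- pracma_cross(ax, sep)
  ang <- atan2(as.vector(rel %*% e2), as.vector(rel %*% sep)) %% (2 * pi)
  # round off float jitter so sector membership survives rigid transforms
  deg <- round(ang * 180 / pi, 6)
  deg[deg >= 360] <- 0
  frac <- round(frac, 9)

  seg <- integer(nrow(v))
  ring <- findInterval(frac, c(0, 1 / 3, 2 / 3, 1 - cap_fraction),
                       rightmost.closed = FALSE)
  # 6-sector rings: septum centre at 0 -> anteroseptal [0,60), anterior
  # [60,120), anterolateral [120,180), inferolateral [180,240), inferior
  # [240,300), inferoseptal [300,360)
  six <- c(2L, 1L, 6L, 5L, 4L, 3L)[findInterval(deg, seq(0, 300, 60))]
  # 4-sector ring: septal [-45,45), anterior [45,135), lateral [135,225),
  # inferior [225,315)
  four <- c(14L, 13L, 16L, 15L)[findInterval((deg + 45) %% 360,
                                             c(0, 90, 180, 270))]
  seg[ring == 1L] <- six[ring == 1L]
  seg[ring == 2L] <- six[ring == 2L] + 6L
  seg[ring == 3L] <- four[ring == 3L]
  seg[ring == 4L] <- 17L

  lab <- heart$mesh$labels
  surface_class <- dplyr::case_when(
    lab == "LV_ENDO" ~ "ENDO",
    lab == "EPI" ~ "EPI",
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(node_id = seq_len(nrow(v)),
                        surface_label = lab,
                        segment_id = seg,
                        surface_class = surface_class,
                        axis_fraction = frac,
                        angle_deg = deg)
  attr(out, "substitution_applied") <- FALSE
  class(out) <- c("segment_model", class(out))
  out
}

#' The five septal segments whose epicardial surface is taken from the RV
#' endocardium
#' @return integer vector of segment ids.
#' @export
rv_substitution_segments <- function() c(2L, 3L, 8L, 9L, 14L)

#' Substitute the RV endocardium for the septal "epicardium"
#'
#' The left-ventricular septum has no epicardial surface; following the
#' convention used in segment-level ECGi analyses, the RV endocardial
#' surface stands in as the "epicardial" surface of the five septal
#' segments (basal anteroseptal and inferoseptal, mid anteroseptal and
#' inferoseptal, apical septal). Affected RV nodes get surface class
#' `EPI_SURROGATE`; every other node is untouched.
#'
#' @param seg a `segment_model` from [assign_aha_segments()].
#' @param heart the matching `heart_geometry`.
#' @return the updated `segment_model` with `substitution_applied = TRUE`.
#' @export
apply_rv_septal_substitution <- function(seg, heart) {
  if (!inherits(seg, "segment_model")) stop("`seg` must be a segment_model")
  septal <- rv_substitution_segments()
  is_rv <- seg$surface_label == "RV_ENDO"
  if (!any(is_rv)) stop("no RV_ENDO nodes available for substitution")
  take <- is_rv & seg$segment_id %in% septal
  missing <- setdiff(septal, unique(seg$segment_id[take]))
  if (length(missing)) {
    stop("no RV_ENDO nodes found for septal segment(s) ",
         paste(missing, collapse = ", "))
  }
  out <- seg
  out$surface_class[take] <- "EPI_SURROGATE"
  # epicardial nodes of the septal segments are dropped from the epicardial
  # analysis surface in favour of the surrogate
  drop_epi <- seg$surface_label == "EPI" & seg$segment_id %in% septal
  out$surface_class[drop_epi] <- NA_character_
  attr(out, "substitution_applied") <- TRUE
  out
}

#' Nodes forming an analysis surface
#'
#' The endocardial analysis surface is the LV endocardium; the epicardial
#' analysis surface is the epicardium with, after substitution, RV
#' endocardial surrogates in the five septal segments.
#'
#' @param seg a `segment_model`.
#' @param surface `"ENDO"` or `"EPI"`.
#' @return integer node ids.
#' @export
analysis_surface_nodes <- function(seg, surface = c("ENDO", "EPI")) {
  surface <- match.arg(surface)
  if (surface == "ENDO") {
    seg$node_id[!is.na(seg$surface_class) & seg$surface_class == "ENDO"]
  } else {
    seg$node_id[!is.na(seg$surface_class) &
                  seg$surface_class %in% c("EPI", "EPI_SURROGATE")]
  }
}
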