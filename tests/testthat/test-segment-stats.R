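toy_maps <- function(values, seg_ids, surface = "EPI", valid = TRUE) {
  n <- length(values)
  seg <- tibble::tibble(node_id = seq_len(n),
                        surface_label = if (surface == "ENDO") "LV_ENDO"
                                        else "EPI",
                        segment_id = seg_ids,
                        surface_class = if (surface == "ENDO") "ENDO"
                                        else "EPI",
                        axis_fraction = 0.5, angle_deg = 0)
  class(seg) <- c("segment_model", class(seg))
  act <- tibble::tibble(node_id = seq_len(n), lat_ms = values,
                        valid = rep_len(valid, n))
  volt <- tibble::tibble(node_id = seq_len(n), vpp_uv = 10 * values,
                         valid = rep_len(valid, n))
  list(seg = seg, act = act, volt = volt)
}

test_that("segment summaries use the sample (n-1) standard deviation", {
  tm <- toy_maps(c(1, 2, 3, 4, 5), rep(1L, 5))
  out <- summarize_segments(tm$act, tm$volt, tm$seg)
  row <- out[out$segment_id == 1 & out$surface == "EPI", ]
  expect_equal(row$mean_lat, 3)
  expect_equal(row$sd_lat, sqrt(2.5))
  expect_equal(row$mean_vpp, 30)
  expect_equal(row$sd_vpp, 10 * sqrt(2.5))
  # all equal -> zero dispersion
  tm0 <- toy_maps(rep(7, 6), rep(2L, 6))
  out0 <- summarize_segments(tm0$act, tm0$volt, tm0$seg)
  expect_equal(out0$sd_lat[out0$segment_id == 2 & out0$surface == "EPI"], 0)
})

test_that("summaries are shift/scale equivariant and respect masks", {
  vals <- c(3, 8, 1, 9, 4, 4)
  tm <- toy_maps(vals, rep(5L, 6))
  base <- summarize_segments(tm$act, tm$volt, tm$seg)
  shifted <- toy_maps(vals + 100, rep(5L, 6))
  out_s <- summarize_segments(shifted$act, shifted$volt, shifted$seg)
  pickrow <- function(x) x[x$segment_id == 5 & x$surface == "EPI", ]
  expect_equal(pickrow(out_s)$sd_lat, pickrow(base)$sd_lat)
  scaled <- toy_maps(3 * vals, rep(5L, 6))
  out_m <- summarize_segments(scaled$act, scaled$volt, scaled$seg)
  expect_equal(pickrow(out_m)$sd_lat, 3 * pickrow(base)$sd_lat)
  # removing an already-masked node changes nothing
  tm_mask <- toy_maps(c(vals, 1e6), rep(5L, 7),
                      valid = c(rep(TRUE, 6), FALSE))
  out_mask <- summarize_segments(tm_mask$act, tm_mask$volt, tm_mask$seg)
  expect_equal(pickrow(out_mask)$sd_lat, pickrow(base)$sd_lat)
  expect_equal(pickrow(out_mask)$n_valid_nodes, 6L)
})

test_that("cells below the node minimum are reported missing", {
  tm <- toy_maps(c(1, 2), c(1L, 1L))
  out <- summarize_segments(tm$act, tm$volt, tm$seg, min_nodes = 3)
  row <- out[out$segment_id == 1 & out$surface == "EPI", ]
  expect_true(is.na(row$sd_lat))
  expect_equal(row$n_valid_nodes, 2L)
  # the full 16 + 17 grid is always present
  expect_equal(nrow(out), 33L)
})

test_that("cohort tables stack tidily and round-trip through CSV", {
  g <- small_geometry()
  set.seed(1)
  mk_summary <- function(seed) {
    set.seed(seed)
    n <- nrow(g$heart$mesh$vertices)
    act <- tibble::tibble(node_id = 1:n, lat_ms = rnorm(n, 50, 10),
                          valid = TRUE)
    volt <- tibble::tibble(node_id = 1:n, vpp_uv = rnorm(n, 900, 100),
                           valid = TRUE)
    summarize_segments(act, volt, g$seg)
  }
  sums <- lapply(1:8, mk_summary)
  names(sums) <- sprintf("subj%02d", 1:8)
  groups <- rep(c("HEALTHY", "HCM"), each = 4)
  tab <- cohort_segment_table(sums, groups)
  expect_equal(nrow(tab), 8L * 33L * 4L)
  expect_setequal(unique(tab$metric),
                  c("mean_lat", "sd_lat", "mean_vpp", "sd_vpp"))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(tab), f, row.names = FALSE)
  back <- tibble::as_tibble(utils::read.csv(f, stringsAsFactors = FALSE))
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  # per-group means agree with an independent aggregation
  m1 <- tab |>
    dplyr::filter(.data$metric == "mean_vpp", .data$segment_id == 1,
                  .data$surface == "EPI") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m = mean(.data$value)) |>
    dplyr::arrange(.data$group)
  direct <- vapply(split(seq_len(8), groups), function(idx) {
    mean(vapply(sums[idx], function(s) {
      s$mean_vpp[s$segment_id == 1 & s$surface == "EPI"]
    }, 0))
  }, 0)
  expect_equal(m1$m, unname(direct[sort(names(direct))]), tolerance = 1e-12)
  expect_error(cohort_segment_table(stats::setNames(sums[c(1, 1)],
                                                    c("a", "a")), "g"),
               "duplicate")
})
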