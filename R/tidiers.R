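#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-row content of a result
#' object as a tibble; `glance()` returns a one-row model-level summary.
#'
#' @param x a package result object.
#' @param ... unused.
#' @name tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.test_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidiers
#' @export
glance.test_result <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df,
                 p_value = x$p_value)
}

#' @rdname tidiers
#' @export
tidy.segment_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidiers
#' @export
tidy.pipeline_result <- function(x, ...) {
  x$cohort_table
}

#' @rdname tidiers
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$recovery),
    median_spearman_lat = stats::median(x$recovery$spearman_lat),
    median_lambda = stats::median(x$recovery$lambda),
    n_epi_sd_lat_significant = sum(
      x$group_tests$sd_lat$p_value < 0.05 &
        x$group_tests$sd_lat$surface == "EPI", na.rm = TRUE),
    seed = x$config$seed)
}

#' @rdname tidiers
#' @export
tidy.qc_decision <- function(x, ...) {
  tibble::tibble(decision = x$decision,
                 morphology_score = x$morphology_score,
                 downslope_diff_ms = x$downslope_diff_ms)
}
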