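#' Heteroscedastic k-sample Wald chi-squared test (James's approximation)
#'
#' Tests equality of k group means without assuming equal variances, from
#' summary statistics alone. With weights \eqn{w_i = n_i / s_i^2},
#' \eqn{W = \sum w_i} and weighted grand mean \eqn{\tilde m}, the Wald
#' statistic is \eqn{J = \sum_i w_i (m_i - \tilde m)^2}. Under the null it
#' is compared against James's first-order small-sample critical value: with
#' \eqn{\Lambda = \sum_i (1 - w_i/W)^2 / (n_i - 1)}, the p-value solves
#' \deqn{J = c_p \left[1 + \frac{(3 c_p + k + 1)\Lambda}{2(k^2 - 1)}\right]}
#' where \eqn{c_p} is the upper-p quantile of the chi-squared distribution
#' with k-1 degrees of freedom. The equation is quadratic in \eqn{c_p};
#' the positive root is inverted through the chi-squared survival function.
#'
#' @param means,sds,ns numeric vectors of group means, standard deviations
#'   and sizes (k >= 2; all `ns >= 2`, all `sds > 0`). Alternatively pass a
#'   data frame as `means` with columns `mean`, `sd`, `n` (tidy-style
#'   summary input).
#' @return a `test_result` (also a tibble): `statistic`, `df`, `p_value`,
#'   `method`.
#' @examples
#' james_test(c(842, 898, 934, 1094), c(90, 358, 189, 211), rep(10, 4))
#' @export
james_test <- function(means, sds = NULL, ns = NULL) {
  g <- as_group_summary(means, sds, ns)
  k <- nrow(g)
  w <- g$n / g$sd^2
  W <- sum(w)
  m_tilde <- sum(w * g$mean) / W
  J <- sum(w * (g$mean - m_tilde)^2)
  Lambda <- sum((1 - w / W)^2 / (g$n - 1))
  A <- 3 * Lambda / (2 * (k^2 - 1))
  B <- 1 + (k + 1) * Lambda / (2 * (k^2 - 1))
  c_p <- if (A > 0) (-B + sqrt(B^2 + 4 * A * J)) / (2 * A) else J / B
  p <- stats::pchisq(c_p, df = k - 1, lower.tail = FALSE)
  new_test_result(statistic = J, df = k - 1, p_value = p, method = "JAMES1")
}

as_group_summary <- function(means, sds, ns) {
  if (is.data.frame(means)) {
    g <- tibble::tibble(mean = means$mean, sd = means$sd, n = means$n)
  } else {
    g <- tibble::tibble(mean = as.double(means), sd = as.double(sds),
                        n = as.double(ns))
  }
  if (nrow(g) < 2L) stop("need at least 2 groups")
  if (any(g$n < 2)) stop("each group needs n >= 2")
  if (any(g$sd <= 0)) stop("degenerate variance: every group needs sd > 0")
  g
}

new_test_result <- function(statistic, df, p_value, method) {
  out <- tibble::tibble(statistic = statistic, df = df, p_value = p_value,
                        method = method)
  class(out) <- c("test_result", class(out))
  out
}

#' Welch's heteroscedastic one-way ANOVA from summary statistics
#'
#' Companion cross-check to [james_test()] on the same Wald statistic J:
#' \deqn{F = \frac{J/(k-1)}{1 + 2(k-2)\Lambda/(k^2-1)}, \quad
#'       df_2 = \frac{k^2-1}{3\Lambda}.}
#'
#' @inheritParams james_test
#' @return a `test_result` with method `"WELCH"` and fractional `df`.
#' @export
welch_anova <- function(means, sds = NULL, ns = NULL) {
  g <- as_group_summary(means, sds, ns)
  k <- nrow(g)
  w <- g$n / g$sd^2
  W <- sum(w)
  m_tilde <- sum(w * g$mean) / W
  J <- sum(w * (g$mean - m_tilde)^2)
  Lambda <- sum((1 - w / W)^2 / (g$n - 1))
  Fstat <- (J / (k - 1)) / (1 + 2 * (k - 2) * Lambda / (k^2 - 1))
  df2 <- (k^2 - 1) / (3 * Lambda)
  p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
  new_test_result(statistic = Fstat, df = df2, p_value = p,
                  method = "WELCH")
}

#' Kruskal-Wallis rank test
#'
#' Rank-based k-sample test of the hypothesis that all groups are drawn
#' from the same population, with the standard tie correction and the
#' chi-squared (k-1 df) reference distribution. For small pooled samples
#' (`n <= exact_n_max`) an exact permutation p-value over all group-label
#' assignments is available.
#'
#' @param samples list of numeric vectors, one per group.
#' @param exact logical; compute the exact permutation p-value.
#' @param exact_n_max largest pooled n for which `exact = TRUE` is allowed
#'   (default 10).
#' @return a `test_result` with method `"KRUSKAL_WALLIS"`; when `exact`,
#'   an extra column `p_exact`.
#' @export
kruskal_wallis <- function(samples, exact = FALSE, exact_n_max = 10L) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("`samples` must be a list of >= 2 groups")
  }
  if (any(lengths(samples) == 0L)) stop("all groups must be non-empty")
  H <- kw_statistic(samples)
  k <- length(samples)
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  if (sum(lengths(samples)) > 0 &&
      isTRUE(all.equal(H, 0))) p <- 1
  out <- new_test_result(statistic = H, df = k - 1, p_value = p,
                         method = "KRUSKAL_WALLIS")
  if (exact) {
    n_tot <- sum(lengths(samples))
    if (n_tot > exact_n_max) {
      stop("exact permutation limited to pooled n <= ", exact_n_max)
    }
    out$p_exact <- kw_exact_p(samples, H)
  }
  out
}

kw_statistic <- function(samples) {
  x <- unlist(samples, use.names = FALSE)
  gsizes <- lengths(samples)
  n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(samples), gsizes)
  Rj <- vapply(split(r, idx), sum, 0)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / gsizes) - 3 * (n + 1)
  # tie correction
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(0)
  H / corr
}

# exact permutation distribution over all assignments of pooled values to
# groups of the observed sizes
kw_exact_p <- function(samples, H_obs) {
  x <- unlist(samples, use.names = FALSE)
  sizes <- lengths(samples)
  n <- length(x)
  perms <- all_group_assignments(n, sizes)
  Hs <- vapply(perms, function(assign) {
    kw_statistic(split(x, assign))
  }, 0)
  mean(Hs >= H_obs - 1e-12)
}

all_group_assignments <- function(n, sizes) {
  # enumerate multiset permutations of group labels
  recurse <- function(remaining, sizes_left) {
    if (length(remaining) == 0L) return(list(integer(0)))
    out <- list()
    for (g in seq_along(sizes_left)) {
      if (sizes_left[g] == 0L) next
      s2 <- sizes_left
      s2[g] <- s2[g] - 1L
      sub <- recurse(remaining[-1L], s2)
      out <- c(out, lapply(sub, function(v) c(g, v)))
    }
    out
  }
  recurse(seq_len(n), sizes)
}

#' Normality-aware group summary formatting
#'
#' Screens each group with a Shapiro-Wilk test at `alpha`; when every group
#' is compatible with normality the variable is summarized as
#' `mean +/- SD`, otherwise as `median (Q1-Q3)` with linear-interpolation
#' quantiles (type 7).
#'
#' @param values numeric vector.
#' @param by optional grouping factor; when given, one row per group.
#' @param alpha normality screen level (default 0.05).
#' @return tibble with `group`, `normal`, `format`, `label`, and the
#'   underlying statistics.
#' @export
summarize_variable <- function(values, by = NULL, alpha = 0.05) {
  if (is.null(by)) by <- rep("all", length(values))
  tb <- tibble::tibble(value = values, group = as.character(by)) |>
    tidyr::drop_na()
  norm <- tb |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(normal = shapiro_normal(.data$value, alpha),
                     .groups = "drop")
  all_normal <- all(norm$normal)
  tb |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value), sd = stats::sd(.data$value),
                     median = stats::median(.data$value),
                     q1 = stats::quantile(.data$value, 0.25, names = FALSE),
                     q3 = stats::quantile(.data$value, 0.75, names = FALSE),
                     .groups = "drop") |>
    dplyr::left_join(norm, by = "group") |>
    dplyr::mutate(
      format = if (all_normal) "mean_sd" else "median_iqr",
      label = if (all_normal) {
        sprintf("%.4g ± %.3g", .data$mean, .data$sd)
      } else {
        sprintf("%.4g (%.4g–%.4g)", .data$median, .data$q1, .data$q3)
      })
}

shapiro_normal <- function(x, alpha) {
  if (length(x) < 3L) return(NA)
  if (stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

#' Per-segment group comparison of a cohort metric
#'
#' Applies the appropriate k-group test per (segment, surface) row of a
#' tidy cohort table: [james_test()] on per-group summary statistics for
#' mean-level metrics (`mean_vpp`, `mean_lat`), and [kruskal_wallis()] on
#' the raw per-subject values for dispersion metrics (`sd_vpp`, `sd_lat`),
#' which are not normally distributed. P-values are reported unadjusted;
#' `adjust = "BH"` adds a Benjamini-Hochberg column.
#'
#' @param cohort tidy table from [cohort_segment_table()].
#' @param metric one of `"mean_vpp"`, `"mean_lat"`, `"sd_vpp"`, `"sd_lat"`.
#' @param test `"auto"` (James for means, Kruskal-Wallis for dispersions),
#'   `"james"` or `"kw"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return tibble with one row per (surface, segment): test statistic,
#'   `p_value`, `method`, `testable`.
#' @export
compare_groups_per_segment <- function(cohort, metric,
                                       test = c("auto", "james", "kw"),
                                       adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (test == "auto") {
    test <- if (grepl("^mean", metric)) "james" else "kw"
  }
  metric_name <- metric
  rows <- cohort |>
    dplyr::filter(.data$metric == metric_name, !is.na(.data$value)) |>
    dplyr::group_by(.data$surface, .data$segment_id)
  n_groups <- length(unique(cohort$group))
  res <- rows |>
    dplyr::group_modify(function(d, key) {
      groups <- split(d$value, d$group)
      if (length(groups) < n_groups || any(lengths(groups) < 2L)) {
        return(tibble::tibble(statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_, method = NA_character_,
                              testable = FALSE))
      }
      r <- if (test == "james") {
        sds <- vapply(groups, stats::sd, 0)
        if (any(sds <= 0)) {
          return(tibble::tibble(statistic = NA_real_, df = NA_real_,
                                p_value = NA_real_, method = NA_character_,
                                testable = FALSE))
        }
        james_test(vapply(groups, mean, 0), sds, lengths(groups))
      } else {
        kruskal_wallis(groups)
      }
      tibble::tibble(statistic = r$statistic, df = r$df,
                     p_value = r$p_value, method = r$method,
                     testable = TRUE)
    }) |>
    dplyr::ungroup()
  if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  }
  res
}
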