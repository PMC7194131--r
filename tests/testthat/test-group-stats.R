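# reference four-group voltage summary (epicardial basal anterior row of
# the bundled fixture): means, SDs, n = 10 per group, reported p = 0.023
ref_row <- list(means = c(842, 898, 934, 1094),
                sds = c(90, 358, 189, 211),
                ns = rep(10, 4))

# raw samples with exactly the requested mean and SD
exact_moment_sample <- function(mean, sd, n, seed) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}

test_that("james test reproduces the published p on printed summaries", {
  r <- james_test(ref_row$means, ref_row$sds, ref_row$ns)
  expect_lt(abs(r$p_value - 0.023), 0.01)
  expect_equal(r$df, 3)
  expect_equal(r$method, "JAMES1")
})

test_that("james test degenerates and errors as specified", {
  r0 <- james_test(c(5, 5, 5), c(1, 2, 3), c(10, 10, 10))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(james_test(c(1, 2), c(1, 0), c(5, 5)), "sd > 0")
  expect_error(james_test(c(1, 2), c(1, 1), c(5, 1)), "n >= 2")
  expect_error(james_test(1, 1, 5), "2 groups")
})

test_that("james test is location and scale invariant", {
  base <- james_test(ref_row$means, ref_row$sds, ref_row$ns)
  shift <- james_test(ref_row$means + 500, ref_row$sds, ref_row$ns)
  expect_equal(shift$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(shift$p_value, base$p_value, tolerance = 1e-12)
  scale <- james_test(3 * ref_row$means, 3 * ref_row$sds, ref_row$ns)
  expect_equal(scale$statistic, base$statistic, tolerance = 1e-10)
  expect_equal(scale$p_value, base$p_value, tolerance = 1e-10)
})

test_that("two-group james agrees with an independent Welch t-test", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- rnorm(2, 10, 2)
    s <- runif(2, 0.5, 4)
    n <- sample(5:20, 2)
    x1 <- exact_moment_sample(m[1], s[1], n[1], seed)
    x2 <- exact_moment_sample(m[2], s[2], n[2], seed + 100)
    p_ref <- stats::t.test(x1, x2)$p.value
    p_james <- james_test(m, s, n)$p_value
    expect_lt(abs(p_james - p_ref), 0.005)
  }
})

test_that("welch anova matches james on summaries and stats::oneway.test", {
  r_j <- james_test(ref_row$means, ref_row$sds, ref_row$ns)
  r_w <- welch_anova(ref_row$means, ref_row$sds, ref_row$ns)
  expect_lt(abs(r_w$p_value - r_j$p_value), 0.01)
  expect_equal(r_w$method, "WELCH")
  # against the reference implementation on exact-moment raw data
  xs <- purrr::pmap(list(ref_row$means, ref_row$sds, ref_row$ns, 1:4),
                    function(m, s, n, seed) exact_moment_sample(m, s, n, seed))
  dat <- data.frame(y = unlist(xs),
                    g = factor(rep(seq_len(4), times = ref_row$ns)))
  p_ref <- stats::oneway.test(y ~ g, dat, var.equal = FALSE)$p.value
  expect_equal(r_w$p_value, p_ref, tolerance = 1e-10)
  # equal variances, large n: converges to the fixed-effects F test
  set.seed(9)
  means <- c(10, 10.1, 9.95, 10.05)
  xs <- purrr::imap(means, function(m, i) exact_moment_sample(m, 2, 1000, i))
  dat <- data.frame(y = unlist(xs), g = factor(rep(1:4, each = 1000)))
  p_fixed <- stats::oneway.test(y ~ g, dat, var.equal = TRUE)$p.value
  p_w <- welch_anova(means, rep(2, 4), rep(1000, 4))$p_value
  expect_lt(abs(p_w - p_fixed), 0.01)
  expect_equal(welch_anova(c(1, 1, 1), 1:3, c(9, 9, 9))$p_value, 1)
})

test_that("kruskal-wallis reproduces the hand-ranked worked example", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  # identical distributions: duplicated group
  r0 <- kruskal_wallis(list(c(2, 4, 9), c(2, 4, 9)))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("kruskal-wallis matches stats::kruskal.test including ties", {
  set.seed(3)
  for (k in 1:4) {
    xs <- list(sample(1:6, 7, TRUE), sample(1:6, 5, TRUE),
               sample(1:6, 6, TRUE))
    ours <- kruskal_wallis(xs)
    ref <- stats::kruskal.test(xs)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("chi-squared p tracks the exact permutation p at n = 9", {
  xs <- list(c(1.2, 3.1, 2.2), c(2.8, 4.7, 5.1), c(6.3, 4.9, 7.2))
  r <- kruskal_wallis(xs, exact = TRUE)
  expect_lt(abs(r$p_value - r$p_exact), 0.05)
  expect_error(kruskal_wallis(list(1:6, 1:6), exact = TRUE), "pooled n")
})

test_that("kruskal-wallis is invariant under monotone transformations", {
  set.seed(11)
  xs <- list(rnorm(8, 0), rnorm(8, 1), rnorm(8, 0.5), rnorm(8, 2))
  H0 <- kruskal_wallis(xs)$statistic
  expect_equal(kruskal_wallis(lapply(xs, exp))$statistic, H0,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(lapply(xs, function(v) 5 * v - 2))$statistic,
               H0, tolerance = 1e-12)
})

test_that("summary formatting follows a seeded normality screen", {
  set.seed(21)
  normal <- rnorm(100)
  out_n <- summarize_variable(normal)
  expect_equal(out_n$format, "mean_sd")
  set.seed(22)
  skewed <- exp(rnorm(100, sd = 1.5))
  out_s <- summarize_variable(skewed)
  expect_equal(out_s$format, "median_iqr")
  out_q <- summarize_variable(c(1, 2, 3, 4, 5))
  expect_equal(out_q$median, 3)
  expect_equal(out_q$q1, 2)
  expect_equal(out_q$q3, 4)
})

test_that("james test holds its type-I error under heteroscedasticity", {
  set.seed(31)
  k <- 4
  n <- 10
  sds <- c(1, 2, 3, 4)  # variance ratio up to 16
  n_sim <- 2000
  rej <- 0
  for (i in seq_len(n_sim)) {
    m <- numeric(k)
    s <- numeric(k)
    for (g in seq_len(k)) {
      x <- rnorm(n, 0, sds[g])
      m[g] <- mean(x)
      s[g] <- stats::sd(x)
    }
    if (james_test(m, s, rep(n, k))$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_sim, 0.03)
  expect_lte(rej / n_sim, 0.08)
})

test_that("per-segment comparisons run the right test and handle nulls", {
  set.seed(41)
  mk_table <- function(shift_hcm) {
    grid <- expand.grid(subject = 1:10,
                        group = c("HEALTHY", "POSTMI_NOVT", "POSTMI_VT",
                                  "HCM"),
                        segment_id = 1:8, surface = "EPI",
                        stringsAsFactors = FALSE)
    grid$subject <- paste(grid$group, grid$subject)
    grid$metric <- "sd_lat"
    grid$value <- rnorm(nrow(grid), 10, 2) +
      ifelse(grid$group == "HCM", shift_hcm, 0)
    tibble::as_tibble(grid)
  }
  null_tab <- mk_table(0)
  res <- compare_groups_per_segment(null_tab, "sd_lat")
  expect_equal(res$method, rep("KRUSKAL_WALLIS", 8))
  expect_true(all(res$testable))
  strong <- mk_table(6)
  res2 <- compare_groups_per_segment(strong, "sd_lat")
  expect_true(all(res2$p_value < 0.01))
  # permuting group labels destroys the effect
  perm <- strong
  set.seed(42)
  perm$group <- sample(perm$group)
  res3 <- compare_groups_per_segment(perm, "sd_lat")
  expect_gt(stats::median(res3$p_value), 0.2)
  # a missing group makes the row not testable
  part <- dplyr::filter(strong, !(.data$group == "HCM" &
                                    .data$segment_id == 1))
  res4 <- compare_groups_per_segment(part, "sd_lat")
  expect_false(res4$testable[res4$segment_id == 1])
  # james route on mean metrics, with optional BH adjustment
  mean_tab <- dplyr::mutate(strong, metric = "mean_vpp")
  res5 <- compare_groups_per_segment(mean_tab, "mean_vpp", adjust = "BH")
  expect_equal(unique(res5$method), "JAMES1")
  expect_true(all(res5$p_adjusted >= res5$p_value - 1e-15))
})

test_that("segment-wise type-I error stays near nominal", {
  set.seed(51)
  n_rep <- 200
  pvals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    xs <- lapply(1:4, function(g) rnorm(10, 5, 1.5))
    pvals[i] <- kruskal_wallis(xs)$p_value
  }
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})
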