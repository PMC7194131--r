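synthetic_leads <- function(onset_ms = 100, fs = 1000, dur_ms = 400,
                            amp = 1000, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur_ms - 1, by = 1000 / fs)
  qrs <- function(a) {
    y <- numeric(length(t))
    act <- t >= onset_ms & t < onset_ms + 80
    y[act] <- a * sin(pi * (t[act] - onset_ms) / 80)^2
    y + rnorm(length(t), sd = 2)
  }
  rbind(qrs(amp), qrs(-0.8 * amp), qrs(0.6 * amp))
}

test_that("QRS onset detection finds a known onset and rejects noise", {
  L <- synthetic_leads(onset_ms = 100)
  expect_equal(detect_qrs_onset(L, 1000), 100, tolerance = 5)
  # constant offsets do not move a derivative-based onset
  expect_equal(detect_qrs_onset(L + 500, 1000),
               detect_qrs_onset(L, 1000))
  set.seed(2)
  flat <- matrix(rnorm(3 * 400, sd = 2), 3)
  expect_error(detect_qrs_onset(flat, 1000), "not found")
})

test_that("steepest downslope matches the analytic tanh minimum", {
  fs <- 1000
  t <- seq(0, 100, by = 1000 / fs)
  v <- 1 - tanh((t - 50) / 5)
  expect_equal(steepest_downslope(v, fs), 50, tolerance = 1.5)
  # linear ramp: constant slope, tie broken to the earliest window sample
  # (the smoothing half-window at the trace edge is flat by construction)
  ramp <- -0.5 * t
  expect_lte(steepest_downslope(ramp, fs), 5)
  expect_equal(steepest_downslope(ramp, fs, window = c(20, 60)), 20)
  expect_error(steepest_downslope(rep(3, 50), fs), "constant")
  expect_error(steepest_downslope(v, fs, window = c(500, 600)), "window")
})

test_that("LAT is the downslope-onset difference and is affine-invariant", {
  expect_equal(local_activation_time(120, 100), 20)
  expect_equal(local_activation_time(100, 100), 0)
  fs <- 1000
  t <- seq(0, 100, by = 1000 / fs)
  v <- 1 - tanh((t - 42) / 4)
  d0 <- steepest_downslope(v, fs)
  expect_equal(steepest_downslope(3.7 * v + 55, fs), d0)
})

test_that("peak-to-peak voltage behaves analytically", {
  expect_equal(peak_to_peak_voltage(rep(5, 100)), 0)
  fs <- 1000
  t <- seq(0, 999, by = 1)
  A <- 340
  expect_equal(peak_to_peak_voltage(A * sin(2 * pi * t / 1000)), 2 * A,
               tolerance = 1e-3 * A)
  # scaling and baseline shift
  v <- A * sin(2 * pi * t / 500)
  expect_equal(peak_to_peak_voltage(3 * v + 100),
               3 * peak_to_peak_voltage(v), tolerance = 1e-9)
  expect_error(peak_to_peak_voltage(v, 1000, window = c(2000, 3000)),
               "empty")
})

test_that("bipolar electrograms are antisymmetric differences", {
  u1 <- sin(seq(0, 10, 0.1))
  u2 <- cos(seq(0, 10, 0.1))
  expect_equal(bipolar_egm(u1, u1), rep(0, length(u1)))
  expect_equal(bipolar_egm(u1, u2), -bipolar_egm(u2, u1))
  expect_error(bipolar_egm(u1, u2[-1]), "equal length")
})

test_that("neighbour QC classifies agreement, shift and noise", {
  fs <- 1000
  t <- seq(0, 299, by = 1000 / fs)
  tpl <- function(shift) 1000 * (1 - tanh((t - 150 - shift) / 6)) / 2
  d_same <- qc_neighbor_agreement(tpl(0), tpl(0), fs)
  expect_equal(d_same$decision, "ACCEPT")
  expect_gt(d_same$morphology_score, 0.99)
  # same morphology shifted beyond tau: recompute
  d_shift <- qc_neighbor_agreement(tpl(0), tpl(25), fs, max_lag_ms = 40)
  expect_equal(d_shift$decision, "RECOMPUTE")
  expect_gt(d_shift$downslope_diff_ms, 10)
  # decision symmetry for accept/exclude
  set.seed(1)
  n_excl <- 0
  for (k in 1:100) {
    a <- rnorm(200)
    b <- rnorm(200)
    d1 <- qc_neighbor_agreement(a, b, fs)
    d2 <- qc_neighbor_agreement(b, a, fs)
    expect_identical(d1$decision, d2$decision)
    if (d1$decision == "EXCLUDE") n_excl <- n_excl + 1
  }
  expect_gte(n_excl, 95)
})

test_that("map extraction propagates masks and flags heavy exclusion", {
  g <- small_geometry()
  s <- small_subject("HEALTHY", seed = 42, snr_db = Inf)
  X <- unclass(s$heart_potentials)
  attr(X, "sampling_rate") <- attr(s$heart_potentials, "sampling_rate")
  maps <- compute_maps(X, qrs_onset = 100, heart = g$heart, qc = TRUE)
  # a noise-free synthetic beat keeps every node
  expect_true(all(maps$activation$valid))
  expect_true(all(maps$voltage$valid))
  expect_equal(cor(maps$activation$lat_ms, s$field$lat_true,
                   method = "spearman"), 1, tolerance = 0.002)
  # corrupt one node: it must drop out of both maps
  Xbad <- X
  set.seed(5)
  Xbad[37, ] <- rnorm(ncol(X), sd = 500)
  maps2 <- compute_maps(Xbad, 100, heart = g$heart, qc = TRUE)
  expect_false(maps2$activation$valid[37])
  expect_false(maps2$voltage$valid[37])
  expect_true(mean(maps2$activation$valid) > 0.95)
})
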