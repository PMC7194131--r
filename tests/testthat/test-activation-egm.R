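# minimal path-like geometry: 3 collinear surface nodes 10 mm apart plus a
# slightly off-axis helper vertex so the mesh has faces
path_heart <- function() {
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(10, 0.01, 0))
  mesh <- triangle_mesh(v, rbind(c(1, 2, 4), c(2, 3, 4)), rep("EPI", 4))
  heart_geometry(mesh, apex_point = 3L, base_center = c(0, 0, 0),
                 long_axis = c(1, 0, 0), septal_direction = c(0, 1, 0))
}

test_that("geodesic activation reproduces a hand-computed path", {
  hg <- path_heart()
  f <- simulate_activation(hg, pacing_sites = 1L, cv_map = 1,
                           transmural_reach = 0)
  expect_equal(f$lat_true[1], 0)
  expect_equal(f$lat_true[2], 10, tolerance = 1e-6)
  expect_equal(f$lat_true[3], 20, tolerance = 1e-4)
  # halving conduction velocity doubles every LAT
  f2 <- simulate_activation(hg, 1L, cv_map = 0.5, transmural_reach = 0)
  expect_equal(f2$lat_true, 2 * f$lat_true, tolerance = 1e-9)
  expect_error(simulate_activation(hg, integer(0), 1), "pacing")
  expect_error(simulate_activation(hg, 1L, -1), "positive")
})

test_that("harmonic-mean edge cost mixes heterogeneous velocities", {
  hg <- path_heart()
  cv <- c(1, 1, 0.25, 1)
  f <- simulate_activation(hg, 1L, cv, transmural_reach = 0)
  # edge 2-3: 10 mm at harmonic mean of (1, 0.25) = 0.4 -> 25 ms
  expect_equal(f$lat_true[3], 10 + 25, tolerance = 1e-4)
})

test_that("synthesized electrograms encode amplitude and timing", {
  hg <- path_heart()
  f <- simulate_activation(hg, 1L, 1, transmural_reach = 0)
  tpl <- egm_template(sampling_rate = 2048)
  hp <- synthesize_heart_potentials(f, tpl, amplitudes = 1000)
  fs <- attr(hp, "sampling_rate")
  for (i in 1:3) {
    expect_equal(peak_to_peak_voltage(hp[i, ]), 1000, tolerance = 0.01)
    ds <- steepest_downslope(hp[i, ], fs)
    expect_equal(ds, 100 + f$lat_true[i], tolerance = 1000 / fs + 1e-9)
  }
  # zero amplitude -> flat trace
  hp0 <- synthesize_heart_potentials(f, tpl, amplitudes = 0)
  expect_equal(max(abs(hp0[1, ])), 0)
  # activation beyond the window errors
  f_far <- f
  f_far$lat_true[3] <- 400
  expect_error(synthesize_heart_potentials(f_far, tpl, 1000), "window")
})

test_that("recordings honour the requested signal-to-noise ratio", {
  s <- small_subject("HEALTHY", seed = 42, snr_db = Inf)
  g <- small_geometry()
  # snr = Inf equals the exact forward projection
  proj <- forward_project(unclass(s$heart_potentials), g$transfer)
  expect_equal(s$recording$potentials, proj, tolerance = 1e-12)
  # same seed -> identical noisy recording
  r1 <- make_body_surface_recording(s$heart_potentials, g$transfer, 20, seed = 9)
  r2 <- make_body_surface_recording(s$heart_potentials, g$transfer, 20, seed = 9)
  expect_identical(r1$potentials, r2$potentials)
  # empirical SNR within +/- 1 dB of the request across seeds
  qrs <- r1$qrs_window
  sig <- mean(proj[, qrs[1]:qrs[2]]^2)
  snrs <- vapply(1:30, function(sd) {
    r <- make_body_surface_recording(s$heart_potentials, g$transfer, 20,
                                     seed = sd)
    noise <- r$potentials - proj
    10 * log10(sig / mean(noise^2))
  }, 0)
  expect_equal(mean(snrs), 20, tolerance = 1)
  expect_error(make_body_surface_recording(s$heart_potentials, g$transfer,
                                           NaN), "finite")
})

test_that("cohort generation is reproducible bookkeeping", {
  g <- small_geometry()
  spec <- cohort_spec(n_subjects = 2L, seed = 3)
  co1 <- generate_cohort(spec, g$heart, g$torso, g$transfer, seg = g$seg)
  expect_length(co1$subjects, 8L)
  expect_equal(unname(table(vapply(co1$subjects, `[[`, "", "group"))),
               rep(2L, 4L), ignore_attr = TRUE)
  co2 <- generate_cohort(spec, g$heart, g$torso, g$transfer, seg = g$seg)
  expect_identical(co1$subjects$HCM_01$recording$potentials,
                   co2$subjects$HCM_01$recording$potentials)
  expect_error(cohort_spec(groups = "NOSUCH"), "unknown group")
})

test_that("group presets order truth dispersion and amplitude as designed", {
  g <- small_geometry()
  seg <- g$seg
  basal_epi <- !is.na(seg$surface_class) &
    seg$surface_class %in% c("EPI", "EPI_SURROGATE") & seg$segment_id %in% 1:6
  pacing <- pick_pacing_sites(g$heart, seg)
  basal_sd <- function(preset, seed) {
    set.seed(seed)
    p <- group_presets()[[preset]]
    cv <- ecgimap:::subject_cv_map(g$heart, seg, p, NULL)
    f <- simulate_activation(g$heart, pacing, cv, seed = seed)
    stats::sd(f$lat_true[basal_epi])
  }
  for (seed in 1:5) {
    expect_gt(basal_sd("HCM", seed), basal_sd("HEALTHY", seed))
  }
  # amplitude presets follow the study's group means
  pr <- group_presets()
  expect_equal(pr$HEALTHY$amp_mean, 842)
  expect_equal(pr$HCM$amp_mean, 1094)
  expect_gt(pr$HCM$amp_within_sd, pr$HEALTHY$amp_within_sd)
})

test_that("deepening a slow patch raises that region's true dispersion", {
  g <- small_geometry()
  seg <- g$seg
  pacing <- pick_pacing_sites(g$heart, seg)
  region_sd <- function(factor) {
    set.seed(8)
    p <- utils::modifyList(group_presets()$POSTMI_NOVT,
                           list(patch_factor = factor, cv_noise_sd = 0))
    cv <- ecgimap:::subject_cv_map(g$heart, seg, p, NULL)
    f <- simulate_activation(g$heart, pacing, cv, seed = 8)
    anteroseptal <- seg$segment_id %in% c(2L, 8L)
    stats::sd(f$lat_true[anteroseptal])
  }
  sds <- vapply(c(0.8, 0.5, 0.3), region_sd, 0)
  expect_true(all(diff(sds) > 0))
})
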