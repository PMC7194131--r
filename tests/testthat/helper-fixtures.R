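# Shared fixtures, built once per test session and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# concentric icospheres wrapped as heart/torso for BEM tests
sphere_pair <- function(subdiv = 3, a = 50, b = 150) {
  fixture(sprintf("spheres_%d_%g_%g", subdiv, a, b), function() {
    heart <- list(mesh = make_icosphere(subdiv, a))
    torso <- list(mesh = make_icosphere(subdiv, b, label = "TORSO"),
                  electrode_vertex_ids = NULL, limb_lead_ids = NULL)
    sys <- build_bem_system(heart, torso)
    list(heart = heart, torso = torso, system = sys,
         transfer = build_transfer_matrix(sys))
  })
}

# reduced-resolution default geometry shared across the heavier tests
small_geometry <- function() {
  fixture("small_geometry", function() {
    heart <- make_synthetic_heart(1000, seed = 1)
    torso <- make_synthetic_torso(heart)
    sys <- build_bem_system(heart, torso)
    transfer <- cache_svd(build_transfer_matrix(sys))
    seg <- apply_rv_septal_substitution(assign_aha_segments(heart), heart)
    list(heart = heart, torso = torso, system = sys, transfer = transfer,
         seg = seg)
  })
}

# one simulated subject on the shared geometry
small_subject <- function(preset = "HEALTHY", seed = 42, snr_db = 30) {
  key <- sprintf("subject_%s_%d_%s", preset, seed, format(snr_db))
  fixture(key, function() {
    g <- small_geometry()
    set.seed(seed)
    p <- group_presets()[[preset]]
    cv <- ecgimap:::subject_cv_map(g$heart, g$seg, p, NULL)
    amp <- ecgimap:::subject_amplitudes(g$heart, g$seg, p)
    pacing <- pick_pacing_sites(g$heart, g$seg)
    field <- simulate_activation(g$heart, pacing, cv, seed = seed)
    hp <- synthesize_heart_potentials(field, egm_template(), amp)
    rec <- make_body_surface_recording(hp, g$transfer, snr_db = snr_db,
                                       seed = seed)
    list(field = field, amplitudes = amp, heart_potentials = hp,
         recording = rec)
  })
}

# zonal (Legendre) harmonic of degree l on unit direction cos(theta)
legendre_zonal <- function(l, ct) {
  switch(l + 1L,
         rep(1, length(ct)),
         ct,
         (3 * ct^2 - 1) / 2,
         (5 * ct^3 - 3 * ct) / 2,
         (35 * ct^4 - 30 * ct^2 + 3) / 8)
}

# relative L2 error of the BEM harmonic transfer against the closed form
harmonic_transfer_error <- function(pair, l, a = 50, b = 150) {
  hm <- pair$heart$mesh
  tm <- pair$torso$mesh
  phi <- legendre_zonal(l, hm$vertices[, 3L] / a)
  out <- pair$transfer$torso_entries %*% phi
  expect <- analytic_sphere_transfer(l, a, b) *
    legendre_zonal(l, tm$vertices[, 3L] / b)
  sqrt(sum((out - expect)^2) / sum(expect^2))
}
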