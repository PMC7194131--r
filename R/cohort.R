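#' Group presets for the synthetic four-group cohort
#'
#' Default generator settings for the four study groups. Conduction and
#' amplitude parameters encode the qualitative group structure the analysis
#' targets: healthy hearts conduct homogeneously with low voltage spread;
#' both post-infarction groups carry a slow-conducting scar patch
#' (anteroseptal in the VT-free preset; anteroseptal or inferoposterior in
#' the VT preset) over globally slowed conduction; the hypertrophic
#' cardiomyopathy preset carries a slow-conducting basal band plus elevated,
#' widely dispersed voltages. Amplitude means and between-subject spreads
#' (microvolts) follow the epicardial basal-anterior summary row of the
#' study population (842 +/- 90 healthy, 898 +/- 358 and 934 +/- 189
#' post-MI, 1094 +/- 211 HCM); within-subject voltage spread follows the
#' corresponding voltage-dispersion medians (110, 158, 189, 215 uV).
#'
#' @return named list of per-group parameter lists.
#' @export
group_presets <- function() {
  list(
    HEALTHY = list(
      cv_base = 1.7, cv_noise_sd = 0.06, cv_subject_sd = 0.05,
      basal_slow_factor = 1, patch = "none", patch_factor = 1,
      amp_mean = 842, amp_between_sd = 90, amp_within_sd = 110),
    POSTMI_NOVT = list(
      cv_base = 1.45, cv_noise_sd = 0.13, cv_subject_sd = 0.07,
      basal_slow_factor = 0.85, patch = "anteroseptal", patch_factor = 0.4,
      amp_mean = 898, amp_between_sd = 358, amp_within_sd = 158),
    POSTMI_VT = list(
      cv_base = 1.35, cv_noise_sd = 0.15, cv_subject_sd = 0.07,
      basal_slow_factor = 0.8, patch = "mixed", patch_factor = 0.35,
      amp_mean = 934, amp_between_sd = 189, amp_within_sd = 189),
    HCM = list(
      cv_base = 1.4, cv_noise_sd = 0.16, cv_subject_sd = 0.07,
      basal_slow_factor = 0.45, patch = "none", patch_factor = 1,
      amp_mean = 1094, amp_between_sd = 211, amp_within_sd = 215)
  )
}

#' Cohort specification
#'
#' @param n_subjects subjects per group (scalar or named vector).
#' @param groups group names (default all four presets).
#' @param snr_db measurement noise level (default 30 dB).
#' @param overrides named list of per-group preset overrides.
#' @param seed master seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 10L, groups = names(group_presets()),
                        snr_db = 30, overrides = list(), seed = 1L) {
  presets <- group_presets()
  bad <- setdiff(groups, names(presets))
  if (length(bad)) stop("unknown group name(s): ", paste(bad, collapse = ", "))
  if (is.null(names(n_subjects))) {
    n_subjects <- stats::setNames(rep_len(n_subjects, length(groups)), groups)
  }
  if (any(n_subjects < 1L)) stop("n_subjects must be >= 1")
  for (g in names(overrides)) {
    presets[[g]] <- utils::modifyList(presets[[g]], overrides[[g]])
  }
  structure(list(groups = groups, n_subjects = n_subjects,
                 presets = presets[groups], snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sinus-rhythm pacing sites
#'
#' Deterministic septal endocardial breakthrough sites: three LV
#' endocardial nodes spread along the septal aspect and one RV endocardial
#' node, emulating normal septal-first activation.
#'
#' @param heart a `heart_geometry`.
#' @param seg optional precomputed `segment_model`.
#' @return integer vertex ids.
#' @export
pick_pacing_sites <- function(heart, seg = NULL) {
  if (is.null(seg)) seg <- assign_aha_segments(heart)
  septal <- abs(((seg$angle_deg + 180) %% 360) - 180) <= 40
  lv <- which(seg$surface_label == "LV_ENDO" & septal &
                seg$axis_fraction > 0.25 & seg$axis_fraction < 0.75)
  rv <- which(seg$surface_label == "RV_ENDO" & septal &
                seg$axis_fraction > 0.3 & seg$axis_fraction < 0.6)
  if (!length(lv)) stop("no septal LV endocardial nodes found")
  lv_pick <- lv[order(seg$axis_fraction[lv])]
  lv_pick <- lv_pick[unique(round(seq(1, length(lv_pick), length.out = 3)))]
  c(lv_pick, if (length(rv)) rv[which.min(abs(seg$axis_fraction[rv] - 0.45))])
}

# per-node conduction-velocity map for one subject of a given preset
subject_cv_map <- function(heart, seg, preset, rng_stream) {
  n <- nrow(heart$mesh$vertices)
  cv <- rep(preset$cv_base, n)
  cv <- cv * exp(stats::rnorm(1, 0, preset$cv_subject_sd))
  # basal slow band (hypertrophy-affected base)
  basal <- seg$axis_fraction < 1 / 3
  cv[basal] <- cv[basal] * (preset$basal_slow_factor +
                              (1 - preset$basal_slow_factor) *
                                seg$axis_fraction[basal] * 3)
  # scar patch
  patch <- preset$patch
  if (patch == "mixed") {
    patch <- if (stats::runif(1) < 0.6) "anteroseptal" else "inferoposterior"
  }
  if (patch != "none") {
    centre_angle <- if (patch == "anteroseptal") 30 else 250
    centre_frac <- if (patch == "anteroseptal") 0.35 else 0.45
    dang <- abs(((seg$angle_deg - centre_angle + 180) %% 360) - 180)
    in_patch <- dang < 45 & abs(seg$axis_fraction - centre_frac) < 0.22
    cv[in_patch] <- cv[in_patch] * preset$patch_factor
  }
  # spatially correlated conduction heterogeneity (smooth log-normal field;
  # point-to-point noise at mesh resolution would be unphysical)
  cv <- cv * exp(smooth_random_field(heart$mesh$vertices,
                                     sd = preset$cv_noise_sd,
                                     correlation_mm = 22))
  pmax(cv, 0.15)
}

# smooth zero-mean Gaussian random field over the mesh vertices: iid normal
# weights at subsampled control points, Gaussian-kernel interpolation,
# normalized to the requested marginal sd
smooth_random_field <- function(vertices, sd, correlation_mm = 22,
                                n_control = 60L) {
  n <- nrow(vertices)
  ctrl <- vertices[round(seq(1L, n, length.out = min(n_control, n))), ,
                   drop = FALSE]
  wts <- stats::rnorm(nrow(ctrl))
  d2 <- outer(rowSums(vertices^2), rep(1, nrow(ctrl))) +
    outer(rep(1, n), rowSums(ctrl^2)) - 2 * vertices %*% t(ctrl)
  K <- exp(-pmax(d2, 0) / (2 * correlation_mm^2))
  g <- as.vector(K %*% wts)
  g <- g - mean(g)
  s <- stats::sd(g)
  if (s < 1e-12) return(rep(0, n))
  g * sd / s
}

subject_amplitudes <- function(heart, seg, preset) {
  n <- nrow(heart$mesh$vertices)
  subj_mean <- stats::rnorm(1, preset$amp_mean, preset$amp_between_sd)
  amp <- subj_mean + stats::rnorm(n, 0, preset$amp_within_sd)
  pmax(amp, 120)
}

#' Generate a synthetic four-group cohort
#'
#' Simulates every subject of the cohort on a shared geometry: a
#' group-preset conduction-velocity map with seeded per-subject
#' perturbations drives a geodesic activation field; unipolar electrograms
#' are synthesized at per-node amplitudes and forward-projected to the
#' 128-electrode array with additive measurement noise.
#'
#' @param spec a `cohort_spec`.
#' @param heart,torso the shared geometry.
#' @param transfer the matching `transfer_matrix`.
#' @param seg optional `segment_model` (computed when missing).
#' @param template an `egm_template` (default settings when missing).
#' @param keep_heart_potentials retain each subject's full heart-potential
#'   matrix (memory-heavy; default `FALSE`).
#' @return a `cohort` list: `subjects` (each with `id`, `group`,
#'   `lat_true`, `amplitudes`, `recording`), `spec`, and the shared
#'   `heart`, `seg`, `pacing_sites`.
#' @export
generate_cohort <- function(spec, heart, torso, transfer, seg = NULL,
                            template = egm_template(),
                            keep_heart_potentials = FALSE) {
  if (is.null(seg)) seg <- assign_aha_segments(heart)
  pacing <- pick_pacing_sites(heart, seg)
  subjects <- list()
  sidx <- 0L
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (g in spec$groups) {
    preset <- spec$presets[[g]]
    for (j in seq_len(spec$n_subjects[[g]])) {
      sidx <- sidx + 1L
      subject_seed <- spec$seed * 1009L + sidx * 97L
      set.seed(subject_seed)
      cv <- subject_cv_map(heart, seg, preset, NULL)
      amp <- subject_amplitudes(heart, seg, preset)
      field <- simulate_activation(heart, pacing, cv, seed = subject_seed)
      hp <- synthesize_heart_potentials(field, template, amp)
      rec <- make_body_surface_recording(hp, transfer, snr_db = spec$snr_db,
                                         seed = subject_seed)
      subjects[[sidx]] <- list(
        id = sprintf("%s_%02d", g, j), group = g, seed = subject_seed,
        lat_true = field$lat_true, amplitudes = amp,
        recording = rec,
        heart_potentials = if (keep_heart_potentials) hp)
    }
  }
  names(subjects) <- vapply(subjects, `[[`, "", "id")
  structure(list(subjects = subjects, spec = spec, heart = heart,
                 seg = seg, pacing_sites = pacing),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, "", "group")
  cat("<cohort>", length(x$subjects), "subjects:",
      paste(sprintf("%s=%d", names(table(groups)), table(groups)),
            collapse = ", "), "\n")
  invisible(x)
}
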