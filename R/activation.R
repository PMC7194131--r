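#' Simulate an activation field by geodesic wavefront propagation
#'
#' Ground-truth local activation times are computed as shortest-path travel
#' times over the mesh edge graph: each edge costs its length divided by the
#' harmonic mean of the conduction velocities at its endpoints, and the LAT
#' of a node is the minimum travel time from any pacing site. To emulate
#' transmural spread (sinus activation starts septally on the endocardium
#' and breaks through to the epicardium), optional cross-surface links
#' connect each endocardial node to its nearest epicardial neighbours within
#' `transmural_reach` mm, traversed at `transmural_cv`.
#'
#' @param heart a `heart_geometry`.
#' @param pacing_sites integer vertex ids with LAT 0.
#' @param cv_map conduction velocity per node (mm/ms); scalar recycled.
#' @param seed integer; kept for pipeline bookkeeping (the computation is
#'   deterministic).
#' @param transmural_reach mm; 0 disables cross-surface links.
#' @param transmural_cv mm/ms for cross-surface links.
#' @return an `activation_field`: list with `lat_true` (ms per node, `Inf`
#'   for unreachable nodes flagged invalid), `valid` (logical), and
#'   `pacing_sites`.
#' @export
simulate_activation <- function(heart, pacing_sites, cv_map, seed = 1L,
                                transmural_reach = 18, transmural_cv = 0.6) {
  mesh <- heart$mesh
  n <- nrow(mesh$vertices)
  if (length(pacing_sites) < 1L) stop("need at least one pacing site")
  cv <- rep_len(as.double(cv_map), n)
  if (any(cv <= 0)) stop("conduction velocities must be positive")
  e <- mesh_edges(mesh)
  len <- mesh_edge_lengths(mesh)
  # harmonic-mean conduction velocity per edge
  tt <- len * (1 / cv[e[, 1L]] + 1 / cv[e[, 2L]]) / 2
  edges <- e
  wts <- tt
  if (transmural_reach > 0) {
    endo <- which(mesh$labels %in% c("LV_ENDO", "RV_ENDO"))
    epi <- which(mesh$labels == "EPI")
    if (length(endo) && length(epi)) {
      ev <- mesh$vertices[epi, , drop = FALSE]
      links <- lapply(endo, function(i) {
        d <- sqrt(colSums((t(ev) - mesh$vertices[i, ])^2))
        j <- which.min(d)
        if (d[j] <= transmural_reach) c(i, epi[j], d[j]) else NULL
      })
      links <- do.call(rbind, links)
      if (!is.null(links)) {
        edges <- rbind(edges, links[, 1:2, drop = FALSE])
        wts <- c(wts, links[, 3L] / transmural_cv)
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = wts)
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  d <- igraph::distances(g, v = pacing_sites, to = seq_len(n),
                         weights = igraph::E(g)$weight)
  lat <- apply(d, 2L, min)
  structure(list(lat_true = lat, valid = is.finite(lat),
                 pacing_sites = as.integer(pacing_sites)),
            class = "activation_field")
}

#' @export
print.activation_field <- function(x, ...) {
  cat(sprintf("<activation_field> %d nodes, LAT range %.1f-%.1f ms\n",
              length(x$lat_true), min(x$lat_true[x$valid]),
              max(x$lat_true[x$valid])))
  invisible(x)
}

#' Unipolar electrogram template
#'
#' Parameterizes the canonical unipolar RS/QS morphology used to synthesize
#' heart-surface potentials: a small positive pre-wave followed by a
#' sigmoidal downstroke through the activation instant. By construction the
#' steepest negative slope occurs exactly at the nominal activation time.
#'
#' @param amplitude_uv peak-to-peak amplitude (microvolts).
#' @param downstroke_ms width parameter of the sigmoidal downstroke (the
#'   10-90 % fall takes about `2.2 * downstroke_ms`).
#' @param prewave_frac amplitude of the positive pre-wave as a fraction of
#'   the peak-to-peak amplitude.
#' @param sampling_rate Hz.
#' @return an `egm_template` list.
#' @export
egm_template <- function(amplitude_uv = 1000, downstroke_ms = 6,
                         prewave_frac = 0.25, sampling_rate = 2048) {
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  structure(list(amplitude_uv = amplitude_uv, downstroke_ms = downstroke_ms,
                 prewave_frac = prewave_frac, sampling_rate = sampling_rate),
            class = "egm_template")
}

# evaluate the template waveform at times t (ms) relative to activation,
# normalized to unit peak-to-peak range
template_waveform <- function(template, t_rel) {
  raw <- template_waveform_raw(template, t_rel)
  raw / template_range(template)
}

template_waveform_raw <- function(template, t_rel) {
  w <- template$downstroke_ms
  s <- -0.5 * tanh(t_rel / w)                    # downstroke through 0
  # positive pre-wave placed far enough ahead that it cannot displace the
  # steepest negative slope from the activation instant
  pre <- template$prewave_frac *
    exp(-((t_rel + 3.2 * w) / (1.2 * w))^2)
  s + pre
}

template_range <- function(template) {
  w <- template$downstroke_ms
  tg <- seq(-10 * w, 10 * w, length.out = 2001)
  diff(range(template_waveform_raw(template, tg)))
}

#' Synthesize heart-surface potentials from an activation field
#'
#' Every node receives the template waveform shifted to its LAT and scaled
#' to its amplitude; peak-to-peak amplitude matches the requested value to
#' within about 1 % and the steepest downslope falls on the activation
#' instant to within one sample.
#'
#' @param field an `activation_field`.
#' @param template an `egm_template`.
#' @param amplitudes microvolts per node (scalar recycled).
#' @param window_ms length of the synthesized beat window; activation times
#'   must fall at least 25 ms before its end.
#' @param t0_ms time of the earliest activation within the window (the
#'   simulated QRS onset), default 100 ms.
#' @return a `heart_potentials` object: matrix `n_nodes x n_time` (uV) with
#'   attributes `sampling_rate`, `time_ms`, `t0_ms`.
#' @export
synthesize_heart_potentials <- function(field, template, amplitudes,
                                        window_ms = 300, t0_ms = 100) {
  n <- length(field$lat_true)
  amp <- rep_len(as.double(amplitudes), n)
  fs <- template$sampling_rate
  nt <- round(window_ms * fs / 1000)
  tms <- (seq_len(nt) - 1L) * 1000 / fs
  lat <- field$lat_true + t0_ms
  if (any(is.finite(lat) & (lat > window_ms - 25))) {
    stop("activation extends beyond the simulated window; enlarge `window_ms`")
  }
  X <- matrix(0, n, nt)
  for (i in seq_len(n)) {
    if (!field$valid[i]) next
    X[i, ] <- amp[i] * template_waveform(template, tms - lat[i])
  }
  structure(X, sampling_rate = fs, time_ms = tms, t0_ms = t0_ms,
            lat_abs_ms = lat, class = c("heart_potentials", "matrix", "array"))
}

#' Body-surface recording from heart potentials
#'
#' Forward-projects heart-surface potentials to the 128 chest electrodes and
#' the four limb-lead surrogate sites, then adds white Gaussian measurement
#' noise at the requested signal-to-noise ratio (signal power measured over
#' the QRS window, i.e. where the heart potentials are active).
#'
#' @param heart_potentials a `heart_potentials` matrix.
#' @param transfer a `transfer_matrix` carrying electrode and limb rows.
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noise-free.
#' @param seed integer seed for the noise.
#' @return a `body_surface_recording`: list with `potentials`
#'   (`128 x n_time`, uV), `limb` (`4 x n_time`, rows RA, LA, LL, ref),
#'   `sampling_rate`, `time_ms`, `qrs_window` (sample range of activity),
#'   `snr_db`, `seed`.
#' @export
make_body_surface_recording <- function(heart_potentials, transfer,
                                        snr_db = 30, seed = 1L) {
  if (!is.finite(snr_db) && !identical(snr_db, Inf)) {
    stop("`snr_db` must be finite or Inf")
  }
  y <- forward_project(unclass(heart_potentials), transfer, rows = "electrodes")
  limb <- if (!is.null(transfer$limb_entries)) {
    forward_project(unclass(heart_potentials), transfer, rows = "limb")
  }
  fs <- attr(heart_potentials, "sampling_rate")
  tms <- attr(heart_potentials, "time_ms")
  lat <- attr(heart_potentials, "lat_abs_ms")
  qrs <- range(which(tms >= min(lat) - 20 & tms <= max(lat) + 25))
  if (is.finite(snr_db)) {
    sig_pow <- mean(y[, qrs[1L]:qrs[2L]]^2)
    sd_noise <- sqrt(sig_pow / 10^(snr_db / 10))
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    y <- y + matrix(rnorm(length(y), sd = sd_noise), nrow(y))
    if (!is.null(limb)) {
      limb <- limb + matrix(rnorm(length(limb), sd = sd_noise), nrow(limb))
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(potentials = y, limb = limb, sampling_rate = fs,
                 time_ms = tms, qrs_window = qrs, snr_db = snr_db,
                 seed = seed),
            class = "body_surface_recording")
}

#' @export
print.body_surface_recording <- function(x, ...) {
  cat(sprintf("<body_surface_recording> %d channels x %d samples @ %g Hz, SNR %s dB\n",
              nrow(x$potentials), ncol(x$potentials), x$sampling_rate,
              format(x$snr_db)))
  invisible(x)
}
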