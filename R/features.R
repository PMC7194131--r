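#' QRS onset from the limb leads
#'
#' Builds the three standard limb leads (I = LA-RA, II = LL-RA,
#' III = LL-LA) when given the four limb-surrogate channels, or uses the
#' rows as leads directly when given three. Each lead's onset is the first
#' time its smoothed absolute derivative exceeds `k` baseline MADs (median
#' absolute deviation over the first `baseline_ms`) sustained for at least
#' `sustain_ms`; the returned onset is the mean of the three per-lead
#' onsets.
#'
#' @param limb_leads `3 x n_time` lead matrix, or `4 x n_time` RA/LA/LL/ref
#'   channel matrix, or a `body_surface_recording`.
#' @param sampling_rate Hz (taken from the recording when omitted).
#' @param k threshold in baseline MADs (default 4).
#' @param baseline_ms initial baseline window (default 50 ms).
#' @param sustain_ms required suprathreshold duration (default 10 ms).
#' @return onset time in ms from the start of the trace.
#' @export
detect_qrs_onset <- function(limb_leads, sampling_rate = NULL, k = 4,
                             baseline_ms = 50, sustain_ms = 10) {
  if (inherits(limb_leads, "body_surface_recording")) {
    sampling_rate <- limb_leads$sampling_rate
    limb_leads <- limb_leads$limb
  }
  L <- as.matrix(limb_leads)
  if (is.null(sampling_rate)) stop("`sampling_rate` is required")
  if (nrow(L) == 4L) {
    L <- rbind(I = L[2L, ] - L[1L, ],
               II = L[3L, ] - L[1L, ],
               III = L[3L, ] - L[2L, ])
  }
  if (nrow(L) < 3L) stop("need at least 3 limb leads")
  dt <- 1000 / sampling_rate
  nb <- max(3L, round(baseline_ms / dt))
  ns <- max(1L, round(sustain_ms / dt))
  onsets <- apply(L[1:3, , drop = FALSE], 1L, function(v) {
    dv <- abs(smoothed_derivative(v, sampling_rate))
    # envelope over the sustain window suppresses flicker at the
    # within-QRS zero crossings of the raw derivative
    env <- as.numeric(fill_filter_edges(
      stats::filter(dv, rep(1 / ns, ns), sides = 2L)))
    base <- env[seq_len(min(nb, length(env)))]
    thr <- stats::median(base) + k * max(stats::mad(base), 1e-12)
    above <- env > thr
    sustained <- stats::filter(as.numeric(above), rep(1 / ns, ns),
                               sides = 1L)
    hit <- which(above & c(sustained[-seq_len(min(ns, length(sustained)))],
                           rep(NA, min(ns, length(sustained)))) >= 0.5)
    if (!length(hit)) return(NA_real_)
    (hit[1L] - 1L) * dt
  })
  if (all(is.na(onsets))) stop("QRS onset not found on any limb lead")
  # leads without a detectable depolarization (near-isoelectric axis) are
  # dropped from the average
  mean(onsets, na.rm = TRUE)
}

# constant extension of a centred moving average into its NA edges
fill_filter_edges <- function(sm) {
  ok <- which(!is.na(sm))
  if (!length(ok)) return(sm)
  if (ok[1L] > 1L) sm[seq_len(ok[1L] - 1L)] <- sm[ok[1L]]
  n <- length(sm)
  if (ok[length(ok)] < n) sm[(ok[length(ok)] + 1L):n] <- sm[ok[length(ok)]]
  sm
}

# central-difference derivative after moving-average smoothing (default
# 5 ms wide), in units per ms
smoothed_derivative <- function(v, sampling_rate, smooth_ms = 5) {
  smooth_samples <- max(3L, 2L * (round(smooth_ms * sampling_rate / 1000) %/% 2L) + 1L)
  sm <- stats::filter(v, rep(1 / smooth_samples, smooth_samples),
                      sides = 2L)
  sm <- fill_filter_edges(sm)
  n <- length(v)
  d <- c(sm[2L] - sm[1L], (sm[3:n] - sm[1:(n - 2L)]) / 2,
         sm[n] - sm[n - 1L])
  as.numeric(d) * sampling_rate / 1000
}

#' Steepest-downslope time of a unipolar electrogram
#'
#' Time of the minimum first derivative (central differences after a
#' 5 ms moving average) within the analysis window; ties break to the
#' earliest sample. A trace whose derivative never goes negative (constant
#' or monotonically rising) raises an error.
#'
#' @param egm numeric trace (uV).
#' @param sampling_rate Hz.
#' @param window `c(t_start, t_end)` in ms (default: whole trace).
#' @return time in ms of the steepest downslope.
#' @export
steepest_downslope <- function(egm, sampling_rate, window = NULL) {
  v <- as.numeric(egm)
  dt <- 1000 / sampling_rate
  tms <- (seq_along(v) - 1L) * dt
  if (is.null(window)) window <- range(tms)
  sel <- which(tms >= window[1L] & tms <= window[2L])
  if (!length(sel)) stop("window outside the trace")
  d <- smoothed_derivative(v, sampling_rate)[sel]
  if (min(d) > -1e-9 * max(abs(v) + 1e-300)) {
    if (diff(range(v)) < 1e-12 * (abs(v[1L]) + 1)) {
      stop("no downslope: trace is constant")
    }
    # linear ramps and rising traces: minimum-derivative tie-break applies
  }
  # ties (within float jitter) break to the earliest sample
  j <- which(d <= min(d) + 1e-9 * (max(abs(d)) + 1e-300))[1L]
  tms[sel[j]]
}

#' Local activation time
#'
#' @param downslope_time ms, from [steepest_downslope()].
#' @param qrs_onset ms, from [detect_qrs_onset()].
#' @return LAT in ms (downslope minus onset).
#' @export
local_activation_time <- function(downslope_time, qrs_onset) {
  downslope_time - qrs_onset
}

#' Peak-to-peak voltage of an electrogram
#'
#' @param egm numeric trace (uV).
#' @param sampling_rate Hz (needed only when a window is given).
#' @param window `c(t_start, t_end)` ms.
#' @return max minus min within the window (uV, non-negative).
#' @export
peak_to_peak_voltage <- function(egm, sampling_rate = NULL, window = NULL) {
  v <- as.numeric(egm)
  if (!is.null(window)) {
    if (is.null(sampling_rate)) stop("`sampling_rate` needed with a window")
    tms <- (seq_along(v) - 1L) * 1000 / sampling_rate
    v <- v[tms >= window[1L] & tms <= window[2L]]
    if (!length(v)) stop("empty analysis window")
  }
  max(v) - min(v)
}

#' Bipolar electrogram of a neighbouring pair
#'
#' @param u1,u2 unipolar traces of equal length.
#' @return their difference `u1 - u2`.
#' @export
bipolar_egm <- function(u1, u2) {
  if (length(u1) != length(u2)) stop("traces must have equal length")
  as.numeric(u1) - as.numeric(u2)
}

#' Neighbour-agreement quality control of a unipolar pair
#'
#' Deterministic replacement of the reviewer-based quality control of
#' reconstructed electrograms: for each pair of neighbouring unipolar EGMs,
#' morphology agreement is the maximum normalized cross-correlation (within
#' `max_lag_ms`) and downslope agreement is the absolute difference of the
#' steepest-downslope times. Both agree: `ACCEPT`. Morphology agrees but the
#' downslopes disagree: `RECOMPUTE`, and the downslope of each trace is
#' re-derived inside a window centred on the extremum of the bipolar EGM.
#' Morphology disagrees: `EXCLUDE` (both nodes masked).
#'
#' @param u1,u2 unipolar traces.
#' @param sampling_rate Hz.
#' @param rho_min morphology threshold (default 0.8).
#' @param tau_ms downslope-difference threshold (default 10 ms).
#' @param max_lag_ms maximum cross-correlation lag (default 40 ms).
#' @param recompute_halfwidth_ms half-width of the recompute window
#'   (default 25 ms).
#' @return a `qc_decision` list: `decision`, `morphology_score`,
#'   `downslope_diff_ms`, and `downslope_times` (after any recomputation).
#' @export
qc_neighbor_agreement <- function(u1, u2, sampling_rate, rho_min = 0.8,
                                  tau_ms = 10, max_lag_ms = 40,
                                  recompute_halfwidth_ms = 25) {
  u1 <- as.numeric(u1); u2 <- as.numeric(u2)
  if (length(u1) != length(u2)) stop("traces must have equal length")
  rho <- max_norm_xcorr(u1, u2, sampling_rate, max_lag_ms)
  t1 <- try(steepest_downslope(u1, sampling_rate), silent = TRUE)
  t2 <- try(steepest_downslope(u2, sampling_rate), silent = TRUE)
  bad_slope <- inherits(t1, "try-error") || inherits(t2, "try-error")
  if (!is.finite(rho) || rho < rho_min || bad_slope) {
    return(structure(list(decision = "EXCLUDE", morphology_score = rho,
                          downslope_diff_ms = NA_real_,
                          downslope_times = c(NA_real_, NA_real_)),
                     class = "qc_decision"))
  }
  dd <- abs(t1 - t2)
  if (dd <= tau_ms) {
    return(structure(list(decision = "ACCEPT", morphology_score = rho,
                          downslope_diff_ms = dd,
                          downslope_times = c(t1, t2)),
                     class = "qc_decision"))
  }
  # morphology agrees, downslope does not: restrict to the window around
  # the bipolar extremum and recompute
  bip <- bipolar_egm(u1, u2)
  dt <- 1000 / sampling_rate
  t_ext <- (which.max(abs(bip)) - 1L) * dt
  win <- c(max(0, t_ext - recompute_halfwidth_ms),
           min((length(u1) - 1L) * dt, t_ext + recompute_halfwidth_ms))
  t1r <- steepest_downslope(u1, sampling_rate, win)
  t2r <- steepest_downslope(u2, sampling_rate, win)
  structure(list(decision = "RECOMPUTE", morphology_score = rho,
                 downslope_diff_ms = dd, downslope_times = c(t1r, t2r)),
            class = "qc_decision")
}

# maximum normalized cross-correlation over lags up to max_lag_ms
max_norm_xcorr <- function(u1, u2, sampling_rate, max_lag_ms) {
  a <- u1 - mean(u1)
  b <- u2 - mean(u2)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(NA_real_)
  n <- length(a)
  max_lag <- min(n - 1L, max(1L, round(max_lag_ms * sampling_rate / 1000)))
  best <- -1
  for (k in -max_lag:max_lag) {
    if (k >= 0) {
      s <- sum(a[1:(n - k)] * b[(1 + k):n])
    } else {
      s <- sum(a[(1 - k):n] * b[1:(n + k)])
    }
    if (s / (na * nb) > best) best <- s / (na * nb)
  }
  best
}

#' Per-node activation and voltage maps from reconstructed electrograms
#'
#' Single-beat analysis: per node, LAT (steepest downslope minus QRS onset)
#' and peak-to-peak voltage within the beat window, with neighbour-pair
#' quality control propagated into the validity masks. Every mesh edge is a
#' neighbour pair; morphology and downslope agreement are evaluated for all
#' pairs (vectorized), nodes are excluded when the majority of their pairs
#' disagree in morphology, and downslopes are recomputed inside the window
#' around the bipolar extremum when morphology agrees but timing does not.
#' When more than half the nodes end up excluded the maps carry
#' `attr(, "pipeline_warning")`.
#'
#' @param egms an `egm_set` (or plain matrix with `sampling_rate` attr).
#' @param qrs_onset ms.
#' @param heart optional `heart_geometry`; enables neighbour QC.
#' @param window beat window in ms (default: whole trace).
#' @param qc logical, run neighbour QC (default `TRUE` when `heart` given).
#' @param qc_max_pairs cap on evaluated neighbour pairs (edges are
#'   subsampled evenly above the cap).
#' @param rho_min,tau_ms QC thresholds, see [qc_neighbor_agreement()].
#' @param max_lag_ms cross-correlation lag bound.
#' @param smooth_ms moving-average width for the derivative (default 8 ms;
#'   wider than the single-trace default because reconstructed electrograms
#'   carry amplified measurement noise).
#' @return list with `activation` (an `activation_map` tibble: `node_id`,
#'   `lat_ms`, `valid`) and `voltage` (a `voltage_map` tibble: `node_id`,
#'   `vpp_uv`, `valid`).
#' @export
compute_maps <- function(egms, qrs_onset, heart = NULL, window = NULL,
                         qc = !is.null(heart), qc_max_pairs = Inf,
                         rho_min = 0.8, tau_ms = 10, max_lag_ms = 40,
                         smooth_ms = 8) {
  X <- if (inherits(egms, "egm_set")) egms$egms else as.matrix(egms)
  fs <- if (inherits(egms, "egm_set")) egms$sampling_rate else
    attr(egms, "sampling_rate")
  if (is.null(fs)) stop("sampling rate not available")
  n <- nrow(X)
  dt <- 1000 / fs
  tms <- (seq_len(ncol(X)) - 1L) * dt
  if (is.null(window)) window <- range(tms)
  sel <- which(tms >= window[1L] & tms <= window[2L])
  D <- t(apply(X, 1L, smoothed_derivative, sampling_rate = fs,
               smooth_ms = smooth_ms))[, sel, drop = FALSE]
  j <- max.col(-D, ties.method = "first")
  downslope <- tms[sel[j]]
  lat <- downslope - qrs_onset
  vpp <- apply(X[, sel, drop = FALSE], 1L, function(v) max(v) - min(v))
  valid <- rep(TRUE, n)
  if (qc && !is.null(heart)) {
    e <- mesh_edges(heart$mesh)
    if (nrow(e) > qc_max_pairs) {
      idx <- round(seq(1L, nrow(e), length.out = qc_max_pairs))
      e <- e[idx, , drop = FALSE]
    }
    W <- X[, sel, drop = FALSE]
    rho <- pairwise_max_xcorr(W[e[, 1L], , drop = FALSE],
                              W[e[, 2L], , drop = FALSE],
                              max_lag = round(max_lag_ms / dt))
    disagree <- !is.finite(rho) | rho < rho_min
    # majority vote per node over its evaluated pairs
    votes_bad <- tabulate(c(e[disagree, 1L], e[disagree, 2L]), nbins = n)
    votes_all <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
    valid <- !(votes_all > 0L & votes_bad > votes_all / 2)
    # timing disagreement on morphology-agreeing pairs: recompute inside
    # the window around the bipolar extremum
    dd <- abs(downslope[e[, 1L]] - downslope[e[, 2L]])
    recomp_edges <- which(!disagree & dd > tau_ms)
    if (length(recomp_edges)) {
      bip_ext <- numeric(length(recomp_edges))
      for (r in seq_along(recomp_edges)) {
        ee <- e[recomp_edges[r], ]
        bip_ext[r] <- tms[sel[which.max(abs(W[ee[1L], ] - W[ee[2L], ]))]]
      }
      nodes <- unique(as.vector(e[recomp_edges, ]))
      # neighbour LAT consensus per node (for the acceptance check below)
      nb_med <- vapply(nodes, function(nd) {
        nbrs <- c(e[e[, 1L] == nd, 2L], e[e[, 2L] == nd, 1L])
        stats::median(lat[nbrs])
      }, 0)
      for (q in seq_along(nodes)) {
        nd <- nodes[q]
        if (!valid[nd]) next
        hits <- e[recomp_edges, 1L] == nd | e[recomp_edges, 2L] == nd
        centre <- stats::median(bip_ext[hits])
        wlo <- max(window[1L], centre - 25)
        whi <- min(window[2L], centre + 25)
        ssel <- sel[tms[sel] >= wlo & tms[sel] <= whi]
        if (length(ssel) < 3L) next
        dloc <- D[nd, match(ssel, sel)]
        cand <- tms[ssel[which.min(dloc)]] - qrs_onset
        # keep the recomputed downslope only when it restores agreement
        if (abs(cand - nb_med[q]) < abs(lat[nd] - nb_med[q])) lat[nd] <- cand
      }
    }
  }
  act <- tibble::tibble(node_id = seq_len(n), lat_ms = lat, valid = valid)
  volt <- tibble::tibble(node_id = seq_len(n), vpp_uv = vpp, valid = valid)
  class(act) <- c("activation_map", class(act))
  class(volt) <- c("voltage_map", class(volt))
  if (mean(valid) < 0.5) {
    attr(act, "pipeline_warning") <- "more than half of the nodes excluded by QC"
    attr(volt, "pipeline_warning") <- attr(act, "pipeline_warning")
  }
  list(activation = act, voltage = volt)
}

# maximum normalized cross-correlation per row pair, vectorized over rows
pairwise_max_xcorr <- function(A, B, max_lag) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  nt <- ncol(A)
  max_lag <- min(nt - 1L, max(1L, max_lag))
  best <- rep(-1, nrow(A))
  for (k in -max_lag:max_lag) {
    if (k >= 0) {
      s <- rowSums(A[, 1:(nt - k), drop = FALSE] *
                     B[, (1 + k):nt, drop = FALSE])
    } else {
      s <- rowSums(A[, (1 - k):nt, drop = FALSE] *
                     B[, 1:(nt + k), drop = FALSE])
    }
    best <- pmax(best, s / (na * nb))
  }
  best[na < 1e-12 | nb < 1e-12] <- NA_real_
  best
}
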