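#' Heart and torso geometry containers
#'
#' `heart_geometry()` wraps a combined biventricular surface mesh (epicardium,
#' LV endocardium, RV endocardium) with the anatomical frame needed for AHA
#' segmentation: the apex vertex, the basal centre, the long axis (unit
#' vector pointing base-to-apex) and the septal direction (unit vector from
#' the LV centroid toward the septum, orthogonal to the long axis).
#'
#' @param mesh a `triangle_mesh` with labels in `LV_ENDO`, `RV_ENDO`, `EPI`.
#' @param apex_point vertex index of the epicardial apex.
#' @param base_center 3-vector, centre of the basal plane (mm).
#' @param long_axis unit 3-vector, base toward apex.
#' @param septal_direction unit 3-vector, orthogonal to `long_axis`.
#' @return a `heart_geometry` object.
#' @export
heart_geometry <- function(mesh, apex_point, base_center, long_axis,
                           septal_direction) {
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  septal_direction <- septal_direction / sqrt(sum(septal_direction^2))
  if (abs(sum(long_axis * septal_direction)) > 1e-8) {
    stop("`long_axis` and `septal_direction` must be orthogonal")
  }
  if (mesh$labels[apex_point] != "EPI") {
    stop("`apex_point` must lie on the EPI surface")
  }
  structure(list(mesh = mesh, apex_point = as.integer(apex_point),
                 base_center = as.double(base_center),
                 long_axis = long_axis,
                 septal_direction = septal_direction),
            class = "heart_geometry")
}

#' @export
print.heart_geometry <- function(x, ...) {
  cat(sprintf("<heart_geometry> %d nodes (%s)\n", nrow(x$mesh$vertices),
              paste(sprintf("%s=%d", names(table(x$mesh$labels)),
                            table(x$mesh$labels)), collapse = ", ")))
  invisible(x)
}

#' @param electrode_vertex_ids integer vector of 128 distinct torso vertex
#'   indices carrying the body-surface electrodes.
#' @param limb_lead_ids integer vector of 4 torso vertex indices for the
#'   RA, LA, LL and reference limb-lead surrogates (in that order).
#' @rdname heart_geometry
#' @export
torso_geometry <- function(mesh, electrode_vertex_ids, limb_lead_ids) {
  electrode_vertex_ids <- as.integer(electrode_vertex_ids)
  if (length(electrode_vertex_ids) != 128L ||
      anyDuplicated(electrode_vertex_ids)) {
    stop("need exactly 128 distinct electrode vertex ids")
  }
  if (length(limb_lead_ids) != 4L) stop("need 4 limb-lead surrogate ids")
  structure(list(mesh = mesh,
                 electrode_vertex_ids = electrode_vertex_ids,
                 limb_lead_ids = as.integer(limb_lead_ids)),
            class = "torso_geometry")
}

#' @export
print.torso_geometry <- function(x, ...) {
  cat(sprintf("<torso_geometry> %d nodes, 128 electrodes\n",
              nrow(x$mesh$vertices)))
  invisible(x)
}

#' Icosphere mesh
#'
#' Recursively subdivided icosahedron projected onto a sphere; the standard
#' quasi-uniform sphere triangulation used by the forward-model test
#' fixtures (concentric-sphere oracle).
#'
#' @param subdivisions non-negative integer; vertex count is
#'   `10 * 4^subdivisions + 2`.
#' @param radius sphere radius (mm).
#' @param center 3-vector centre.
#' @param label surface label applied to every vertex.
#' @return a closed `triangle_mesh`.
#' @export
make_icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0),
                           label = "EPI") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    nv <- nrow(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      nv <<- nv + 1L
      mid_cache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; cc <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(4L * k - 3L):(4L * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                              c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  v <- v * radius
  v <- v + matrix(center, nrow(v), 3L, byrow = TRUE)
  triangle_mesh(v, f, rep(label, nrow(v)))
}

# distance along a ray from the origin at angle `theta` (in the base plane)
# to a circle of radius R centred at c2 = (cx, cy); origin must be inside
ellipse_ray_dist <- function(cx, cy, R, theta) {
  ce <- cx * cos(theta) + cy * sin(theta)
  disc <- ce^2 + R^2 - (cx^2 + cy^2)
  ce + sqrt(pmax(disc, 0))
}

# zipper triangulation between two closed vertex loops ordered by angle
ring_zipper <- function(idxA, angA, idxB, angB) {
  mA <- length(idxA); mB <- length(idxB)
  oA <- order(angA); idxA <- idxA[oA]; angA <- angA[oA]
  oB <- order(angB); idxB <- idxB[oB]; angB <- angB[oB]
  # align start of B to A's first angle
  shift <- which.min(abs(((angB - angA[1] + pi) %% (2 * pi)) - pi))
  if (shift > 1L) {
    idxB <- c(idxB[shift:mB], idxB[1:(shift - 1L)])
    angB <- c(angB[shift:mB], angB[1:(shift - 1L)])
  }
  unwrap <- function(a) {
    a <- a - a[1]
    a <- a %% (2 * pi)
    a <- cummax(a + 1e-12 * seq_along(a))  # enforce monotone
    a
  }
  uA <- c(unwrap(angA), 2 * pi)
  uB <- c(unwrap(angB - angB[1] + angA[1] - angA[1]), 2 * pi)
  faces <- matrix(0L, mA + mB, 3L)
  i <- 1L; j <- 1L; k <- 0L
  while (i <= mA || j <= mB) {
    ai <- if (i <= mA) uA[i + 1L] else Inf
    bj <- if (j <= mB) uB[j + 1L] else Inf
    k <- k + 1L
    if (ai <= bj) {
      faces[k, ] <- c(idxA[(i - 1L) %% mA + 1L], idxA[i %% mA + 1L],
                      idxB[(j - 1L) %% mB + 1L])
      i <- i + 1L
    } else {
      faces[k, ] <- c(idxA[(i - 1L) %% mA + 1L], idxB[j %% mB + 1L],
                      idxB[(j - 1L) %% mB + 1L])
      j <- j + 1L
    }
  }
  faces[seq_len(k), , drop = FALSE]
}

# index-aligned cyclic ladder between two loops with equal point counts
ring_ladder_aligned <- function(idxA, idxB) {
  m <- length(idxA)
  out <- vector("list", m)
  for (p in seq_len(m)) {
    q <- p %% m + 1L
    a1 <- idxA[p]; a2 <- idxA[q]; b1 <- idxB[p]; b2 <- idxB[q]
    tris <- list()
    if (a1 != a2) tris <- c(tris, list(c(a1, a2, b1)))
    if (b1 != b2 && a2 != b2) tris <- c(tris, list(c(a2, b2, b1)))
    out[[p]] <- do.call(rbind, tris)
  }
  do.call(rbind, out)
}

#' Synthetic biventricular heart surface
#'
#' Builds a closed combined surface standing in for a segmented patient
#' heart: a truncated-ellipsoid epicardial cup, a smaller truncated-ellipsoid
#' LV endocardial cup offset away from the septum, and a crescent-section RV
#' endocardial shell between them on the septal side, all joined by a planar
#' basal cap. The basal cap carries two openings (the LV and RV cavity
#' mouths), so the blood pools communicate with the surrounding volume the
#' way the combined valve orifice does in segmented patient meshes.
#'
#' Mesh resolution is derived from `n_target_nodes` and adjusted once so the
#' final vertex count lands near the request; the build is deterministic for
#' a fixed `seed`, which also applies a small global scale perturbation
#' (+/-2 %) emulating between-subject size variation.
#'
#' @param n_target_nodes requested vertex count (>= 500).
#' @param wall_params list overriding any of: `epi_radius` (mm, default 40),
#'   `epi_length` (apex depth, 90), `wall_thickness` (10), `lv_offset`
#'   (LV-endo centre shift away from the septum, -6), `rv_depth_frac`
#'   (0.8), `rv_halfwidth_deg` (65), `rv_clearance` (4.5), `cap_fraction`
#'   (0.05).
#' @param seed integer seed.
#' @return a `heart_geometry`.
#' @export
make_synthetic_heart <- function(n_target_nodes = 4000, wall_params = list(),
                                 seed = 1L) {
  if (n_target_nodes < 500) stop("`n_target_nodes` must be >= 500")
  p <- utils::modifyList(list(epi_radius = 40, epi_length = 90,
                              wall_thickness = 10, lv_offset = -6,
                              rv_depth_frac = 0.8, rv_halfwidth_deg = 65,
                              rv_clearance = 4.5, cap_fraction = 0.05),
                         wall_params)
  if (p$wall_thickness <= 0) stop("`wall_thickness` must be positive")
  if (p$epi_radius <= p$wall_thickness) stop("wall thicker than the heart radius")
  scale <- withr_seed_uniform(seed, 0.98, 1.02)
  p$epi_radius <- p$epi_radius * scale
  p$epi_length <- p$epi_length * scale
  built <- build_heart_mesh(p, h = heart_resolution_guess(p, n_target_nodes))
  # one corrective rebuild toward the requested node count
  h2 <- attr(built, "h") * sqrt(nrow(built$mesh$vertices) / n_target_nodes)
  built <- build_heart_mesh(p, h = h2)
  built
}

withr_seed_uniform <- function(seed, lo, hi) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  stats::runif(1, lo, hi)
}

heart_resolution_guess <- function(p, n_target) {
  # crude area estimate: epi and LV half-spheroids + base + RV shell
  a_epi <- 2 * pi * p$epi_radius * (p$epi_radius + p$epi_length) / 2
  r_lv <- p$epi_radius - p$wall_thickness
  a_lv <- 2 * pi * r_lv * (r_lv + p$epi_length - p$wall_thickness) / 2
  a_rv <- 2 * 2.2 * p$epi_radius * p$rv_depth_frac * p$epi_length * 0.6
  area <- a_epi + a_lv + a_rv + pi * (p$epi_radius^2 - r_lv^2)
  sqrt(area / (0.866 * n_target))
}

build_heart_mesh <- function(p, h) {
  Re <- p$epi_radius; Le <- p$epi_length
  Rl <- p$epi_radius - p$wall_thickness
  Ll <- p$epi_length - p$wall_thickness
  cx <- p$lv_offset; cy <- 0
  Lrv <- p$rv_depth_frac * Le
  w <- p$rv_halfwidth_deg * pi / 180
  clr <- p$rv_clearance

  verts <- list(); labs <- character(); nv <- 0L
  addv <- function(x, y, z, lab) {
    nv <<- nv + 1L
    verts[[nv]] <<- c(x, y, z)
    labs[nv] <<- lab
    nv
  }
  faces <- list()
  addf <- function(f) faces[[length(faces) + 1L]] <<- f

  n_theta <- max(16L, 2L * round(pi * Re / h))
  dth <- 2 * pi / n_theta
  th <- function(i) i * dth  # station angle, i in 0..n_theta-1 (0 = septal)
  S2 <- max(2L, round(w / dth))
  w_eff <- S2 * dth

  # ---- base rings -------------------------------------------------------
  E <- integer(n_theta); L <- integer(n_theta)
  for (i in 0:(n_theta - 1L)) {
    E[i + 1L] <- addv(Re * cos(th(i)), Re * sin(th(i)), 0, "EPI")
    tl <- ellipse_ray_dist(cx, cy, Rl, th(i))
    L[i + 1L] <- addv(tl * cos(th(i)), tl * sin(th(i)), 0, "LV_ENDO")
  }
  # RV crescent profile at a given depth; returns NULL when the wedge closes
  rv_profile <- function(z, g_m) {
    re_z <- Re * sqrt(max(0, 1 - (z / Le)^2))
    rl_z <- Rl * sqrt(max(0, 1 - (z / Ll)^2))
    ks <- (-S2):S2
    ang <- ks * dth
    t_lv <- ellipse_ray_dist(cx, cy, rl_z, ang)
    inner_lim <- t_lv + clr
    outer_lim <- re_z - clr
    if (any(outer_lim - inner_lim < 1)) return(NULL)
    mid <- (inner_lim + outer_lim) / 2
    tipf <- sqrt(pmax(0, 1 - (ks / S2)^2))
    halfw <- (outer_lim - inner_lim) / 2 * tipf * g_m
    list(ang = ang, mid = mid, halfw = halfw)
  }
  make_rv_ring <- function(prof, z) {
    ks <- (-S2):S2
    nk <- length(ks)
    O <- integer(nk); I <- integer(nk)
    for (q in seq_len(nk)) {
      a <- prof$ang[q]
      if (prof$halfw[q] < 1e-9) {  # tip: single shared vertex
        O[q] <- addv(prof$mid[q] * cos(a), prof$mid[q] * sin(a), z, "RV_ENDO")
        I[q] <- O[q]
      } else {
        ro <- prof$mid[q] + prof$halfw[q]
        ri <- prof$mid[q] - prof$halfw[q]
        O[q] <- addv(ro * cos(a), ro * sin(a), z, "RV_ENDO")
        I[q] <- addv(ri * cos(a), ri * sin(a), z, "RV_ENDO")
      }
    }
    # closed loop: outer k=-S2..S2 then inner back k=S2-1..-S2+1
    loop <- c(O, rev(I[2:(nk - 1L)]))
    list(O = O, I = I, loop = loop)
  }

  ring0 <- make_rv_ring(rv_profile(0, 1), 0)

  # ---- basal cap (annulus with LV mouth ring already there + RV hole) ---
  # station index i corresponds to signed k = ((i + n/2) mod n) - n/2
  signed_k <- function(i) {
    k <- i %% n_theta
    if (k > n_theta / 2) k - n_theta else k
  }
  in_sector <- function(k) k >= -S2 && k <= S2
  O_of <- function(k) ring0$O[k + S2 + 1L]
  I_of <- function(k) ring0$I[k + S2 + 1L]
  for (i in 0:(n_theta - 1L)) {
    ii <- i + 1L
    jj <- (i + 1L) %% n_theta + 1L
    k1 <- signed_k(i); k2 <- signed_k(i + 1L)
    if (in_sector(k1) && in_sector(k2) && k2 == k1 + 1L) {
      # inside the sector: outer and inner ladders around the RV hole
      addf(c(E[ii], E[jj], O_of(k2)))
      if (O_of(k1) != O_of(k2)) addf(c(E[ii], O_of(k2), O_of(k1)))
      addf(c(I_of(k1), I_of(k2), L[jj]))
      if (L[ii] != L[jj]) addf(c(I_of(k1), L[jj], L[ii]))
    } else if (in_sector(k2) && k2 == -S2) {
      tip <- O_of(-S2)
      addf(c(E[ii], E[jj], tip))
      addf(c(E[ii], tip, L[jj]))
      addf(c(E[ii], L[jj], L[ii]))
    } else if (in_sector(k1) && k1 == S2) {
      tip <- O_of(S2)
      addf(c(tip, E[ii], E[jj]))
      addf(c(tip, E[jj], L[jj]))
      addf(c(tip, L[jj], L[ii]))
    } else {
      addf(c(E[ii], E[jj], L[jj]))
      addf(c(E[ii], L[jj], L[ii]))
    }
  }

  # ---- RV shell ---------------------------------------------------------
  M <- max(3L, round(0.92 * Lrv / h))
  prev <- ring0
  for (m in seq_len(M)) {
    z <- -0.92 * Lrv * m / M
    g_m <- sqrt(max(0, 1 - (z / Lrv)^2))
    prof <- rv_profile(z, g_m)
    if (is.null(prof)) break
    ring <- make_rv_ring(prof, z)
    addf(ring_ladder_aligned(prev$loop, ring$loop))
    prev <- ring
  }
  # lid: ladder between outer and inner strands of the deepest ring
  nk <- 2L * S2 + 1L
  for (q in 1:(nk - 1L)) {
    a1 <- prev$O[q]; a2 <- prev$O[q + 1L]
    b1 <- prev$I[q]; b2 <- prev$I[q + 1L]
    if (a1 != a2 && a1 != b1) addf(c(a1, b1, a2))
    if (b1 != b2 && a2 != b2) addf(c(a2, b1, b2))
  }

  # ---- epicardial and LV endocardial cups -------------------------------
  build_cup <- function(base_idx, base_ang, R, Lz, ccx, ccy, lab) {
    phis <- cup_phi_stations(R, Lz, h)
    prev_idx <- base_idx
    prev_ang <- base_ang
    for (phi in phis) {
      r <- R * cos(phi); z <- -Lz * sin(phi)
      nk <- max(6L, round(2 * pi * r / h))
      if (2 * pi * r / nk < 0.45 * h) break
      ang <- (0:(nk - 1L)) * 2 * pi / nk
      idx <- integer(nk)
      for (q in seq_len(nk)) {
        idx[q] <- addv(ccx + r * cos(ang[q]), ccy + r * sin(ang[q]), z, lab)
      }
      addf(ring_zipper(prev_idx, prev_ang, idx, ang))
      prev_idx <- idx
      prev_ang <- ang
    }
    pole <- addv(ccx, ccy, -Lz, lab)
    m <- length(prev_idx)
    for (q in seq_len(m)) addf(c(prev_idx[q], prev_idx[q %% m + 1L], pole))
    pole
  }
  base_ang_E <- (0:(n_theta - 1L)) * dth
  lv_pts <- do.call(rbind, verts[L])
  base_ang_L <- atan2(lv_pts[, 2L] - cy, lv_pts[, 1L] - cx) %% (2 * pi)
  apex_idx <- build_cup(E, base_ang_E, Re, Le, 0, 0, "EPI")
  build_cup(L, base_ang_L, Rl, Ll, cx, cy, "LV_ENDO")

  mesh <- triangle_mesh(do.call(rbind, verts),
                        do.call(rbind, faces), labs)
  mesh <- orient_faces_outward(mesh)
  out <- heart_geometry(mesh, apex_point = apex_idx,
                        base_center = c(0, 0, 0),
                        long_axis = c(0, 0, -1),
                        septal_direction = c(1, 0, 0))
  attr(out, "h") <- h
  out
}

cup_phi_stations <- function(R, Lz, h) {
  grid <- seq(0, pi / 2, length.out = 512)
  ds <- sqrt((Lz * cos(grid))^2 + (R * sin(grid))^2)
  arc <- sum(ds) * (grid[2] - grid[1])
  n <- max(3L, round(arc / h))
  seq(0, pi / 2, length.out = n + 1L)[-1L]
}

#' Synthetic torso with a 128-electrode array
#'
#' Builds a closed, rounded elliptic-cylinder torso around a heart and
#' places 128 electrodes as 4 panels (anterior, posterior, left, right) of
#' 4 strips x 8 electrodes each, snapped to distinct torso vertices, plus
#' four limb-lead surrogate vertices (RA, LA at the shoulder level; LL,
#' reference at the hip level).
#'
#' @param heart a `heart_geometry` that must fit inside with >= `margin` mm.
#' @param params list overriding any of: `rx` (left-right half width, 140),
#'   `ry` (front-back half depth, 110), `z_bottom` (-260), `z_top` (150),
#'   `resolution` (mm, 26), `margin` (20), `center_xy` (transverse torso
#'   centre relative to the heart frame; the default `c(-20, -45)` places
#'   the heart anterior and left of the torso midline, as in situ).
#' @param seed integer seed (the torso build itself is deterministic; the
#'   seed is kept in the call signature for pipeline bookkeeping).
#' @return a `torso_geometry`.
#' @export
make_synthetic_torso <- function(heart, params = list(), seed = 1L) {
  p <- utils::modifyList(list(rx = 140, ry = 110, z_bottom = -260,
                              z_top = 150, resolution = 26, margin = 20,
                              center_xy = c(-20, -45)),
                         params)
  h <- p$resolution
  verts <- list(); nv <- 0L
  addv <- function(x, y, z) {
    nv <<- nv + 1L
    verts[[nv]] <<- c(x, y, z)
    nv
  }
  faces <- list()
  addf <- function(f) faces[[length(faces) + 1L]] <<- f
  zspan <- p$z_top - p$z_bottom
  nz <- max(6L, round(zspan / h))
  zs <- seq(p$z_bottom, p$z_top, length.out = nz + 1L)
  taper <- function(z) {
    # rounded caps over the top/bottom 18 % of the height
    t <- 0.18 * zspan
    d <- pmin(z - p$z_bottom, p$z_top - z)
    ifelse(d >= t, 1, sqrt(pmax(1e-4, 1 - ((t - d) / t)^2)))
  }
  rings <- list(); angs <- list()
  for (k in seq_along(zs)) {
    s <- taper(zs[k])
    rx <- p$rx * s; ry <- p$ry * s
    nk <- max(8L, round(pi * (rx + ry) / h))
    a <- (0:(nk - 1L)) * 2 * pi / nk
    idx <- integer(nk)
    for (q in seq_len(nk)) {
      idx[q] <- addv(p$center_xy[1L] + rx * cos(a[q]),
                     p$center_xy[2L] + ry * sin(a[q]), zs[k])
    }
    rings[[k]] <- idx
    angs[[k]] <- a
    if (k > 1L) addf(ring_zipper(rings[[k - 1L]], angs[[k - 1L]], idx, a))
  }
  bot <- addv(p$center_xy[1L], p$center_xy[2L], p$z_bottom - 0.05 * zspan)
  m1 <- length(rings[[1L]])
  for (q in seq_len(m1)) addf(c(rings[[1L]][q %% m1 + 1L], rings[[1L]][q], bot))
  top <- addv(p$center_xy[1L], p$center_xy[2L], p$z_top + 0.05 * zspan)
  mk <- length(rings[[nz + 1L]])
  last <- rings[[nz + 1L]]
  for (q in seq_len(mk)) addf(c(last[q], last[q %% mk + 1L], top))

  V <- do.call(rbind, verts)
  mesh <- triangle_mesh(V, do.call(rbind, faces), rep("TORSO", nrow(V)))
  mesh <- orient_faces_outward(mesh)

  # containment with margin: every heart vertex inside the torso shrunk by
  # `margin` in the transverse plane and along z
  hv <- heart$mesh$vertices
  rr <- sqrt(((hv[, 1L] - p$center_xy[1L]) / (p$rx - p$margin))^2 +
             ((hv[, 2L] - p$center_xy[2L]) / (p$ry - p$margin))^2)
  if (any(rr >= 1) || any(hv[, 3L] <= p$z_bottom + p$margin) ||
      any(hv[, 3L] >= p$z_top - p$margin)) {
    stop("heart does not fit inside the torso with the required margin")
  }
  if (!all(points_in_mesh(mesh, hv))) {
    stop("heart must lie strictly inside the torso mesh")
  }

  # electrode panels: azimuth centres (anterior +y, left +x, posterior -y,
  # right -x), 4 strips x 8 rows per panel
  panel_centres <- c(pi / 2, 3 * pi / 2, 0, pi)
  strip_off <- c(-0.55, -0.18, 0.18, 0.55)
  rowz <- seq(-150, 30, length.out = 8L)
  surf_r <- function(a) p$rx * p$ry / sqrt((p$ry * cos(a))^2 + (p$rx * sin(a))^2)
  targets <- list()
  for (pc in panel_centres) {
    for (so in strip_off) {
      a <- pc + so
      for (z in rowz) {
        targets[[length(targets) + 1L]] <-
          c(p$center_xy[1L] + surf_r(a) * cos(a),
            p$center_xy[2L] + surf_r(a) * sin(a), z)
      }
    }
  }
  targets <- do.call(rbind, targets)
  used <- integer(0)
  elec <- integer(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    d2 <- rowSums((V - matrix(targets[i, ], nrow(V), 3L, byrow = TRUE))^2)
    d2[used] <- Inf
    elec[i] <- which.min(d2)
    used <- c(used, elec[i])
  }
  cx <- p$center_xy[1L]; cy <- p$center_xy[2L]
  limb_targets <- rbind(c(cx - p$rx, cy, p$z_top - 0.22 * zspan),   # RA
                        c(cx + p$rx, cy, p$z_top - 0.22 * zspan),   # LA
                        c(cx + p$rx, cy, p$z_bottom + 0.18 * zspan),# LL
                        c(cx - p$rx, cy, p$z_bottom + 0.18 * zspan))
  limb <- integer(4L)
  for (i in 1:4) {
    d2 <- rowSums((V - matrix(limb_targets[i, ], nrow(V), 3L, byrow = TRUE))^2)
    d2[used] <- Inf
    limb[i] <- which.min(d2)
    used <- c(used, limb[i])
  }
  torso_geometry(mesh, elec, limb)
}
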