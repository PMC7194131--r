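#' Signed solid angle of a triangle
#'
#' Analytic plane-triangle solid angle (van Oosterom-Strackee formula). The
#' sign follows the triangle winding order: positive when the oriented normal
#' faces away from the observer side given by the right-hand rule.
#'
#' Degenerate cases follow the conventions used by the BEM assembly: an
#' observer in the plane of the triangle subtends zero solid angle; when it
#' additionally lies inside the triangle the result carries attribute
#' `singular = TRUE`.
#'
#' @param triangle numeric `3 x 3` matrix; rows are the triangle vertices.
#' @param observer numeric length-3 point.
#' @return solid angle in steradians (attribute `singular` flags an observer
#'   on the triangle interior).
#' @export
triangle_solid_angle <- function(triangle, observer) {
  triangle <- matrix(as.double(triangle), 3L, 3L)
  observer <- as.double(observer)
  if (length(observer) != 3L) stop("`observer` must be a 3-vector")
  w <- .solid_angle_matrix_cpp(triangle, matrix(1:3, 1L, 3L),
                               matrix(observer, 1L, 3L))[1L, 1L]
  # coplanar-interior detection for the singular flag
  n <- pracma_cross(triangle[2L, ] - triangle[1L, ],
                    triangle[3L, ] - triangle[1L, ])
  nn <- sqrt(sum(n^2))
  singular <- FALSE
  if (nn > 0) {
    h <- sum((observer - triangle[1L, ]) * n) / nn
    if (abs(h) < 1e-9 * sqrt(nn)) {
      b <- barycentric_coords(triangle, observer)
      if (all(b > -1e-9)) {
        singular <- TRUE
        w <- 0
      }
    }
  }
  structure(w, singular = singular)
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

barycentric_coords <- function(triangle, p) {
  v0 <- triangle[2L, ] - triangle[1L, ]
  v1 <- triangle[3L, ] - triangle[1L, ]
  v2 <- p - triangle[1L, ]
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  c(1 - v - w, v, w)
}

#' Solid-angle matrix of a mesh seen from observer points
#'
#' @param vertices `n x 3` vertex matrix.
#' @param faces `m x 3` 1-based face index matrix.
#' @param observers `k x 3` observer points.
#' @return `k x m` matrix of signed solid angles (steradians).
#' @keywords internal
solid_angle_matrix <- function(vertices, faces, observers) {
  .solid_angle_matrix_cpp(as.matrix(vertices),
                          matrix(as.integer(faces), ncol = 3L),
                          matrix(as.double(observers), ncol = 3L))
}

#' Analytic harmonic transfer ratio between concentric spheres
#'
#' Closed-form oracle for the forward model: a pure degree-`l` spherical
#' harmonic potential prescribed on the inner sphere (radius `a`) of a
#' homogeneous conducting shell with an insulated outer boundary (radius `b`)
#' appears on the outer sphere attenuated by
#' \deqn{\frac{\phi(b)}{\phi(a)} = \frac{(2l+1)\,b^l}{(l+1)a^l + l\,b^{2l+1}a^{-(l+1)}}}
#' obtained from \eqn{\phi = Ar^l + Br^{-(l+1)}} with \eqn{\phi'(b) = 0}.
#'
#' @param l harmonic degree (integer >= 0).
#' @param a inner radius.
#' @param b outer radius, `b > a`.
#' @return attenuation ratio in (0, 1].
#' @export
analytic_sphere_transfer <- function(l, a, b) {
  if (any(a <= 0) || any(b <= a)) stop("need 0 < a < b")
  if (any(l < 0) || any(l != round(l))) stop("`l` must be a non-negative integer")
  (2 * l + 1) * b^l / ((l + 1) * a^l + l * b^(2 * l + 1) * a^(-(l + 1)))
}

#' Assemble the two-surface boundary-element system
#'
#' Builds the potential-based BEM for a homogeneous, isotropic volume
#' conductor bounded externally by a closed torso surface (zero normal
#' current) and internally by a closed heart surface on which the potential
#' is prescribed. Collocation is at vertices; the double layer uses analytic
#' plane-triangle solid angles lumped equally to the face vertices, and the
#' heart-surface single layer uses an analytic formula for singular entries
#' with adaptively subdivided quadrature elsewhere. The diagonal (interior
#' solid angle at each collocation point) is fixed by the closure sum rule,
#' which makes a constant heart potential transfer exactly.
#'
#' Normals are re-oriented outward automatically before assembly. The mixed
#' Dirichlet/Neumann system is full rank (the prescribed heart potential
#' pins the additive constant); an optional rank-one deflation term fixing
#' the mean torso potential is applied only if the assembled system is
#' numerically near-singular.
#'
#' @param heart a `heart_geometry` (or any closed `triangle_mesh` wrapped in
#'   one) strictly inside the torso.
#' @param torso a `torso_geometry` with a closed mesh.
#' @param deflation_tol reciprocal-condition threshold below which the
#'   rank-one deflation term is added.
#' @return a `bem_system` object.
#' @export
build_bem_system <- function(heart, torso, deflation_tol = 1e-12) {
  hmesh <- heart$mesh
  tmesh <- torso$mesh
  if (!mesh_is_closed(hmesh)) stop("heart mesh is not closed")
  if (!mesh_is_closed(tmesh)) stop("torso mesh is not closed")
  hmesh <- orient_faces_outward(hmesh)
  tmesh <- orient_faces_outward(tmesh)
  if (!all(points_in_mesh(tmesh, hmesh$vertices))) {
    stop("heart mesh must lie strictly inside the torso mesh")
  }
  n_t <- nrow(tmesh$vertices)
  n_h <- nrow(hmesh$vertices)
  obs <- rbind(tmesh$vertices, hmesh$vertices)
  # domain-outward orientation: torso as-is, heart faces reversed (normals
  # point out of the conducting volume, i.e. into the heart solid)
  heart_faces_rev <- hmesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  W_t <- solid_angle_matrix(tmesh$vertices, tmesh$faces, obs)
  W_h <- solid_angle_matrix(hmesh$vertices, heart_faces_rev, obs)
  alpha <- rowSums(W_t) + rowSums(W_h)
  lump <- function(W, faces, nv) {
    D <- matrix(0, nrow(W), nv)
    for (cc in 1:3) {
      idx <- faces[, cc]
      M <- t(rowsum(t(W), group = idx, reorder = FALSE))
      cols <- as.integer(colnames(M))
      D[, cols] <- D[, cols] + M / 3
    }
    D
  }
  D_t <- lump(W_t, tmesh$faces, n_t)
  D_h <- lump(W_h, heart_faces_rev, n_h)
  obs_vertex <- c(rep(0L, n_t), seq_len(n_h))
  S_h <- .single_layer_matrix_cpp(hmesh$vertices,
                                  matrix(as.integer(hmesh$faces), ncol = 3L),
                                  obs, as.integer(obs_vertex))
  # alpha_i phi_i - sum_j D_ij phi_j = sum_v S_iv gamma_v
  M <- cbind(-D_t, -D_h)
  diag_idx <- cbind(seq_len(n_t + n_h), seq_len(n_t + n_h))
  M[diag_idx] <- M[diag_idx] + alpha
  K <- cbind(M[, 1:n_t, drop = FALSE], -S_h)
  deflation <- 0
  rc <- rcond_estimate(K)
  if (rc < deflation_tol) {
    deflation <- mean(abs(diag(K)))
    w <- c(rep(1 / n_t, n_t), rep(0, n_h))
    K <- K + deflation * outer(rep(1, nrow(K)), w)
  }
  structure(list(K = K, M_heart = M[, (n_t + 1):(n_t + n_h), drop = FALSE],
                 n_torso = n_t, n_heart = n_h,
                 heart_mesh = hmesh, torso_mesh = tmesh,
                 electrode_vertex_ids = torso$electrode_vertex_ids,
                 limb_lead_ids = torso$limb_lead_ids,
                 deflation = deflation),
            class = "bem_system")
}

rcond_estimate <- function(K) {
  out <- tryCatch(rcond(K), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}

#' @export
print.bem_system <- function(x, ...) {
  cat(sprintf("<bem_system> %d torso + %d heart collocation points\n",
              x$n_torso, x$n_heart))
  cat(sprintf("  deflation constant: %g\n", x$deflation))
  invisible(x)
}

#' Transfer matrix from heart-surface to body-surface potentials
#'
#' Solves the assembled BEM system for unit potentials at each heart node,
#' yielding the dense linear map from heart-surface potentials to torso
#' potentials; rows are then restricted to the electrode vertices (all torso
#' vertices when the torso carries no electrode layout).
#'
#' @param system a `bem_system` from [build_bem_system()].
#' @return a `transfer_matrix` object with elements `entries`
#'   (`n_electrodes x n_heart_nodes`), `limb_entries` (rows for the four
#'   limb-lead surrogate vertices, when present), `torso_entries` (all torso
#'   rows), `electrode_ids`, `heart_node_ids`.
#' @export
build_transfer_matrix <- function(system) {
  rhs <- -system$M_heart
  sol <- tryCatch(solve(system$K, rhs), error = function(e) {
    stop("BEM system is singular after assembly/deflation: ",
         conditionMessage(e))
  })
  phi_t <- sol[seq_len(system$n_torso), , drop = FALSE]
  elec <- system$electrode_vertex_ids
  if (is.null(elec)) elec <- seq_len(system$n_torso)
  limb <- system$limb_lead_ids
  structure(list(entries = phi_t[elec, , drop = FALSE],
                 limb_entries = if (!is.null(limb))
                   phi_t[limb, , drop = FALSE],
                 torso_entries = phi_t,
                 electrode_ids = elec,
                 limb_lead_ids = limb,
                 heart_node_ids = seq_len(system$n_heart)),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> %d electrodes x %d heart nodes\n",
              nrow(x$entries), ncol(x$entries)))
  invisible(x)
}

#' Forward-project heart-surface potentials to the electrodes
#'
#' @param heart_potentials `n_heart_nodes x n_time` matrix (microvolts).
#' @param transfer a `transfer_matrix`.
#' @param rows `"electrodes"` (default), `"limb"` or `"torso"`.
#' @return matrix of electrode potentials, same units, `n_rows x n_time`.
#' @export
forward_project <- function(heart_potentials, transfer,
                            rows = c("electrodes", "limb", "torso")) {
  rows <- match.arg(rows)
  x <- as.matrix(heart_potentials)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("heart potentials contain NA or non-finite values")
  }
  A <- switch(rows,
              electrodes = transfer$entries,
              limb = transfer$limb_entries,
              torso = transfer$torso_entries)
  if (is.null(A)) stop("requested rows are not available in this transfer matrix")
  if (ncol(A) != nrow(x)) stop("dimension mismatch between transfer matrix and potentials")
  A %*% x
}
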