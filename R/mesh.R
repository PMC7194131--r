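#' Triangulated surface mesh
#'
#' A `triangle_mesh` is the basic geometric container of the package: a set of
#' 3-D vertices (millimetres, right-handed coordinates), a triangle index
#' matrix, and a per-vertex anatomical surface label. All meshes fed to the
#' boundary-element forward model must be closed and orientable (every edge
#' shared by exactly two faces) with outward-pointing face normals.
#'
#' Vertex indexing is 1-based throughout (R convention); clinical segment
#' numbering in reports is 1-based as well.
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates in mm.
#' @param faces integer matrix, `m x 3`, 1-based vertex indices per triangle.
#' @param labels character or factor of length `n`; one of `"LV_ENDO"`,
#'   `"RV_ENDO"`, `"EPI"`, `"TORSO"`. Defaults to `"EPI"` for all vertices.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces`, `labels`.
#' @export
triangle_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("`faces` index vertices outside 1..n")
  }
  if (is.null(labels)) labels <- rep("EPI", nrow(vertices))
  labels <- as.character(labels)
  if (length(labels) != nrow(vertices)) {
    stop("`labels` must have one entry per vertex")
  }
  bad <- setdiff(unique(labels), surface_label_levels())
  if (length(bad)) stop("unknown surface labels: ", paste(bad, collapse = ", "))
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "triangle_mesh")
}

surface_label_levels <- function() c("LV_ENDO", "RV_ENDO", "EPI", "TORSO")

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  closed: %s, mean edge length: %.2f mm\n",
              mesh_is_closed(x), mean_edge_length(x)))
  invisible(x)
}

#' Edge table of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return integer matrix of unique undirected edges (2 columns) with an
#'   attribute `"count"` giving the number of incident faces per edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  key <- paste(e[, 1L], e[, 2L])
  cnt <- table(key)
  uniq <- !duplicated(key)
  out <- e[uniq, , drop = FALSE]
  attr(out, "count") <- as.integer(cnt[paste(out[, 1L], out[, 2L])])
  out
}

#' Closedness check
#'
#' A mesh is closed (watertight) when every edge is shared by exactly two
#' faces. Disconnected closed components also pass.
#'
#' @param mesh a `triangle_mesh`.
#' @return logical scalar.
#' @export
mesh_is_closed <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  all(attr(mesh_edges(mesh), "count") == 2L)
}

#' Edge lengths and mesh resolution
#'
#' @param mesh a `triangle_mesh`.
#' @return `mesh_edge_lengths()`: numeric vector of unique edge lengths (mm);
#'   `mean_edge_length()`: their mean, the conventional mesh-resolution figure.
#' @export
mesh_edge_lengths <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1L], , drop = FALSE] -
    mesh$vertices[e[, 2L], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' @rdname mesh_edge_lengths
#' @export
mean_edge_length <- function(mesh) mean(mesh_edge_lengths(mesh))

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Face areas and normals
#'
#' @param mesh a `triangle_mesh`.
#' @return `face_areas()`: numeric vector (mm^2); `face_normals()`: `m x 3`
#'   matrix of unit normals following the stored winding order.
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr * cr))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  nrm <- sqrt(rowSums(cr * cr))
  cr / pmax(nrm, .Machine$double.eps)
}

#' Signed enclosed volume
#'
#' Divergence-theorem volume of a closed oriented mesh; positive when face
#' normals point outward.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric scalar (mm^3).
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  sum(p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
      p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
      p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])) / 6
}

#' Re-orient faces consistently outward
#'
#' Makes the winding order consistent across each connected component by
#' flood fill over shared edges, then flips whole components whose signed
#' volume is negative, so that normals point out of the enclosed solid.
#' Input files from external tools frequently carry mixed orientation; the
#' BEM assembly calls this automatically.
#'
#' @param mesh a closed `triangle_mesh`.
#' @return the mesh with consistently outward-oriented faces.
#' @export
orient_faces_outward <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  if (m == 0L) return(mesh)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  # map undirected edge -> incident faces
  e_all <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  fid <- rep(seq_len(m), times = 3L)
  key <- ekey(e_all[, 1L], e_all[, 2L])
  inc <- split(fid, key)
  # directed-edge keys per face for orientation comparison
  visited <- rep(FALSE, m)
  flipped <- rep(FALSE, m)
  face_dir_edges <- function(i) {
    tri <- f[i, ]
    if (flipped[i]) tri <- tri[c(1L, 3L, 2L)]
    rbind(tri[c(1L, 2L)], tri[c(2L, 3L)], tri[c(3L, 1L)])
  }
  for (start in seq_len(m)) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      de_i <- face_dir_edges(i)
      for (r in 1:3) {
        a <- de_i[r, 1L]; b <- de_i[r, 2L]
        for (j in inc[[ekey(a, b)]]) {
          if (j == i || visited[j]) next
          de_j <- face_dir_edges(j)
          # consistent orientation: neighbour traverses the edge reversed
          same_dir <- any(de_j[, 1L] == a & de_j[, 2L] == b)
          flipped[j] <- same_dir
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  f2 <- f
  f2[flipped, ] <- f[flipped, c(1L, 3L, 2L), drop = FALSE]
  out <- mesh
  out$faces <- f2
  # flip whole components with negative enclosed volume
  comp <- mesh_face_components(out)
  for (cc in unique(comp)) {
    sub <- out
    sub$faces <- out$faces[comp == cc, , drop = FALSE]
    if (mesh_signed_volume(sub) < 0) {
      idx <- comp == cc
      out$faces[idx, ] <- out$faces[idx, c(1L, 3L, 2L), drop = FALSE]
    }
  }
  out
}

# connected components over shared edges, one id per face
mesh_face_components <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e_all <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  fid <- rep(seq_len(m), times = 3L)
  inc <- split(fid, ekey(e_all[, 1L], e_all[, 2L]))
  comp <- integer(m)
  cur <- 0L
  for (start in seq_len(m)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      tri <- f[i, ]
      for (r in 1:3) {
        k <- ekey(tri[r], tri[if (r == 3L) 1L else r + 1L])
        for (j in inc[[k]]) {
          if (comp[j] == 0L) {
            comp[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  comp
}

#' Test whether points lie inside a closed mesh
#'
#' Winding-number test via summed solid angles: a point is inside when the
#' total solid angle subtended by the (outward-oriented) surface is close to
#' 4*pi.
#'
#' @param mesh a closed, outward-oriented `triangle_mesh`.
#' @param points numeric matrix `k x 3`.
#' @return logical vector of length `k`.
#' @export
points_in_mesh <- function(mesh, points) {
  points <- matrix(as.double(points), ncol = 3L)
  w <- solid_angle_matrix(mesh$vertices, mesh$faces, points)
  abs(rowSums(w)) > 2 * pi
}

rigid_transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  out <- mesh
  out$vertices <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3L, byrow = TRUE)
  out
}
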