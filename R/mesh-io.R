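#' Read and write triangle meshes
#'
#' Supported formats: PLY (ASCII and binary little-endian), Wavefront OBJ,
#' and legacy-VTK polydata (ASCII). PLY and VTK carry the per-vertex integer
#' property `surface_label` (coded by [surface_label_levels()] order) and
#' round-trip it exactly; OBJ has no vertex-attribute slot, so labels are
#' dropped on write and default to `EPI` on read.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"obj"`, `"vtk"`; inferred from the file
#'   extension when missing.
#' @return `read_mesh()`: a `triangle_mesh`. `write_mesh()`: `path`,
#'   invisibly.
#' @export
read_mesh <- function(path, format = NULL) {
  format <- infer_mesh_format(path, format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         ply = read_ply(path),
         obj = read_obj(path),
         vtk = read_vtk(path))
}

#' @param mesh a `triangle_mesh`.
#' @param binary for PLY only: write binary little-endian instead of ASCII.
#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  format <- infer_mesh_format(path, format)
  switch(format,
         ply = write_ply(mesh, path, binary),
         obj = write_obj(mesh, path),
         vtk = write_vtk(mesh, path))
  invisible(path)
}

infer_mesh_format <- function(path, format) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- tolower(format)
  if (!format %in% c("ply", "obj", "vtk")) {
    stop("unsupported mesh format: ", format)
  }
  format
}

label_to_code <- function(labels) {
  match(labels, surface_label_levels()) - 1L
}

code_to_label <- function(codes) {
  lv <- surface_label_levels()
  out <- lv[codes + 1L]
  if (anyNA(out)) stop("invalid surface_label codes in file")
  out
}

write_ply <- function(mesh, path, binary) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           "property int surface_label",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  codes <- label_to_code(mesh$labels)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    for (i in seq_len(nv)) {
      writeBin(as.double(mesh$vertices[i, ]), con, size = 8,
               endian = "little")
      writeBin(codes[i], con, size = 4, endian = "little")
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    vl <- sprintf("%.17g %.17g %.17g %d", mesh$vertices[, 1L],
                  mesh$vertices[, 2L], mesh$vertices[, 3L], codes)
    fl <- sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                  mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L)
    writeLines(c(hdr, vl, fl), path)
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("PLY parse error: truncated header in ", path)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
    if (length(hdr) > 200L) stop("PLY parse error: header too long")
  }
  if (hdr[1L] != "ply") stop("PLY parse error: missing magic line (line 1)")
  fmt <- grep("^format ", hdr, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)))
  if (!length(nv) || !length(nf) || is.na(nv) || is.na(nf)) {
    stop("PLY parse error: missing element counts in header")
  }
  vprops <- sub("^property ", "",
                grep("^property (?!list)", hdr, value = TRUE, perl = TRUE))
  has_label <- any(grepl("surface_label", vprops))
  if (binary) {
    V <- matrix(0, nv, 3L)
    codes <- integer(nv)
    for (i in seq_len(nv)) {
      xyz <- readBin(con, "double", 3L, size = 8, endian = "little")
      if (length(xyz) < 3L) stop("PLY parse error: truncated vertex ", i)
      V[i, ] <- xyz
      if (has_label) codes[i] <- readBin(con, "integer", 1L, size = 4,
                                         endian = "little")
    }
    F <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1L))
      if (length(cnt) == 0L || cnt != 3L) {
        stop("PLY parse error: face ", i, " is not a triangle")
      }
      F[i, ] <- readBin(con, "integer", 3L, size = 4, endian = "little") + 1L
    }
  } else {
    body <- readLines(con)
    if (length(body) < nv + nf) {
      stop("PLY parse error: expected ", nv + nf, " body lines, found ",
           length(body))
    }
    vparts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]),
                                             "\\s+"), as.numeric))
    V <- vparts[, 1:3, drop = FALSE]
    codes <- if (has_label && ncol(vparts) >= 4L) as.integer(vparts[, 4L])
             else integer(nv)
    fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    F <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      x <- as.integer(fparts[[i]])
      if (length(x) < 4L || x[1L] != 3L) {
        stop("PLY parse error: face line ", nv + i,
             " is not a triangle record")
      }
      F[i, ] <- x[2:4] + 1L
    }
  }
  labels <- if (has_label) code_to_label(codes) else rep("EPI", nv)
  triangle_mesh(V, F, labels)
}

write_obj <- function(mesh, path) {
  vl <- sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1L],
                mesh$vertices[, 2L], mesh$vertices[, 3L])
  fl <- sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                mesh$faces[, 3L])
  writeLines(c("# ecgimap OBJ export (surface labels not representable)",
               vl, fl), path)
  invisible(path)
}

read_obj <- function(path) {
  lns <- readLines(path)
  vln <- grep("^v ", lns)
  fln <- grep("^f ", lns)
  if (!length(vln) || !length(fln)) {
    stop("OBJ parse error: no vertex/face records in ", path)
  }
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", lns[vln])),
                                      "\\s+"),
                             function(x) as.numeric(x[x != ""])))
  F <- do.call(rbind, lapply(seq_along(fln), function(k) {
    x <- strsplit(trimws(sub("^f", "", lns[fln[k]])), "\\s+")[[1L]]
    x <- x[x != ""]
    idx <- as.integer(sub("/.*$", "", x))
    if (length(idx) != 3L || anyNA(idx)) {
      stop("OBJ parse error at line ", fln[k], ": need triangular faces")
    }
    idx
  }))
  triangle_mesh(V[, 1:3, drop = FALSE], F, rep("EPI", nrow(V)))
}

write_vtk <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  lns <- c("# vtk DataFile Version 3.0", "ecgimap surface mesh", "ASCII",
           "DATASET POLYDATA",
           sprintf("POINTS %d double", nv),
           sprintf("%.17g %.17g %.17g", mesh$vertices[, 1L],
                   mesh$vertices[, 2L], mesh$vertices[, 3L]),
           sprintf("POLYGONS %d %d", nf, 4L * nf),
           sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                   mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L),
           sprintf("POINT_DATA %d", nv),
           "SCALARS surface_label int 1",
           "LOOKUP_TABLE default",
           sprintf("%d", label_to_code(mesh$labels)))
  writeLines(lns, path)
  invisible(path)
}

read_vtk <- function(path) {
  lns <- readLines(path)
  pt <- grep("^POINTS", lns)
  if (!length(pt)) stop("VTK parse error: no POINTS section in ", path)
  nv <- as.integer(strsplit(lns[pt], "\\s+")[[1L]][2L])
  # points may span a variable number of lines; consume 3*nv numbers
  i <- pt
  acc <- numeric(0)
  while (length(acc) < 3L * nv) {
    i <- i + 1L
    if (i > length(lns)) stop("VTK parse error: truncated POINTS at line ", i)
    acc <- c(acc, as.numeric(strsplit(trimws(lns[i]), "\\s+")[[1L]]))
  }
  V <- matrix(acc[seq_len(3L * nv)], ncol = 3L, byrow = TRUE)
  pg <- grep("^POLYGONS", lns)
  if (!length(pg)) stop("VTK parse error: no POLYGONS section in ", path)
  nf <- as.integer(strsplit(lns[pg], "\\s+")[[1L]][2L])
  facc <- integer(0)
  i <- pg
  while (length(facc) < 4L * nf) {
    i <- i + 1L
    if (i > length(lns)) stop("VTK parse error: truncated POLYGONS at line ", i)
    facc <- c(facc, as.integer(strsplit(trimws(lns[i]), "\\s+")[[1L]]))
  }
  Fm <- matrix(facc[seq_len(4L * nf)], ncol = 4L, byrow = TRUE)
  if (any(Fm[, 1L] != 3L)) stop("VTK parse error: non-triangular polygon")
  labels <- rep("EPI", nv)
  sl <- grep("^SCALARS surface_label", lns)
  if (length(sl)) {
    lacc <- integer(0)
    i <- sl + 1L  # LOOKUP_TABLE line
    while (length(lacc) < nv) {
      i <- i + 1L
      if (i > length(lns)) stop("VTK parse error: truncated POINT_DATA")
      lacc <- c(lacc, as.integer(strsplit(trimws(lns[i]), "\\s+")[[1L]]))
    }
    labels <- code_to_label(lacc[seq_len(nv)])
  }
  triangle_mesh(V, Fm[, 2:4, drop = FALSE] + 1L, labels)
}
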