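#' Triangulated surface mesh
#'
#' Container for a closed (watertight) triangulated surface, the standard
#' representation of a segmented vessel wall exported from lumen segmentation
#' software.  Coordinates are millimetres throughout the package.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles integer matrix, one row per triangle, columns indexing
#'   rows of `vertices` (1-based).  Triangles must be consistently oriented
#'   (outward normals) for watertightness checks to pass.
#' @param source optional character label recording where the mesh came from
#'   (a file name, or a generator description).
#'
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles` and `source`.
#' @export
surface_mesh <- function(vertices, triangles, source = "unknown") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z)")
  if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
  if (nrow(triangles) < 4L) stop("a closed surface needs at least 4 triangles")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices)) {
    stop("triangle indices out of range")
  }
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3])) {
    stop("degenerate triangles (repeated vertex index)")
  }
  structure(
    list(vertices = vertices, triangles = triangles, source = source),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf(
    "surface_mesh: %d vertices, %d triangles (source: %s)\n",
    nrow(x$vertices), nrow(x$triangles), x$source
  ))
  cat(sprintf(
    "  bounding box [mm]: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
    bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]
  ))
  invisible(x)
}

#' Check that a mesh is watertight
#'
#' A surface is watertight when every undirected edge is shared by exactly two
#' triangles and the two incident triangles traverse it in opposite directions
#' (consistent orientation).  Slicing and interior voxelization both require
#' this property.
#'
#' @param mesh a [surface_mesh()].
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  from <- c(tr[, 1], tr[, 2], tr[, 3])
  to <- c(tr[, 2], tr[, 3], tr[, 1])
  ukey <- paste(pmin(from, to), pmax(from, to))
  counts <- table(ukey)
  if (any(counts != 2L)) return(FALSE)
  # consistent orientation: each directed edge must appear exactly once
  dkey <- paste(from, to)
  !anyDuplicated(dkey)
}

#' Per-triangle unit normals and areas
#' @param mesh a [surface_mesh()].
#' @return list with `normals` (n x 3) and `areas` (mm^2).
#' @keywords internal
triangle_geometry <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nrm <- sqrt(rowSums(cr^2))
  list(normals = cr / pmax(nrm, .Machine$double.eps), areas = nrm / 2)
}

#' Volume enclosed by a watertight mesh (signed, positive for outward normals)
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  sum(det) / 6
}

#' Minimum distance from points to a mesh surface
#'
#' Exact point-to-triangle distances, minimised over all triangles.  Used to
#' evaluate the inscribed radius along a centerline.
#'
#' @param points numeric matrix (n x 3), mm.
#' @param mesh a [surface_mesh()].
#' @return numeric vector of distances (mm), one per point.
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- rbind(points)
  v <- mesh$vertices
  tr <- mesh$triangles
  A <- v[tr[, 1], , drop = FALSE]
  B <- v[tr[, 2], , drop = FALSE]
  C <- v[tr[, 3], , drop = FALSE]
  e1 <- B - A
  e2 <- C - A
  d11 <- rowSums(e1 * e1)
  d22 <- rowSums(e2 * e2)
  d12 <- rowSums(e1 * e2)
  denom <- d11 * d22 - d12^2
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    w <- cbind(p[1] - A[, 1], p[2] - A[, 2], p[3] - A[, 3])
    wd1 <- rowSums(w * e1)
    wd2 <- rowSums(w * e2)
    # barycentric coordinates of the in-plane projection
    s <- (d22 * wd1 - d12 * wd2) / denom
    t <- (d11 * wd2 - d12 * wd1) / denom
    inside <- s >= 0 & t >= 0 & (s + t) <= 1
    dmin <- Inf
    if (any(inside)) {
      proj <- A[inside, , drop = FALSE] +
        s[inside] * e1[inside, , drop = FALSE] +
        t[inside] * e2[inside, , drop = FALSE]
      dif <- proj - matrix(p, nrow(proj), 3, byrow = TRUE)
      dmin <- sqrt(min(rowSums(dif^2)))
    }
    seg_d2 <- function(P0, E, ee) {
      wv <- cbind(p[1] - P0[, 1], p[2] - P0[, 2], p[3] - P0[, 3])
      tt <- pmin(pmax(rowSums(wv * E) / ee, 0), 1)
      dif <- wv - E * tt
      min(rowSums(dif^2))
    }
    d2 <- min(seg_d2(A, e1, d11), seg_d2(A, e2, d22),
              seg_d2(B, C - B, rowSums((C - B)^2)))
    min(dmin, sqrt(d2))
  }, numeric(1))
}

#' Read an STL file (binary or ASCII)
#'
#' Coincident vertices are merged so that the result is an indexed mesh on
#' which watertightness can be verified.
#'
#' @param path file path.
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  fsize <- file.size(path)
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    fsize == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    raw <- readBin(con, "raw", n = 50L * ntri)
    m <- matrix(raw, nrow = 50L)
    flo <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                   n = 12L * ntri, endian = "little")
    flo <- matrix(flo, ncol = 12L, byrow = TRUE)
    verts <- rbind(flo[, 4:6], flo[, 7:9], flo[, 10:12])
    ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
    verts <- verts[ord, , drop = FALSE]
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L) {
      stop("not a valid STL file: ", path)
    }
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(f) {
      as.numeric(f[2:4])
    }))
  }
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  idx <- match(key, key)
  keep <- !duplicated(idx)
  remap <- cumsum(keep)[idx]
  surface_mesh(verts[keep, , drop = FALSE],
               matrix(remap, ncol = 3L, byrow = TRUE),
               source = basename(path))
}

#' Write a mesh as binary STL (millimetre units)
#'
#' Output is deterministic: identical meshes produce byte-identical files.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  tg <- triangle_geometry(mesh)
  v <- mesh$vertices
  tr <- mesh$triangles
  ntri <- nrow(tr)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "vesselwss binary STL (mm)"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  block <- matrix(0, nrow = 12L, ncol = ntri)
  block[1:3, ] <- t(tg$normals)
  block[4:6, ] <- t(v[tr[, 1], , drop = FALSE])
  block[7:9, ] <- t(v[tr[, 2], , drop = FALSE])
  block[10:12, ] <- t(v[tr[, 3], , drop = FALSE])
  floats <- writeBin(as.vector(block), raw(), size = 4L, endian = "little")
  fm <- matrix(floats, nrow = 48L)
  out <- rbind(fm, matrix(as.raw(0L), nrow = 2L, ncol = ntri))
  writeBin(as.vector(out), con)
  invisible(path)
}

#' Apply a rigid transform to a mesh
#' @param mesh a [surface_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 offset (mm).
#' @return transformed [surface_mesh()].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  surface_mesh(v, mesh$triangles, source = mesh$source)
}
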