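# Plane slicing of watertight triangle meshes.
#
# A slicing plane is given by a point and a unit normal.  Every triangle
# straddling the plane contributes one segment; because crossing points are
# computed once per (canonically oriented) mesh edge, segments from adjacent
# triangles share endpoints exactly and chain into closed contours without a
# tolerance search.  Contours are returned in 2D plane coordinates.

plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(n = n, u = u, v = v)
}

# All closed intersection contours of mesh and plane, as a list of 2D
# polygon matrices (columns u, v; plane point at the origin).  Returns an
# empty list when the plane misses the mesh.
slice_contours <- function(mesh, point, normal) {
  bs <- plane_basis(normal)
  verts <- mesh$vertices
  tr <- mesh$triangles
  dv <- (verts[, 1] - point[1]) * bs$n[1] +
    (verts[, 2] - point[2]) * bs$n[2] +
    (verts[, 3] - point[3]) * bs$n[3]
  # nudge vertices lying exactly on the plane to keep crossings generic
  scale <- max(abs(dv), 1)
  dv[dv == 0] <- 1e-12 * scale
  d1 <- dv[tr[, 1]]
  d2 <- dv[tr[, 2]]
  d3 <- dv[tr[, 3]]
  crosses <- (pmin(d1, d2, d3) < 0) & (pmax(d1, d2, d3) > 0)
  if (!any(crosses)) return(list())
  trc <- tr[crosses, , drop = FALSE]

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seg_ends <- vector("list", nrow(trc))
  cross_pts <- new.env(parent = emptyenv())
  pt_on_edge <- function(a, b) {
    key <- edge_key(a, b)
    hit <- cross_pts[[key]]
    if (!is.null(hit)) return(hit)
    lo <- min(a, b)
    hi <- max(a, b)
    tt <- dv[lo] / (dv[lo] - dv[hi])
    p <- verts[lo, ] + tt * (verts[hi, ] - verts[lo, ])
    cross_pts[[key]] <- p
    p
  }
  seg_keys <- matrix("", nrow(trc), 2L)
  for (i in seq_len(nrow(trc))) {
    v3 <- trc[i, ]
    dd <- dv[v3]
    ks <- character(0)
    pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
    for (pr in pairs) {
      if (dd[pr[1]] * dd[pr[2]] < 0) {
        pt_on_edge(v3[pr[1]], v3[pr[2]])
        ks <- c(ks, edge_key(v3[pr[1]], v3[pr[2]]))
      }
    }
    if (length(ks) != 2L) return(list()) # degenerate slice; treat as miss
    seg_keys[i, ] <- ks
  }
  keys <- unique(as.vector(seg_keys))
  idx <- stats::setNames(seq_along(keys), keys)
  a <- idx[seg_keys[, 1]]
  b <- idx[seg_keys[, 2]]
  # adjacency: on a watertight mesh every crossing point joins exactly 2
  # segments, so the segments decompose into disjoint cycles
  adj <- vector("list", length(keys))
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  deg <- lengths(adj)
  if (any(deg != 2L)) {
    stop("open contour: slice produced a non-closed intersection")
  }
  pts3 <- t(vapply(keys, function(k) cross_pts[[k]], numeric(3)))
  p2 <- cbind((pts3[, 1] - point[1]) * bs$u[1] +
                (pts3[, 2] - point[2]) * bs$u[2] +
                (pts3[, 3] - point[3]) * bs$u[3],
              (pts3[, 1] - point[1]) * bs$v[1] +
                (pts3[, 2] - point[2]) * bs$v[2] +
                (pts3[, 3] - point[3]) * bs$v[3])
  visited <- logical(length(keys))
  contours <- list()
  for (start in seq_along(keys)) {
    if (visited[start]) next
    cyc <- integer(0)
    cur <- start
    prev <- 0L
    repeat {
      visited[cur] <- TRUE
      cyc <- c(cyc, cur)
      nxt <- adj[[cur]]
      nxt <- nxt[nxt != prev]
      if (length(nxt) == 0L) break
      nxt <- nxt[1]
      if (nxt == start) break
      prev <- cur
      cur <- nxt
    }
    if (length(cyc) >= 3L) {
      contours[[length(contours) + 1L]] <- p2[cyc, , drop = FALSE]
    }
  }
  contours
}

polygon_area_centroid <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) {
    return(list(area = 0, centroid = colMeans(poly)))
  }
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = abs(a), centroid = c(cx, cy))
}

point_in_polygon <- function(pt, poly) {
  x <- poly[, 1] - pt[1]
  y <- poly[, 2] - pt[2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  crossing <- ((y > 0) != (yn > 0)) &
    (x - y * (xn - x) / (yn - y) > 0)
  sum(crossing) %% 2L == 1L
}

# Pick the contour containing the query point (origin of plane coordinates);
# tie-break / fallback: smallest centroid distance.
select_contour <- function(contours) {
  containing <- which(vapply(contours, function(p) {
    point_in_polygon(c(0, 0), p)
  }, logical(1)))
  if (length(containing) == 1L) return(contours[[containing]])
  pool <- if (length(containing) > 1L) containing else seq_along(contours)
  cd <- vapply(pool, function(i) {
    sum(polygon_area_centroid(contours[[i]])$centroid^2)
  }, numeric(1))
  contours[[pool[which.min(cd)]]]
}

#' Cross-sectional area of a mesh cut by a plane
#'
#' Intersects the (watertight) surface with the plane through `point` with
#' the given `normal`, chains the intersection into closed contours, selects
#' the contour enclosing `point` (or, failing containment, the one whose
#' centroid is nearest), and returns its enclosed area.
#'
#' @param mesh a [surface_mesh()].
#' @param point 3-point on the slicing plane (mm), typically a centerline
#'   sample.
#' @param normal plane normal (the local centerline tangent); need not be
#'   unit length.
#' @return cross-sectional area in mm^2.
#' @export
cross_section_area <- function(mesh, point, normal) {
  cs <- slice_contours(mesh, point, normal)
  if (length(cs) == 0L) stop("slicing plane does not intersect the mesh")
  polygon_area_centroid(select_contour(cs))$area
}

# Area and 3D centroid of the selected cross-section (used for centerline
# refinement); NULL when the plane misses the mesh.
cross_section_info <- function(mesh, point, normal) {
  cs <- tryCatch(slice_contours(mesh, point, normal), error = function(e) list())
  if (length(cs) == 0L) return(NULL)
  poly <- select_contour(cs)
  ac <- polygon_area_centroid(poly)
  bs <- plane_basis(normal)
  centroid3 <- point + ac$centroid[1] * bs$u + ac$centroid[2] * bs$v
  list(area = ac$area, centroid = centroid3)
}
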