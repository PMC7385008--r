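# Centerline extraction by the maximal inscribed sphere principle:
# the lumen is voxelized, a Euclidean distance field to the wall is computed,
# and the centerline is the minimum-cost path between the two openings with
# step cost inversely weighted by the local inscribed radius, so the path
# hugs the locus of maximal inscribed spheres.  The voxel-accurate path is
# then refined by replacing each sample with the area centroid of the
# perpendicular cross-section, which is exact on tubular geometry.

#' Arclength-parameterized centerline
#'
#' @param points n x 3 matrix of centerline points (mm), ordered.
#' @param tangents n x 3 matrix of unit tangents; computed by central
#'   differences when omitted.
#' @param radius optional inscribed radii (mm), one per point.
#' @return a `centerline` object with fields `points`, `s` (arclength from
#'   the curve start, mm), `tangents`, `radius`.
#' @export
centerline <- function(points, tangents = NULL, radius = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 3L) {
    stop("points must be an n x 3 matrix with n >= 3")
  }
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) stop("repeated consecutive points")
  s <- c(0, cumsum(seg))
  if (is.null(tangents)) tangents <- polyline_tangents(points, s)
  tn <- sqrt(rowSums(tangents^2))
  if (any(abs(tn - 1) > 1e-9)) tangents <- tangents / tn
  structure(list(points = points, s = s, tangents = tangents,
                 radius = radius),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d samples, arclength %.2f mm\n",
              nrow(x$points), max(x$s)))
  invisible(x)
}

polyline_tangents <- function(points, s) {
  n <- nrow(points)
  tg <- matrix(0, n, 3)
  tg[1, ] <- (points[2, ] - points[1, ]) / (s[2] - s[1])
  tg[n, ] <- (points[n, ] - points[n - 1, ]) / (s[n] - s[n - 1])
  i <- 2:(n - 1)
  tg[i, ] <- (points[i + 1, , drop = FALSE] - points[i - 1, , drop = FALSE]) /
    (s[i + 1] - s[i - 1])
  tg / sqrt(rowSums(tg^2))
}

# Linear interpolation of centerline point and unit tangent at arclengths s.
centerline_at <- function(cl, s) {
  pt <- cbind(stats::approx(cl$s, cl$points[, 1], xout = s)$y,
              stats::approx(cl$s, cl$points[, 2], xout = s)$y,
              stats::approx(cl$s, cl$points[, 3], xout = s)$y)
  tg <- cbind(stats::approx(cl$s, cl$tangents[, 1], xout = s)$y,
              stats::approx(cl$s, cl$tangents[, 2], xout = s)$y,
              stats::approx(cl$s, cl$tangents[, 3], xout = s)$y)
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = pt, tangents = tg)
}

# --- interior voxelization -------------------------------------------------

# Ray casting along the coordinate axis least parallel to the surface:
# for every grid column, crossing parities classify voxel centers as
# inside/outside the watertight surface.
voxelize_interior <- function(mesh, pitch, max_voxels = 4e6) {
  bb <- apply(mesh$vertices, 2, range)
  span <- bb[2, ] - bb[1, ]
  n <- pmax(ceiling(span / pitch) + 3L, 3L)
  while (prod(n) > max_voxels) {
    pitch <- pitch * 1.26
    n <- pmax(ceiling(span / pitch) + 3L, 3L)
  }
  orig <- bb[1, ] - pitch * 1.0137 # irregular offset avoids grid degeneracy
  ax_x <- seq_len(n[1]) * pitch + orig[1] - pitch / 2
  ax_y <- seq_len(n[2]) * pitch + orig[2] - pitch / 2
  ax_z <- seq_len(n[3]) * pitch + orig[3] - pitch / 2
  axes <- list(ax_x, ax_y, ax_z)

  tg <- triangle_geometry(mesh)
  w <- colSums(abs(tg$normals) * tg$areas)
  cast <- which.max(w)
  other <- setdiff(1:3, cast)
  b_ax <- axes[[other[1]]]
  c_ax <- axes[[other[2]]]
  nb <- length(b_ax)
  nc <- length(c_ax)

  v <- mesh$vertices
  tr <- mesh$triangles
  col_idx <- integer(0)
  xs <- numeric(0)
  nrm <- tg$normals
  for (i in seq_len(nrow(tr))) {
    if (abs(nrm[i, cast]) < 1e-12) next
    p1 <- v[tr[i, 1], ]
    p2 <- v[tr[i, 2], ]
    p3 <- v[tr[i, 3], ]
    b3 <- c(p1[other[1]], p2[other[1]], p3[other[1]])
    c3 <- c(p1[other[2]], p2[other[2]], p3[other[2]])
    ib <- which(b_ax >= min(b3) & b_ax <= max(b3))
    ic <- which(c_ax >= min(c3) & c_ax <= max(c3))
    if (length(ib) == 0L || length(ic) == 0L) next
    gb <- rep(b_ax[ib], times = length(ic))
    gc <- rep(c_ax[ic], each = length(ib))
    # barycentric point-in-triangle in the projection plane
    d1 <- (b3[2] - b3[1]) * (gc - c3[1]) - (c3[2] - c3[1]) * (gb - b3[1])
    d2 <- (b3[3] - b3[2]) * (gc - c3[2]) - (c3[3] - c3[2]) * (gb - b3[2])
    d3 <- (b3[1] - b3[3]) * (gc - c3[3]) - (c3[1] - c3[3]) * (gb - b3[3])
    inside <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
    if (!any(inside)) next
    gb <- gb[inside]
    gc <- gc[inside]
    # plane equation: n . (X - p1) = 0, solve for the cast coordinate
    xcr <- p1[cast] +
      (-(gb - p1[other[1]]) * nrm[i, other[1]] -
         (gc - p1[other[2]]) * nrm[i, other[2]]) / nrm[i, cast]
    ib_g <- rep(ib, times = length(ic))[inside]
    ic_g <- rep(ic, each = length(ib))[inside]
    col_idx <- c(col_idx, (ic_g - 1L) * nb + ib_g)
    xs <- c(xs, xcr)
  }
  mask <- array(FALSE, dim = c(length(axes[[cast]]), nb, nc))
  if (length(col_idx) > 0L) {
    xc <- axes[[cast]]
    by_col <- split(xs, col_idx)
    for (key in names(by_col)) {
      cr <- sort(by_col[[key]])
      if (length(cr) %% 2L != 0L) next # grazing column; leave outside
      fi <- findInterval(xc, cr)
      col <- as.integer(key)
      ic_g <- (col - 1L) %/% nb + 1L
      ib_g <- col - (ic_g - 1L) * nb
      mask[, ib_g, ic_g] <- fi %% 2L == 1L
    }
  }
  # permute mask back to (x, y, z) order
  perm <- order(c(cast, other))
  mask <- aperm(mask, perm)
  list(mask = mask, origin = orig, pitch = pitch, dims = dim(mask))
}

# Exact Euclidean distance transform (in voxels) of the inside mask:
# distance from each inside voxel to the nearest outside voxel.  Separable
# brute-force over offsets, vectorized over the whole array per offset.
edt3d <- function(mask) {
  d <- array(Inf, dim = dim(mask))
  d[!mask] <- 0
  nx <- dim(mask)[1]
  ny <- dim(mask)[2]
  nz <- dim(mask)[3]
  # pass 1: sequential scan along x (distance in voxel units)
  for (i in 2:nx) d[i, , ] <- pmin(d[i, , ], d[i - 1, , ] + 1)
  for (i in (nx - 1):1) d[i, , ] <- pmin(d[i, , ], d[i + 1, , ] + 1)
  # passes 2 and 3: min over squared-distance parabolas via offsets
  d2 <- d^2
  out <- d2
  for (k in seq_len(ny - 1)) {
    k2 <- k^2
    out[, seq_len(ny - k), ] <-
      pmin(out[, seq_len(ny - k), , drop = FALSE],
           d2[, k + seq_len(ny - k), , drop = FALSE] + k2)
    out[, k + seq_len(ny - k), ] <-
      pmin(out[, k + seq_len(ny - k), , drop = FALSE],
           d2[, seq_len(ny - k), , drop = FALSE] + k2)
  }
  d2 <- out
  for (k in seq_len(nz - 1)) {
    k2 <- k^2
    out[, , seq_len(nz - k)] <-
      pmin(out[, , seq_len(nz - k), drop = FALSE],
           d2[, , k + seq_len(nz - k), drop = FALSE] + k2)
    out[, , k + seq_len(nz - k)] <-
      pmin(out[, , k + seq_len(nz - k), drop = FALSE],
           d2[, , seq_len(nz - k), drop = FALSE] + k2)
  }
  sqrt(out)
}

# Minimum-cost path between two voxels through the inside mask; 26-connected,
# step cost = step length / (local inscribed radius + eps).
voxel_path <- function(vox, dist_mm, from_voxel, to_voxel) {
  dims <- vox$dims
  inside <- which(vox$mask)
  if (length(inside) == 0L) stop("voxelization produced an empty lumen")
  node_of <- integer(prod(dims))
  node_of[inside] <- seq_along(inside)
  nx <- dims[1]
  nxy <- dims[1] * dims[2]
  coord <- arrayInd(inside, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  keep <- offsets[, 1] + offsets[, 2] * 10 + offsets[, 3] * 100 > 0
  offsets <- offsets[keep, , drop = FALSE] # one direction per pair
  eps <- vox$pitch * 0.05
  rr <- dist_mm[inside]
  ef <- integer(0)
  et <- integer(0)
  ew <- numeric(0)
  for (o in seq_len(nrow(offsets))) {
    dxyz <- offsets[o, ]
    ok <- coord[, 1] + dxyz[1] >= 1 & coord[, 1] + dxyz[1] <= dims[1] &
      coord[, 2] + dxyz[2] >= 1 & coord[, 2] + dxyz[2] <= dims[2] &
      coord[, 3] + dxyz[3] >= 1 & coord[, 3] + dxyz[3] <= dims[3]
    lin2 <- inside[ok] + dxyz[1] + dxyz[2] * nx + dxyz[3] * nxy
    nb <- node_of[lin2]
    good <- nb > 0L
    a <- node_of[inside[ok]][good]
    b <- nb[good]
    len <- vox$pitch * sqrt(sum(dxyz^2))
    ef <- c(ef, a)
    et <- c(et, b)
    ew <- c(ew, len / ((rr[a] + rr[b]) / 2 + eps))
  }
  g <- igraph::make_graph(as.vector(rbind(ef, et)), n = length(inside),
                          directed = FALSE)
  sp <- igraph::shortest_paths(g, from = node_of[from_voxel],
                               to = node_of[to_voxel], weights = ew,
                               output = "vpath")
  path_nodes <- as.integer(sp$vpath[[1]])
  if (length(path_nodes) < 2L) stop("no interior path between the endpoints")
  centers <- (coord[path_nodes, , drop = FALSE] - 0.5) * vox$pitch
  sweep(centers, 2, vox$origin, "+")
}

nearest_inside_voxel <- function(vox, p, max_dist) {
  ijk <- round((p - vox$origin) / vox$pitch + 0.5)
  inside <- which(vox$mask)
  coord <- arrayInd(inside, vox$dims)
  centers <- sweep((coord - 0.5) * vox$pitch, 2, vox$origin, "+")
  d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 +
    (centers[, 3] - p[3])^2
  i <- which.min(d2)
  if (sqrt(d2[i]) > max_dist) {
    stop(sprintf(
      "point (%.2f, %.2f, %.2f) is outside the lumen (nearest interior voxel %.2f mm away)",
      p[1], p[2], p[3], sqrt(d2[i])
    ))
  }
  inside[i]
}

#' Extract a vessel centerline between two endpoints
#'
#' Implements the maximal-inscribed-sphere principle on a watertight tubular
#' mesh: the lumen interior is voxelized, a Euclidean distance field to the
#' wall provides the local inscribed radius, and the centerline is traced as
#' the minimum-cost interior path between the openings with step cost
#' inversely weighted by the inscribed radius.  The voxel path is smoothed,
#' resampled uniformly, and refined by snapping each sample to the area
#' centroid of its perpendicular cross-section.  Inscribed radii along the
#' final curve are exact point-to-surface distances.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param source,target 3-points inside (or at) the two tube openings, mm.
#' @param voxel_pitch voxel size in mm; defaults to a quarter of the
#'   estimated lumen radius (`2 V / S` of the closed surface), capped for
#'   memory.
#' @param ds_out output sample spacing along the curve, mm (default 0.5).
#' @return a [centerline()] with inscribed radii.
#' @export
extract_centerline <- function(mesh, source, target, voxel_pitch = NULL,
                               ds_out = 0.5) {
  if (!is_watertight(mesh)) {
    stop("mesh is not watertight; centerline extraction requires a closed surface")
  }
  if (is.null(voxel_pitch)) {
    surf <- sum(triangle_geometry(mesh)$areas)
    r_est <- 2 * abs(mesh_volume(mesh)) / surf
    voxel_pitch <- max(r_est / 4, 1e-3)
  }
  vox <- voxelize_interior(mesh, voxel_pitch)
  dist_mm <- edt3d(vox$mask) * vox$pitch
  vfrom <- nearest_inside_voxel(vox, source, max_dist = 4 * vox$pitch)
  vto <- nearest_inside_voxel(vox, target, max_dist = 4 * vox$pitch)
  pts <- voxel_path(vox, dist_mm, vfrom, vto)
  pts <- rbind(source, pts, target)
  pts <- pts[c(TRUE, rowSums(diff(pts)^2) > 1e-12), , drop = FALSE]

  # smooth the voxel-accurate path coordinate-wise against arclength
  s_raw <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  smooth_coord <- function(x) {
    if (length(s_raw) < 10L) return(stats::approxfun(s_raw, x))
    sp <- stats::smooth.spline(s_raw, x)
    function(si) stats::predict(sp, si)$y
  }
  fx <- smooth_coord(pts[, 1])
  fy <- smooth_coord(pts[, 2])
  fz <- smooth_coord(pts[, 3])
  L <- max(s_raw)
  si <- seq(0, L, length.out = max(ceiling(L / ds_out) + 1L, 10L))
  sm <- cbind(fx(si), fy(si), fz(si))

  # refine samples to perpendicular cross-section centroids; stations too
  # close to the openings (where smoothed tangents are unreliable) are
  # dropped rather than kept, and the exact endpoints anchor the curve
  r_guess <- stats::median(dist_mm[vox$mask]) + vox$pitch
  refine_pass <- function(cl0, margin, max_shift) {
    Lp <- max(cl0$s)
    keep_rows <- list(source)
    for (i in seq_len(nrow(cl0$points))) {
      if (cl0$s[i] < margin || Lp - cl0$s[i] < margin) next
      info <- cross_section_info(mesh, cl0$points[i, ], cl0$tangents[i, ])
      if (!is.null(info) &&
          sqrt(sum((info$centroid - cl0$points[i, ])^2)) < max_shift) {
        keep_rows[[length(keep_rows) + 1L]] <- info$centroid
      }
    }
    keep_rows[[length(keep_rows) + 1L]] <- target
    refined <- do.call(rbind, keep_rows)
    centerline(refined[c(TRUE, rowSums(diff(refined)^2) > 1e-12), ,
                       drop = FALSE])
  }
  # pass 1 stays clear of the caps (oblique slices there can graze them);
  # pass 2 re-slices with the now-accurate tangents closer to the ends
  cl1 <- refine_pass(centerline(sm), margin = r_guess,
                     max_shift = r_guess / 2)
  su1 <- seq(0, max(cl1$s), by = ds_out)
  at1 <- centerline_at(cl1, su1)
  cl1 <- refine_pass(centerline(at1$points, tangents = at1$tangents),
                     margin = max(vox$pitch, ds_out),
                     max_shift = r_guess / 2)
  # resample to uniform arclength spacing
  su <- seq(0, max(cl1$s), by = ds_out)
  if (max(cl1$s) - su[length(su)] > ds_out / 2) su <- c(su, max(cl1$s))
  at <- centerline_at(cl1, su)
  rad <- point_mesh_distance(at$points, mesh)
  centerline(at$points, tangents = at$tangents, radius = rad)
}

#' Origin specification on a centerline
#'
#' Defines the shared measurement origin between paired reconstructions:
#' `explicit_point` takes the arclength of the closest centerline point to a
#' given 3-point; `box_entry` takes the (unique) crossing of a plane, e.g.
#' the wall of the phantom box; `branch_intersection` takes the closest
#' approach to a second centerline (e.g. the artery centerline at an
#' anastomosis).
#'
#' @param rule `"explicit_point"`, `"box_entry"` or `"branch_intersection"`.
#' @param point 3-point for `explicit_point`.
#' @param plane_point,plane_normal plane for `box_entry`.
#' @param other a second [centerline()] for `branch_intersection`.
#' @return an `origin_spec` list.
#' @export
origin_spec <- function(rule = c("explicit_point", "box_entry",
                                 "branch_intersection"),
                        point = NULL, plane_point = NULL, plane_normal = NULL,
                        other = NULL) {
  rule <- match.arg(rule)
  if (rule == "explicit_point" && is.null(point)) {
    stop("explicit_point requires `point`")
  }
  if (rule == "box_entry" && (is.null(plane_point) || is.null(plane_normal))) {
    stop("box_entry requires `plane_point` and `plane_normal`")
  }
  if (rule == "branch_intersection" && !inherits(other, "centerline")) {
    stop("branch_intersection requires `other`, a centerline")
  }
  structure(list(rule = rule, point = point, plane_point = plane_point,
                 plane_normal = plane_normal, other = other),
            class = "origin_spec")
}

#' Resolve the measurement origin to an arclength
#'
#' @param cl a [centerline()].
#' @param origin an [origin_spec()].
#' @return the origin arclength `s0` in mm (on the centerline's own `s`
#'   coordinate).
#' @export
locate_origin <- function(cl, origin) {
  stopifnot(inherits(cl, "centerline"), inherits(origin, "origin_spec"))
  if (origin$rule == "explicit_point") {
    p <- origin$point
    return(project_point_s(cl, p))
  }
  if (origin$rule == "box_entry") {
    n <- origin$plane_normal / sqrt(sum(origin$plane_normal^2))
    f <- as.vector((cl$points - matrix(origin$plane_point,
                                       nrow(cl$points), 3,
                                       byrow = TRUE)) %*% n)
    sgn <- sign(f)
    cross_at <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    on_plane <- which(f == 0)
    n_cross <- length(cross_at) + length(on_plane)
    if (n_cross == 0L) stop("centerline does not cross the box-entry plane")
    if (n_cross > 1L) {
      stop("ambiguous box entry: centerline crosses the plane ", n_cross,
           " times; use an explicit_point origin")
    }
    if (length(on_plane) == 1L) return(cl$s[on_plane])
    i <- cross_at
    tt <- f[i] / (f[i] - f[i + 1])
    return(cl$s[i] + tt * (cl$s[i + 1] - cl$s[i]))
  }
  # branch_intersection: closest approach between sampled points
  A <- cl$points
  B <- origin$other$points
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  i <- which(d2 == min(d2), arr.ind = TRUE)[1, 1]
  cl$s[i]
}

# Arclength of the closest point on the centerline polyline to p (projects
# onto segments, not just vertices).
project_point_s <- function(cl, p) {
  P <- cl$points
  n <- nrow(P)
  a <- P[-n, , drop = FALSE]
  e <- P[-1, , drop = FALSE] - a
  w <- matrix(p, n - 1L, 3, byrow = TRUE) - a
  ee <- rowSums(e^2)
  tt <- pmin(pmax(rowSums(w * e) / ee, 0), 1)
  dif <- w - e * tt
  d2 <- rowSums(dif^2)
  i <- which.min(d2)
  cl$s[i] + tt[i] * (cl$s[i + 1] - cl$s[i])
}

#' Cross-sectional area profile along a centerline
#'
#' Samples the perpendicular cross-sectional area at fixed arclength
#' intervals from the measurement origin.  Samples within one local inscribed
#' radius of either end of the centerline are dropped, since slices there cut
#' the end caps rather than the vessel wall.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param cl a [centerline()] extracted from it.
#' @param origin an [origin_spec()], or a numeric arclength `s0` (mm).
#' @param delta_s sample spacing in mm (default 1).
#' @return an `area_profile` data.frame with columns `s_mm` (origin-shifted,
#'   so the origin is at 0), `area_mm2` and `eq_diameter_mm`.
#' @export
compute_area_profile <- function(mesh, cl, origin, delta_s = 1) {
  if (delta_s <= 0) stop("delta_s must be > 0")
  s0 <- if (is.numeric(origin)) origin else locate_origin(cl, origin)
  smin <- min(cl$s)
  smax <- max(cl$s)
  kk <- seq(ceiling((smin - s0) / delta_s), floor((smax - s0) / delta_s))
  s_abs <- s0 + kk * delta_s
  # cap margins: the inscribed radius collapses to zero at the caps (they
  # are part of the surface), so measure the local vessel radius just
  # inside each cap instead of at the sample itself
  if (!is.null(cl$radius)) {
    r_med <- stats::median(cl$radius)
    m_lo <- max(cl$radius[cl$s <= smin + 2 * r_med], r_med / 2)
    m_hi <- max(cl$radius[cl$s >= smax - 2 * r_med], r_med / 2)
  } else {
    m_lo <- m_hi <- 0
  }
  keep <- (s_abs - smin) >= m_lo & (smax - s_abs) >= m_hi
  s_abs <- s_abs[keep]
  kk <- kk[keep]
  if (length(s_abs) == 0L) stop("no valid samples between the end caps")
  at <- centerline_at(cl, s_abs)
  areas <- vapply(seq_along(s_abs), function(i) {
    tryCatch(
      cross_section_area(mesh, at$points[i, ], at$tangents[i, ]),
      error = function(e) {
        stop(sprintf("cross-section failed at s = %.2f mm: %s",
                     s_abs[i] - s0, conditionMessage(e)))
      }
    )
  }, numeric(1))
  out <- data.frame(s_mm = kk * delta_s, area_mm2 = areas,
                    eq_diameter_mm = equivalent_diameter(areas))
  class(out) <- c("area_profile", "data.frame")
  out
}
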