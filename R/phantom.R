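#' Phantom vessel specification
#'
#' Describes an idealized tubular vessel phantom: a straight tube (aligned by
#' default with the scanner z / B0 axis) or a curved tube following a circular
#' arc.  The curved kinds `curve_high` and `curve_low` model the two
#' swing-site phantoms: same diameter, different curvature, with the
#' high-curvature arc radius defaulting to 15 mm and the low-curvature one to
#' 40 mm so their peak flow-direction derivatives differ well over twofold.
#'
#' @param internal_diameter lumen diameter in mm (> 0).
#' @param length generating path length in mm (> 0).
#' @param path_kind one of `"straight"`, `"arc"`, `"curve_high"`,
#'   `"curve_low"`.
#' @param arc_radius arc radius in mm for curved kinds; defaults to 15 mm for
#'   `curve_high`, 40 mm for `curve_low`, and must exceed the internal
#'   diameter.
#' @param axial_direction unit 3-vector giving the straight-tube axis
#'   (default `c(0, 0, 1)`, the B0 direction).
#' @param n_circumferential vertices per cross-section ring (>= 8).
#' @param n_axial axial rings along the path (>= 10).
#'
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(internal_diameter, length,
                         path_kind = c("straight", "arc", "curve_high",
                                       "curve_low"),
                         arc_radius = NULL,
                         axial_direction = c(0, 0, 1),
                         n_circumferential = 48L, n_axial = 60L) {
  path_kind <- match.arg(path_kind)
  if (!is.numeric(internal_diameter) || internal_diameter <= 0) {
    stop("internal_diameter must be > 0")
  }
  if (!is.numeric(length) || length <= 0) stop("length must be > 0")
  if (n_circumferential < 8L) {
    stop("degenerate resolution: n_circumferential must be >= 8")
  }
  if (n_axial < 10L) stop("degenerate resolution: n_axial must be >= 10")
  if (is.null(arc_radius)) {
    arc_radius <- switch(path_kind, curve_high = 15, curve_low = 40, NA_real_)
  }
  if (path_kind != "straight") {
    if (!is.finite(arc_radius) || arc_radius <= internal_diameter) {
      stop("arc_radius must exceed internal_diameter for curved kinds")
    }
  }
  nrm <- sqrt(sum(axial_direction^2))
  if (nrm < .Machine$double.eps) stop("axial_direction must be non-zero")
  structure(
    list(
      internal_diameter = internal_diameter, length = length,
      path_kind = path_kind, arc_radius = arc_radius,
      axial_direction = axial_direction / nrm,
      n_circumferential = as.integer(n_circumferential),
      n_axial = as.integer(n_axial)
    ),
    class = "phantom_spec"
  )
}

# Generating path of a phantom: points, unit tangents and a twist-free
# cross-section frame (e1, e2 with e1 x e2 = tangent) at n+1 stations.
# Straight tubes run along axial_direction; arcs live in the x-z plane,
# starting at the origin with tangent +z and bending towards +x, so the
# tangent angle to B0 grows linearly in arclength.
phantom_path <- function(spec, n = spec$n_axial) {
  s <- seq(0, spec$length, length.out = n + 1L)
  if (spec$path_kind == "straight") {
    ax <- spec$axial_direction
    pts <- outer(s, ax)
    tans <- matrix(ax, length(s), 3, byrow = TRUE)
    ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- ref - sum(ref * ax) * ax
    e2 <- e2 / sqrt(sum(e2^2))
    e1 <- c(e2[2] * ax[3] - e2[3] * ax[2],
            e2[3] * ax[1] - e2[1] * ax[3],
            e2[1] * ax[2] - e2[2] * ax[1])
    e1m <- matrix(e1, length(s), 3, byrow = TRUE)
    e2m <- matrix(e2, length(s), 3, byrow = TRUE)
  } else {
    R <- spec$arc_radius
    th <- s / R
    pts <- cbind(R * (1 - cos(th)), 0, R * sin(th))
    tans <- cbind(sin(th), 0, cos(th))
    # e2 is the (constant) out-of-plane direction; e1 = e2 x t is the
    # in-plane outward radial direction, so e1 x e2 = t holds.
    e2m <- matrix(c(0, 1, 0), length(s), 3, byrow = TRUE)
    e1m <- cbind(tans[, 3], 0, -tans[, 1])
  }
  list(s = s, points = pts, tangents = tans, e1 = e1m, e2 = e2m)
}

# Build a capped tube mesh around a path.  radius_fn(s, theta) returns the
# local lumen radius in mm; theta is the angle in the (e1, e2) frame.
tube_mesh_from_path <- function(path, radius_fn, n_circ, source) {
  ns <- length(path$s)
  theta <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  verts <- matrix(0, ns * n_circ + 2L, 3)
  for (i in seq_len(ns)) {
    r <- radius_fn(path$s[i], theta)
    if (any(r <= 0)) {
      stop("perturbation drives the radius non-positive at s = ",
           format(path$s[i]), " mm")
    }
    off <- outer(r * cos(theta), path$e1[i, ]) +
      outer(r * sin(theta), path$e2[i, ])
    verts[(i - 1L) * n_circ + seq_len(n_circ), ] <-
      sweep(off, 2, path$points[i, ], "+")
  }
  c0 <- ns * n_circ + 1L
  c1 <- ns * n_circ + 2L
  verts[c0, ] <- path$points[1, ]
  verts[c1, ] <- path$points[ns, ]

  j <- seq_len(n_circ)
  jn <- c(seq_len(n_circ)[-1], 1L)
  side <- vector("list", ns - 1L)
  for (i in seq_len(ns - 1L)) {
    a <- (i - 1L) * n_circ + j
    b <- (i - 1L) * n_circ + jn
    cc <- i * n_circ + jn
    d <- i * n_circ + j
    side[[i]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  cap0 <- cbind(c0, (1L - 1L) * n_circ + jn, (1L - 1L) * n_circ + j)
  cap1 <- cbind(c1, (ns - 1L) * n_circ + j, (ns - 1L) * n_circ + jn)
  tris <- do.call(rbind, c(side, list(cap0, cap1)))
  surface_mesh(verts, tris, source = source)
}

#' Generate an idealized phantom tube mesh
#'
#' Builds a watertight triangulated tube whose cross-sections perpendicular to
#' the generating path are regular polygons inscribed in a circle of the
#' requested internal diameter; end caps are closed with triangle fans.
#'
#' @param spec a [phantom_spec()].
#' @return a [surface_mesh()] in mm.
#' @export
generate_tube_mesh <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  path <- phantom_path(spec)
  r0 <- spec$internal_diameter / 2
  tube_mesh_from_path(
    path, function(s, theta) rep(r0, length(theta)),
    spec$n_circumferential,
    source = sprintf("phantom %s D=%g mm L=%g mm", spec$path_kind,
                     spec$internal_diameter, spec$length)
  )
}

#' Segmentation-style perturbation specification
#'
#' Describes how a reconstructed lumen surface deviates from the true vessel:
#' a systematic radial bias (over/under-estimation), smooth correlated noise
#' along the vessel (a Gaussian process with squared-exponential kernel,
#' mimicking the smooth lofted-spline character of sweeping segmentation),
#' and optional local features such as an apparent narrowing or dilation.
#'
#' @param radial_bias_fraction signed fractional radius change (|bias| < 0.5).
#' @param noise_amplitude standard deviation of the radial noise, mm.
#' @param noise_correlation_length kernel length scale along the vessel, mm.
#' @param local_features list of `c(position, extent, fraction)` triples:
#'   a Gaussian radius modulation centred at `position` (mm along the path)
#'   with standard deviation `extent / 2` and peak fractional change
#'   `fraction` (negative = narrowing).
#' @param seed integer; fully determines the noise realisation.
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(radial_bias_fraction = 0, noise_amplitude = 0,
                              noise_correlation_length = 5,
                              local_features = list(), seed = 1L) {
  if (abs(radial_bias_fraction) >= 0.5) {
    stop("|radial_bias_fraction| must be < 0.5")
  }
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  if (noise_correlation_length <= 0) {
    stop("noise_correlation_length must be > 0")
  }
  structure(
    list(
      radial_bias_fraction = radial_bias_fraction,
      noise_amplitude = noise_amplitude,
      noise_correlation_length = noise_correlation_length,
      local_features = local_features, seed = as.integer(seed)
    ),
    class = "perturbation_spec"
  )
}

# Smooth unit-variance Gaussian-process sample on grid s (SE kernel).
se_gp_sample <- function(s, ell, seed) {
  K <- exp(-outer(s, s, "-")^2 / (2 * ell^2))
  L <- chol(K + diag(1e-10, length(s)))
  withr::with_seed(seed, as.vector(t(L) %*% rnorm(length(s))))
}

# Fractional radius modulation from local features at arclengths s.
feature_field <- function(s, local_features) {
  out <- numeric(length(s))
  for (f in local_features) {
    out <- out + f[3] * exp(-(s - f[1])^2 / (2 * (f[2] / 2)^2))
  }
  out
}

#' Generate a pair of perturbed segmentations of the same vessel
#'
#' Emulates two independent reconstructions (e.g. from two MRI sequences) of
#' one underlying phantom: each mesh's radius field is
#' `r0 * (1 + bias + features(s)) + noise(s)`, with the noise a smooth seeded
#' Gaussian process along the vessel.  Identical specs and seeds reproduce
#' bit-identical meshes.
#'
#' @param spec a [phantom_spec()] for the underlying vessel.
#' @param perturbA,perturbB [perturbation_spec()]s for the two
#'   reconstructions.
#' @return list with elements `A` and `B`, both [surface_mesh()]s.
#' @export
generate_paired_meshes <- function(spec, perturbA, perturbB) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(perturbA, "perturbation_spec"),
            inherits(perturbB, "perturbation_spec"))
  path <- phantom_path(spec)
  r0 <- spec$internal_diameter / 2
  one <- function(p, label) {
    g <- if (p$noise_amplitude > 0) {
      p$noise_amplitude *
        se_gp_sample(path$s, p$noise_correlation_length, p$seed)
    } else {
      numeric(length(path$s))
    }
    feat <- feature_field(path$s, p$local_features)
    rs <- r0 * (1 + p$radial_bias_fraction + feat) + g
    radius_fn <- function(s, theta) {
      rep(rs[which.min(abs(path$s - s))], length(theta))
    }
    tube_mesh_from_path(path, radius_fn, spec$n_circumferential,
                        source = sprintf("perturbed phantom %s", label))
  }
  list(A = one(perturbA, "A"), B = one(perturbB, "B"))
}

#' The five study phantoms
#'
#' Convenience constructor for the phantom set used throughout the analyses:
#' straight tubes of internal diameter 2, 3 and 5 mm and the two curved
#' swing-site phantoms (high and low curvature, 5 mm diameter).
#'
#' @param length tube path length in mm (default 50).
#' @param n_circumferential,n_axial mesh resolution passed to
#'   [phantom_spec()].
#' @return named list of [phantom_spec()]s.
#' @export
phantom_set <- function(length = 50, n_circumferential = 48L, n_axial = 60L) {
  mk <- function(d, kind) {
    phantom_spec(d, length, kind, n_circumferential = n_circumferential,
                 n_axial = n_axial)
  }
  list(
    straight_5mm = mk(5, "straight"),
    straight_3mm = mk(3, "straight"),
    straight_2mm = mk(2, "straight"),
    curve_high = mk(5, "curve_high"),
    curve_low = mk(5, "curve_low")
  )
}
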