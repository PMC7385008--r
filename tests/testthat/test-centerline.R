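test_that("straight-tube centerline recovers the axis, radius and length", {
  for (d in c(2, 5)) {
    cl <- straight_centerline(d)
    dev <- sqrt(cl$points[, 1]^2 + cl$points[, 2]^2)
    expect_lt(max(dev), 0.1)
    expect_equal(max(cl$s) - min(cl$s), 50, tolerance = 0.01)
    interior <- cl$s > d / 2 + 1 & cl$s < max(cl$s) - d / 2 - 1
    expect_equal(cl$radius[interior], rep(d / 2, sum(interior)),
                 tolerance = 0.02)
  }
})

test_that("curved-tube centerline stays within 0.15 mm of the generating arc", {
  spec <- phantom_spec(5, 50, "arc", arc_radius = 20)
  m <- cached("arc_tube", generate_tube_mesh(spec))
  path <- vesselwss:::phantom_path(spec)
  cl <- cached("arc_cl", suppressMessages(extract_centerline(
    m, path$points[1, ], path$points[nrow(path$points), ]
  )))
  # distance from each sample to the analytic arc (radius 20, centre
  # (20, 0, 0), in the x-z plane)
  dev <- pmax(abs(sqrt((cl$points[, 1] - 20)^2 + cl$points[, 3]^2) - 20),
              abs(cl$points[, 2]))
  expect_lt(max(dev), 0.15)
})

test_that("centerline invariants hold: monotone s, unit tangents, arclength consistency", {
  cl <- straight_centerline(5)
  expect_true(all(diff(cl$s) > 0))
  expect_equal(sqrt(rowSums(cl$tangents^2)), rep(1, nrow(cl$tangents)),
               tolerance = 1e-9)
  seg_sum <- sum(sqrt(rowSums(diff(cl$points)^2)))
  expect_equal(seg_sum, max(cl$s) - min(cl$s), tolerance = 1e-6)
})

test_that("extraction is invariant under rigid motion of the mesh", {
  m <- straight_tube(5)
  RR <- rotation_matrix(0.7, 1.3)
  shift <- c(3, -2, 7)
  mr <- transform_mesh(m, RR, shift)
  clr <- suppressMessages(extract_centerline(
    mr, as.vector(RR %*% c(0, 0, 0)) + shift,
    as.vector(RR %*% c(0, 0, 50)) + shift
  ))
  back <- sweep(clr$points, 2, shift) %*% RR
  dev <- sqrt(back[, 1]^2 + back[, 2]^2)
  expect_lt(max(dev), 0.1)
})

test_that("non-watertight meshes and points outside the lumen are rejected", {
  m <- straight_tube(5)
  holed <- surface_mesh(m$vertices, m$triangles[-1, , drop = FALSE])
  expect_error(extract_centerline(holed, c(0, 0, 0), c(0, 0, 50)),
               "watertight")
  expect_error(
    suppressMessages(extract_centerline(m, c(20, 20, 0), c(0, 0, 50))),
    "outside the lumen"
  )
})

test_that("origin rules resolve to the constructed arclengths", {
  # an analytic centerline is enough: origin logic never touches the mesh
  s <- seq(0, 50, by = 0.5)
  cl <- centerline(cbind(0, 0, s))
  # explicit point on the curve at s = 10
  expect_equal(
    locate_origin(cl, origin_spec("explicit_point", point = c(0, 0, 10))),
    10, tolerance = 1e-9
  )
  # explicit point off the curve projects orthogonally
  expect_equal(
    locate_origin(cl, origin_spec("explicit_point", point = c(1, 1, 32.25))),
    32.25, tolerance = 1e-9
  )
  # box entry: plane z = 5 crossed once
  expect_equal(
    locate_origin(cl, origin_spec("box_entry", plane_point = c(0, 0, 5),
                                  plane_normal = c(0, 0, 1))),
    5, tolerance = 1e-9
  )
  # no crossing
  expect_error(
    locate_origin(cl, origin_spec("box_entry", plane_point = c(0, 0, 60),
                                  plane_normal = c(0, 0, 1))),
    "does not cross"
  )
})

test_that("a centerline crossing the box plane twice is rejected as ambiguous", {
  s <- seq(0, 2 * pi, length.out = 100)
  cl <- centerline(cbind(s, 0, sin(s))) # crosses z = 0.5 twice... and more
  expect_error(
    locate_origin(cl, origin_spec("box_entry", plane_point = c(0, 0, 0.5),
                                  plane_normal = c(0, 0, 1))),
    "ambiguous"
  )
})

test_that("branch intersection takes the closest approach to the other centerline", {
  # vein along z; artery crossing it at (0, 0, 20) at an angle
  vein <- centerline(cbind(0, 0, seq(0, 50, by = 0.5)))
  u <- seq(-20, 20, by = 0.5)
  artery <- centerline(cbind(u / sqrt(2), 0.2, 20 + u / sqrt(2)))
  s0 <- locate_origin(vein, origin_spec("branch_intersection",
                                        other = artery))
  # brute-force oracle over all sample pairs
  d2 <- as.matrix(stats::dist(rbind(vein$points, artery$points)))
  nv <- nrow(vein$points)
  block <- d2[seq_len(nv), -seq_len(nv)]
  i_best <- which(block == min(block), arr.ind = TRUE)[1, 1]
  expect_equal(s0, vein$s[i_best])
  expect_equal(s0, 20, tolerance = 0.5)
})

test_that("area profile drops cap-contaminated samples and hits the constructed minimum", {
  m <- straight_tube(5)
  cl <- straight_centerline(5)
  org <- origin_spec("explicit_point", point = c(0, 0, 0))
  prof <- compute_area_profile(m, cl, org, delta_s = 1)
  # no sample within one radius of either cap
  expect_gte(min(prof$s_mm), 2.5)
  expect_lte(max(prof$s_mm), 47.5)
  expect_equal(prof$area_mm2, rep(prof$area_mm2[1], nrow(prof)),
               tolerance = 1e-9)
  expect_equal(prof$area_mm2[1], pi * 2.5^2, tolerance = 0.01)
  # local narrowing: -20% radius at s = 10 over a 6 mm extent
  spec <- phantom_spec(5, 50, "straight")
  pairN <- generate_paired_meshes(
    spec, perturbation_spec(seed = 1),
    perturbation_spec(local_features = list(c(10, 6, -0.2)), seed = 2)
  )
  clN <- suppressMessages(extract_centerline(pairN$B, c(0, 0, 0),
                                             c(0, 0, 50)))
  profN <- compute_area_profile(pairN$B, clN, org, delta_s = 1)
  i_min <- which.min(profN$area_mm2)
  expect_lte(abs(profN$s_mm[i_min] - 10), 1)
  expect_equal(profN$area_mm2[i_min], pi * (2.5 * 0.8)^2, tolerance = 0.03)
})

test_that("doubling circumferential resolution cuts the area error at least in half", {
  err <- vapply(c(16L, 32L), function(nc) {
    m <- generate_tube_mesh(phantom_spec(5, 20, "straight",
                                         n_circumferential = nc,
                                         n_axial = 10L))
    abs(cross_section_area(m, c(0, 0, 10), c(0, 0, 1)) - pi * 2.5^2)
  }, numeric(1))
  expect_gte(err[1] / err[2], 2)
})
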