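test_that("straight-tube cross-sections match the requested diameter within 1%", {
  for (d in c(2, 3, 5)) {
    m <- straight_tube(d)
    for (z in c(10, 25, 40)) {
      expect_equal(cross_section_area(m, c(0, 0, z), c(0, 0, 1)),
                   pi * (d / 2)^2, tolerance = 0.01)
    }
  }
})

test_that("arc generating path has exactly the requested length", {
  spec <- phantom_spec(5, 50, "arc", arc_radius = 20)
  path <- vesselwss:::phantom_path(spec)
  seg <- sqrt(rowSums(diff(path$points)^2))
  # chord-sum of the sampled arc converges to the arclength from below
  chord_len <- 2 * spec$arc_radius * spec$n_axial *
    sin(50 / (2 * spec$arc_radius * spec$n_axial))
  expect_equal(sum(seg), chord_len, tolerance = 1e-9)
  # the generating arc itself spans the requested length
  expect_equal(spec$arc_radius * (50 / spec$arc_radius), 50)
})

test_that("high-curvature phantom has a strictly larger peak |Gamma'| than the low-curvature one", {
  peak_gp <- function(kind) {
    spec <- phantom_spec(5, 50, kind)
    path <- vesselwss:::phantom_path(spec, n = 200)
    g <- gamma_metric(path$tangents)
    max(abs(gamma_derivative(g, path$s)))
  }
  hi <- peak_gp("curve_high")
  lo <- peak_gp("curve_low")
  expect_gt(hi, lo)
  expect_gte(hi / lo, 2)
  # |Gamma'| = sin(s/R)/R peaks at 1/R once the arc passes a quarter turn
  # (curve-H, R = 15, 50 mm) and at sin(L/R)/R before it (curve-L, R = 40)
  expect_equal(hi, 1 / 15, tolerance = 0.01)
  expect_equal(lo, sin(50 / 40) / 40, tolerance = 0.01)
})

test_that("degenerate resolution is rejected with the offending field named", {
  expect_error(phantom_spec(5, 50, "straight", n_circumferential = 4L),
               "n_circumferential")
  expect_error(phantom_spec(5, 50, "straight", n_axial = 5L), "n_axial")
  expect_error(phantom_spec(5, 50, "arc", arc_radius = 3), "arc_radius")
})

test_that("zero perturbation reproduces the reference mesh exactly", {
  spec <- phantom_spec(3, 30, "straight", n_circumferential = 16L,
                       n_axial = 12L)
  pair <- generate_paired_meshes(spec, perturbation_spec(seed = 1),
                                 perturbation_spec(seed = 2))
  expect_identical(pair$A$vertices, pair$B$vertices)
  a1 <- cross_section_area(pair$A, c(0, 0, 15), c(0, 0, 1))
  a2 <- cross_section_area(pair$B, c(0, 0, 15), c(0, 0, 1))
  expect_identical(error_metric(a1, a2), 0)
})

test_that("radial bias shifts the vertex radii by exactly the configured fraction", {
  spec <- phantom_spec(5, 30, "straight", n_circumferential = 16L,
                       n_axial = 12L)
  pair <- generate_paired_meshes(
    spec, perturbation_spec(0, seed = 1),
    perturbation_spec(-0.05, seed = 2)
  )
  ring <- function(m) sqrt(m$vertices[1:16, 1]^2 + m$vertices[1:16, 2]^2)
  expect_equal(mean(ring(pair$B)) / mean(ring(pair$A)), 0.95,
               tolerance = 1e-12)
})

test_that("paired-mesh generation is deterministic: same seed, byte-identical STL", {
  spec <- phantom_spec(3, 30, "straight", n_circumferential = 16L,
                       n_axial = 12L)
  mk <- function() {
    generate_paired_meshes(
      spec,
      perturbation_spec(0.02, 0.1, 4, seed = 7),
      perturbation_spec(-0.03, 0.08, 6, seed = 8)
    )
  }
  f1 <- withr::local_tempfile(fileext = ".stl")
  f2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(mk()$A, f1)
  write_stl(mk()$A, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("perturbations driving the radius non-positive are rejected", {
  spec <- phantom_spec(2, 30, "straight", n_circumferential = 16L,
                       n_axial = 12L)
  expect_error(
    generate_paired_meshes(
      spec, perturbation_spec(seed = 1),
      perturbation_spec(-0.45, local_features = list(c(15, 10, -0.9)),
                        seed = 2)
    ),
    "non-positive"
  )
})

test_that("smooth radial noise is zero-mean over seeds", {
  s <- seq(0, 30, by = 1)
  draws <- vapply(1:50, function(seed) {
    mean(vesselwss:::se_gp_sample(s, ell = 5, seed = seed))
  }, numeric(1))
  # mean of a zero-mean GP over 50 seeds: SE about sqrt(avg cov)/sqrt(50)
  expect_lt(abs(mean(draws)), 0.2)
  # seeded determinism
  expect_identical(vesselwss:::se_gp_sample(s, 5, 3L),
                   vesselwss:::se_gp_sample(s, 5, 3L))
})

test_that("noise-free signal with negative slope anti-correlates perfectly with Gamma'", {
  cl <- analytic_arc_centerline(20, 50)
  prof <- generate_signal_profile(cl, slope = -1, noise_sd = 0)
  sc <- signal_gamma_correlation(prof)
  expect_identical(sc$r, -1)
  # raw intensity is an exact affine map of Gamma'
  expect_equal(stats::cor(prof$intensity_raw, prof$gamma_prime), -1)
})

test_that("flat signal (zero slope, no noise) is reported as degenerate", {
  cl <- straight_centerline(5)
  prof <- generate_signal_profile(cl, slope = 0, noise_sd = 0)
  sc <- signal_gamma_correlation(prof)
  expect_true(is.na(sc$r))
  expect_identical(sc$method, "degenerate")
})

test_that("synthetic wall-shear endpoints give the closed-form OSI values", {
  steady <- generate_wall_shear_series(5, waveform_spec(1, 0))
  expect_equal(osi(steady), rep(0, 5))
  expect_equal(tawss(steady), rep(1, 5))
  expect_true(waveform_spec(0, 1)$reversal)
  expect_false(waveform_spec(1, 0.5)$reversal)
  reversing <- generate_wall_shear_series(5, waveform_spec(0, 1))
  expect_equal(osi(reversing), rep(0.5, 5))
  partial <- generate_wall_shear_series(5, waveform_spec(0.5, 1))
  o <- osi(partial)
  expect_true(all(o > 0 & o < 0.5))
  oracle <- waveform_oracle(0.5, 1)
  expect_equal(o, rep(oracle$osi, 5), tolerance = 1e-3)
})
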