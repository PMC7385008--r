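make_series <- function(m, a, nt = 64L, dir = c(1, 0, 0), T_pulse = 1) {
  t0 <- 2 * T_pulse
  times <- t0 + T_pulse * (seq_len(nt) - 1L) / nt
  amp <- m + a * sin(2 * pi * (times - t0) / T_pulse)
  shear <- array(0, dim = c(1, nt, 3))
  for (k in 1:3) shear[1, , k] <- amp * dir[k]
  wall_shear_series(shear, times, T_pulse, t0 = t0)
}

test_that("TAWSS averages the shear magnitude over the pulse", {
  expect_identical(tawss(make_series(1, 0)), 1)
  # rectified sinusoid: mean |sin| = 2/pi
  expect_equal(tawss(make_series(0, 1)), 2 / pi, tolerance = 0.005)
  # homogeneity
  s1 <- make_series(0.5, 1)
  s3 <- make_series(1.5, 3)
  expect_equal(tawss(s3), 3 * tawss(s1), tolerance = 1e-12)
})

test_that("TAWSS/OSI converge to the quadrature oracle at second order", {
  oracle <- waveform_oracle(0, 1)
  err <- vapply(c(16L, 32L, 64L), function(nt) {
    abs(tawss(make_series(0, 1, nt = nt)) - oracle$tawss)
  }, numeric(1))
  expect_gte(err[1] / err[2], 3.5)
  expect_gte(err[2] / err[3], 3.5)
  o_err <- vapply(c(16L, 32L), function(nt) {
    abs(osi(make_series(0.5, 1, nt = nt)) - waveform_oracle(0.5, 1)$osi)
  }, numeric(1))
  expect_gte(o_err[1] / o_err[2], 3.5)
})

test_that("OSI endpoints and bounds follow the orientation of the shear vector", {
  # single orientation throughout the pulse
  expect_equal(osi(make_series(1.5, 0.5)), 0)
  # symmetric reversal: zero time-integral
  expect_equal(osi(make_series(0, 1)), 0.5)
  # partial reversal sits strictly inside (0, 0.5) and matches quadrature
  o <- osi(make_series(0.5, 1))
  expect_true(o > 0 && o < 0.5)
  expect_equal(o, waveform_oracle(0.5, 1)$osi, tolerance = 1e-3)
  # invariance under positive rescaling
  expect_equal(osi(make_series(1, 2)), osi(make_series(2, 4)),
               tolerance = 1e-12)
  # all-zero series has no defined OSI
  expect_true(is.na(osi(make_series(0, 0))))
})

test_that("non-uniform or mis-spanned time grids are rejected", {
  shear <- array(1, dim = c(1, 8, 3))
  expect_error(wall_shear_series(shear, c(0, 1, 2, 3, 4, 5, 6, 8) / 8, 1,
                                 t0 = 0), "uniform")
  expect_error(wall_shear_series(shear, seq(0, 7) / 4, 1, t0 = 0), "span")
})

test_that("Reynolds number follows (4/pi) rho Q / (mu D) and the velocity identity", {
  expect_identical(reynolds(flow_conditions(D = 0.005, Q = 0)), 0)
  fl <- flow_conditions(rho = 1e3, mu = 1e-3, D = 0.005, v = 1)
  expect_equal(reynolds(fl), 5000, tolerance = 1e-9)
  expect_equal(reynolds(fl), fl$rho * fl$v * fl$D / fl$mu, tolerance = 1e-12)
  fl2 <- flow_conditions(rho = 1e3, mu = 1e-3, D = 0.005, Q = 2 * fl$Q)
  expect_equal(reynolds(fl2), 2 * reynolds(fl), tolerance = 1e-12)
})

test_that("inconsistent Q and v are rejected", {
  expect_error(flow_conditions(D = 0.005, Q = 1e-5, v = 1), "inconsistent")
})

test_that("Darcy-Weisbach with laminar friction reproduces Poiseuille exactly", {
  expect_identical(
    darcy_weisbach_wss(0.04, flow_conditions(D = 0.005, Q = 0), 1e-5), 0
  )
  # f_D = 0.04, rho = 1060, Q/A = 1 m/s -> 5.3 Pa
  fl <- blood_conditions(D = 0.01, v = 1)
  A <- pi * 0.01^2 / 4
  expect_equal(darcy_weisbach_wss(0.04, fl, A), 5.3, tolerance = 1e-12)
  # algebraic identity across a parameter sweep
  for (mu in c(1e-3, 3.5e-3)) {
    for (D in c(0.002, 0.005, 0.01)) {
      for (v in c(0.01, 0.05, 0.2)) {
        fl <- flow_conditions(rho = 1e3, mu = mu, D = D, v = v)
        fd <- laminar_friction_factor(reynolds(fl))
        expect_equal(darcy_weisbach_wss(fd, fl, pi * D^2 / 4),
                     poiseuille_wss(mu, fl$Q, D), tolerance = 1e-12)
      }
    }
  }
})

test_that("laminar friction factor and regime thresholds behave as stated", {
  expect_identical(laminar_friction_factor(64), 1)
  Re <- c(10, 500, 1500, 3000)
  expect_equal(laminar_friction_factor(Re) * Re, rep(64, 4))
  expect_error(laminar_friction_factor(0), "Re")
  expect_identical(flow_regime(2000), "laminar")
  expect_identical(flow_regime(2200), "transitional")
  expect_identical(flow_regime(8000), "turbulent")
})

test_that("log-log WSS-area slopes are exactly 1.5 (laminar) and 2 (constant friction)", {
  fl <- flow_conditions(rho = 1e3, mu = 1e-3, D = 0.005, Q = 1e-6)
  expect_equal(wss_area_scaling_exponent("laminar", fl, c(2, 3, 4, 5)),
               1.5, tolerance = 1e-6)
  expect_equal(wss_area_scaling_exponent("constant_fD", fl, c(2, 3, 4, 5)),
               2, tolerance = 1e-6)
  expect_error(wss_area_scaling_exponent("laminar", fl, 5), "3 diameters")
})

test_that("sequence voxel sizes come out as FOV over matrix", {
  pars <- mri_sequence_params()
  vox <- mri_voxel_size(pars$fov_mm, pars$matrix_px)
  expect_equal(vox[pars$sequence == "tof"], 140 / 512)
  expect_equal(vox[pars$sequence == "medic"], 136 / 512)
})
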