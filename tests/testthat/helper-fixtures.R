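# Shared fixtures, built once per test run.  Centerline extraction is the
# expensive step, so meshes/centerlines used across tests are cached here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

straight_tube <- function(d_mm, length_mm = 50, ...) {
  cached(sprintf("tube_%g_%g", d_mm, length_mm), {
    generate_tube_mesh(phantom_spec(d_mm, length_mm, "straight", ...))
  })
}

straight_centerline <- function(d_mm, length_mm = 50) {
  cached(sprintf("cl_%g_%g", d_mm, length_mm), {
    suppressMessages(extract_centerline(
      straight_tube(d_mm, length_mm), c(0, 0, 0), c(0, 0, length_mm)
    ))
  })
}

# An analytic arc centerline (no mesh involved): radius R in the x-z plane,
# starting at the origin with tangent +z; ds sample spacing.
analytic_arc_centerline <- function(R, length_mm, ds = 1) {
  s <- seq(0, length_mm, by = ds)
  th <- s / R
  centerline(
    cbind(R * (1 - cos(th)), 0, R * sin(th)),
    tangents = cbind(sin(th), 0, cos(th))
  )
}

rotation_matrix <- function(ax, ay) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rx %*% Ry
}

# Independent quadrature oracle for TAWSS/OSI of a fixed-direction waveform
# tau(t) = m + a sin(2 pi t / T): adaptive quadrature of both integrals.
waveform_oracle <- function(m, a, T_pulse = 1) {
  f_mag <- function(t) abs(m + a * sin(2 * pi * t / T_pulse))
  f_sig <- function(t) m + a * sin(2 * pi * t / T_pulse)
  int_mag <- stats::integrate(f_mag, 0, T_pulse, subdivisions = 2000L,
                              rel.tol = 1e-10)$value
  int_sig <- stats::integrate(f_sig, 0, T_pulse, subdivisions = 2000L,
                              rel.tol = 1e-10)$value
  list(tawss = int_mag / T_pulse, osi = 0.5 * (1 - abs(int_sig) / int_mag))
}
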