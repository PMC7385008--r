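#' Time-resolved wall-shear series over one pulse period
#'
#' Wall-shear vectors sampled at wall points over a uniform time grid spanning
#' exactly one pulse period.  The grid includes the window start `t0` and
#' excludes `t0 + T`, so periodic trapezoidal integration is well defined.
#' By convention the analysis window starts at `t0 = 2 T` (the third pulse of
#' a simulation, past flow-development transients); the series supplied is
#' assumed to already be that analysis pulse.
#'
#' @param shear array of dimension `(n_points, n_times, 3)`, Pa.
#' @param times time grid in seconds; must be uniform, start at `t0`, and
#'   span `[t0, t0 + T)`.
#' @param pulse_period pulse period T, s.
#' @param t0 window start, s (default `2 * pulse_period`).
#' @param point_ids optional identifiers, one per wall point.
#' @param normals optional `(n_points, 3)` outward surface unit normals.
#' @return a `wall_shear_series` object.
#' @export
wall_shear_series <- function(shear, times, pulse_period,
                              t0 = 2 * pulse_period, point_ids = NULL,
                              normals = NULL) {
  if (pulse_period <= 0) stop("pulse_period must be > 0")
  d <- dim(shear)
  if (length(d) != 3L || d[3] != 3L) {
    stop("shear must be an (n_points, n_times, 3) array")
  }
  nt <- length(times)
  if (nt != d[2]) stop("times length must match dim(shear)[2]")
  if (nt < 2L) stop("need at least 2 timesteps")
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * pulse_period) {
    stop("time grid must be uniform")
  }
  if (abs(times[1] - t0) > 1e-9 * pulse_period ||
      abs((times[nt] + dt[1]) - (t0 + pulse_period)) >
        1e-9 * pulse_period) {
    stop("times must span [t0, t0 + T) on a uniform grid")
  }
  if (is.null(point_ids)) point_ids <- seq_len(d[1])
  structure(
    list(shear = shear, times = times, pulse_period = pulse_period,
         t0 = t0, point_ids = point_ids, normals = normals),
    class = "wall_shear_series"
  )
}

#' @export
print.wall_shear_series <- function(x, ...) {
  cat(sprintf(
    "wall_shear_series: %d wall points, %d timesteps over T = %g s (t0 = %g s)\n",
    dim(x$shear)[1], dim(x$shear)[2], x$pulse_period, x$t0
  ))
  invisible(x)
}

# Periodic trapezoidal integral over [t0, t0 + T) on a uniform grid: with the
# endpoint excluded and the signal periodic, the rule reduces to dt * sum.
periodic_integral <- function(values_matrix, dt) {
  dt * rowSums(values_matrix)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' `TAWSS = (1/T) * integral over one pulse of ||tau_w|| dt`, evaluated by
#' the periodic trapezoidal rule.
#'
#' @param series a [wall_shear_series()].
#' @return numeric vector of TAWSS values (Pa), one per wall point.
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wall_shear_series"))
  np <- dim(series$shear)[1]
  dt <- series$pulse_period / dim(series$shear)[2]
  mag <- matrix(sqrt(series$shear[, , 1]^2 + series$shear[, , 2]^2 +
                       series$shear[, , 3]^2), nrow = np)
  unname(periodic_integral(mag, dt) / series$pulse_period)
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 1/2 * (1 - ||integral tau_w dt|| / integral ||tau_w|| dt)`.
#' It is 0 when the shear vector keeps a single orientation through the pulse
#' and 0.5 when it oscillates symmetrically between opposite orientations
#' (zero time-integral).  Points where the shear is identically zero have no
#' defined OSI and are reported as `NA`.
#'
#' @param series a [wall_shear_series()].
#' @return numeric vector of OSI values in `[0, 0.5]` (or `NA`), one per
#'   wall point.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wall_shear_series"))
  np <- dim(series$shear)[1]
  dt <- series$pulse_period / dim(series$shear)[2]
  mag <- matrix(sqrt(series$shear[, , 1]^2 + series$shear[, , 2]^2 +
                       series$shear[, , 3]^2), nrow = np)
  den <- periodic_integral(mag, dt)
  ix <- periodic_integral(matrix(series$shear[, , 1], nrow = np), dt)
  iy <- periodic_integral(matrix(series$shear[, , 2], nrow = np), dt)
  iz <- periodic_integral(matrix(series$shear[, , 3], nrow = np), dt)
  num <- sqrt(ix^2 + iy^2 + iz^2)
  out <- 0.5 * (1 - num / den)
  out[den == 0] <- NA_real_
  # clamp tiny negative round-off
  unname(pmin(pmax(out, 0), 0.5))
}

#' Wall-shear field summary (TAWSS and OSI per wall point)
#'
#' @param series a [wall_shear_series()].
#' @return data.frame with columns `point_id`, `tawss_Pa`, `osi`.
#' @export
wall_field_summary <- function(series) {
  data.frame(point_id = series$point_ids, tawss_Pa = tawss(series),
             osi = osi(series))
}

#' Pulsatile waveform specification for synthetic wall shear
#'
#' A fixed-direction sinusoid
#' `tau(p, t) = (m + a sin(2 pi (t - t0) / T)) d_p` with per-point unit
#' directions `d_p`: the simplest waveform that spans the whole OSI range.
#' Flow reversal occurs when the oscillation amplitude `a` exceeds the mean
#' level `m`.  `direction_mode = "rotating"` instead rotates the shear vector
#' in a tangent plane over the pulse, giving direction (not sign) oscillation.
#'
#' @param mean_shear_magnitude mean shear level m, Pa (>= 0).
#' @param oscillation_amplitude oscillation amplitude a, Pa.
#' @param n_timesteps samples per pulse (>= 8).
#' @param direction_mode `"fixed"` or `"rotating"`.
#' @param seed integer seed for the per-point directions.
#' @return a `waveform_spec` list; its `reversal` field is `TRUE` when
#'   `a > m`.
#' @export
waveform_spec <- function(mean_shear_magnitude, oscillation_amplitude,
                          n_timesteps = 64L,
                          direction_mode = c("fixed", "rotating"),
                          seed = 1L) {
  direction_mode <- match.arg(direction_mode)
  if (mean_shear_magnitude < 0) stop("mean_shear_magnitude must be >= 0")
  if (n_timesteps < 8L) stop("n_timesteps must be >= 8")
  structure(
    list(mean_shear_magnitude = mean_shear_magnitude,
         oscillation_amplitude = oscillation_amplitude,
         n_timesteps = as.integer(n_timesteps),
         reversal = oscillation_amplitude > mean_shear_magnitude,
         direction_mode = direction_mode, seed = as.integer(seed)),
    class = "waveform_spec"
  )
}

#' Generate a synthetic pulsatile wall-shear series
#'
#' Stands in for a flow solver's wall output over the analysis pulse
#' (`t0 = 2 T`).  Per-point shear directions are random unit vectors fully
#' determined by the waveform seed.
#'
#' @param wall_points number of wall sample points.
#' @param waveform a [waveform_spec()].
#' @param T_pulse pulse period, s.
#' @return a [wall_shear_series()].
#' @export
generate_wall_shear_series <- function(wall_points, waveform, T_pulse = 1) {
  stopifnot(inherits(waveform, "waveform_spec"))
  n <- as.integer(wall_points)
  nt <- waveform$n_timesteps
  t0 <- 2 * T_pulse
  times <- t0 + T_pulse * (seq_len(nt) - 1L) / nt
  phase <- 2 * pi * (times - t0) / T_pulse
  amp <- waveform$mean_shear_magnitude +
    waveform$oscillation_amplitude * sin(phase)
  dirs <- withr::with_seed(waveform$seed, {
    m <- matrix(stats::rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
  })
  shear <- array(0, dim = c(n, nt, 3))
  if (waveform$direction_mode == "fixed") {
    for (k in 1:3) shear[, , k] <- outer(dirs[, k], amp)
  } else {
    # rotate in the plane spanned by d_p and a perpendicular partner
    perp <- withr::with_seed(waveform$seed + 1L, {
      m <- matrix(stats::rnorm(3 * n), n, 3)
      m <- m - dirs * rowSums(m * dirs)
      m / sqrt(rowSums(m^2))
    })
    ca <- cos(phase)
    sa <- sin(phase)
    for (k in 1:3) {
      shear[, , k] <- outer(dirs[, k], abs(amp) * ca) +
        outer(perp[, k], abs(amp) * sa)
    }
  }
  wall_shear_series(shear, times, T_pulse, t0 = t0)
}
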