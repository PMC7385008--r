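#' Pipe-flow conditions
#'
#' Bundles the fluid and flow parameters of a cylindrical vessel in SI units.
#' Either the flow rate `Q` or the mean velocity `v` may be given; the other
#' is derived from `v = 4 Q / (pi D^2)` and, if both are supplied, they must
#' be consistent to a relative 1e-9.
#'
#' Defaults are the working fluids of the study: water
#' (`rho = 1e3`, `mu = 1e-3`) for phantom flow and blood
#' (`rho = 1.06e3`, `mu = 3.5e-3`) via [blood_conditions()].
#'
#' @param rho density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param D internal diameter, m.
#' @param Q flow rate, m^3/s.
#' @param v mean velocity, m/s.
#' @param pulse_period pulse period T, s.
#' @return a `flow_conditions` list.
#' @export
flow_conditions <- function(rho = 1e3, mu = 1e-3, D, Q = NULL, v = NULL,
                            pulse_period = 1) {
  if (rho <= 0 || mu <= 0 || pulse_period <= 0) {
    stop("rho, mu and pulse_period must be > 0")
  }
  if (D <= 0) stop("D must be > 0")
  area <- pi * D^2 / 4
  if (is.null(Q) && is.null(v)) stop("supply Q or v")
  if (is.null(Q)) Q <- v * area
  if (is.null(v)) v <- Q / area
  if (Q < 0) stop("Q must be >= 0")
  if (abs(v * area - Q) > 1e-9 * max(Q, .Machine$double.eps)) {
    stop("Q and v are inconsistent: v must equal 4Q/(pi D^2)")
  }
  structure(list(rho = rho, mu = mu, D = D, Q = Q, v = v,
                 pulse_period = pulse_period),
            class = "flow_conditions")
}

#' @rdname flow_conditions
#' @param ... passed on to [flow_conditions()].
#' @export
blood_conditions <- function(D, ..., rho = 1.06e3, mu = 3.5e-3) {
  flow_conditions(rho = rho, mu = mu, D = D, ...)
}

#' Reynolds number of pipe flow
#'
#' `Re = (4 / pi) * rho * Q / (mu * D)`, algebraically identical to
#' `rho v D / mu` with `v = 4 Q / (pi D^2)`.
#'
#' @param flow a [flow_conditions()].
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(flow) {
  stopifnot(inherits(flow, "flow_conditions"))
  (4 / pi) * flow$rho * flow$Q / (flow$mu * flow$D)
}

#' Laminar Darcy friction factor
#'
#' `f_D = 64 / Re`, valid in the laminar regime.
#'
#' @param Re Reynolds number, > 0.
#' @return friction factor.
#' @export
laminar_friction_factor <- function(Re) {
  if (any(Re <= 0)) stop("Re must be > 0")
  64 / Re
}

#' Flow regime classification
#'
#' Pipe flow is laminar below Re = 2100 (the conventional lower bound for
#' departure from laminar behaviour), transitional from 2100 up to 4000, and
#' turbulent above.
#'
#' @param Re Reynolds number.
#' @return character vector: `"laminar"`, `"transitional"` or `"turbulent"`.
#' @export
flow_regime <- function(Re) {
  ifelse(Re < 2100, "laminar", ifelse(Re < 4000, "transitional", "turbulent"))
}

#' Darcy-Weisbach wall shear stress
#'
#' `tau_w = (f_D / 8) * rho * (Q / A)^2` — wall shear from the friction
#' factor, density, flow rate and cross-sectional area, all SI.
#'
#' @param f_D Darcy friction factor.
#' @param flow a [flow_conditions()] (supplies rho and Q).
#' @param A cross-sectional area, m^2.
#' @return wall shear stress, Pa.
#' @export
darcy_weisbach_wss <- function(f_D, flow, A) {
  stopifnot(inherits(flow, "flow_conditions"))
  if (any(A <= 0)) stop("A must be > 0")
  (f_D / 8) * flow$rho * (flow$Q / A)^2
}

#' Poiseuille wall shear stress (laminar closed form)
#'
#' `tau_w = 32 mu Q / (pi D^3)`, the exact laminar pipe-flow wall shear; the
#' independent check that Darcy-Weisbach with `f_D = 64 / Re` must reproduce.
#'
#' @param mu dynamic viscosity, Pa s.
#' @param Q flow rate, m^3/s.
#' @param D diameter, m.
#' @return wall shear stress, Pa.
#' @export
poiseuille_wss <- function(mu, Q, D) {
  32 * mu * Q / (pi * D^3)
}

#' Log-log scaling exponent of wall shear versus area
#'
#' At fixed flow rate, wall shear follows a power law in cross-sectional
#' area: `tau_w ~ A^-1.5` in the laminar regime (where `f_D = 64/Re` itself
#' depends on diameter) and `tau_w ~ A^-2` when the friction factor is
#' constant (rough-pipe turbulent limit).  The exponent magnitude is
#' recovered as the negated least-squares slope of `log(tau_w)` on `log(A)`.
#'
#' @param regime `"laminar"` or `"constant_fD"`.
#' @param flow a [flow_conditions()]; its `D` is ignored, `Q`, `rho`, `mu`
#'   are used.
#' @param diameters_mm vessel diameters in mm (at least 3).
#' @param f_D friction factor for the `constant_fD` regime (default 0.04).
#' @return exponent magnitude (positive number).
#' @export
wss_area_scaling_exponent <- function(regime = c("laminar", "constant_fD"),
                                      flow, diameters_mm, f_D = 0.04) {
  regime <- match.arg(regime)
  stopifnot(inherits(flow, "flow_conditions"))
  if (length(diameters_mm) < 3L) {
    stop("need at least 3 diameters to fit a slope")
  }
  D <- diameters_mm / 1000
  A <- pi * D^2 / 4
  tau <- vapply(D, function(d) {
    fl <- flow_conditions(rho = flow$rho, mu = flow$mu, D = d, Q = flow$Q,
                          pulse_period = flow$pulse_period)
    fd <- if (regime == "laminar") laminar_friction_factor(reynolds(fl)) else f_D
    darcy_weisbach_wss(fd, fl, pi * d^2 / 4)
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(A)), log(tau))
  -unname(fit$coefficients[2])
}
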