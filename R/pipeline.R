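# End-to-end drivers for the two studies: the phantom study (synthetic
# paired segmentations of known tubes) and the paired-geometry comparison
# (two reconstructions of the same vessel, optionally with wall-shear
# series).  All randomness flows from config seeds; outputs are written as
# deterministic CSV so identical configs reproduce byte-identical reports.

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

mesh_audit <- function(mesh) {
  sprintf("%d verts, %d tris, coord-sum %.6f", nrow(mesh$vertices),
          nrow(mesh$triangles), sum(mesh$vertices))
}

#' Default configuration for the phantom study
#'
#' Named defaults mirror the study conditions: tube diameters 2/3/5 mm plus
#' the two curved swing-site phantoms, 1 mm profile spacing, water as the
#' working fluid at 1.0 m/s, and a 50 mm analysis window centred on the
#' curve for curved phantoms.
#'
#' @param out_dir output directory for report CSVs.
#' @param seed master seed; all per-phantom seeds derive from it.
#' @return a config list understood by [run_phantom_study()].
#' @export
phantom_study_config <- function(out_dir = tempfile("phantom_study"),
                                 seed = 1L) {
  list(
    out_dir = out_dir,
    phantoms = c("straight_5mm", "straight_3mm", "straight_2mm",
                 "curve_high", "curve_low"),
    length = 50, n_circumferential = 48L, n_axial = 60L,
    delta_s = 1,
    perturb_A = list(bias = 0, noise_amplitude = 0.05,
                     noise_correlation_length = 5),
    perturb_B = list(bias = -0.05, noise_amplitude = 0.05,
                     noise_correlation_length = 5),
    velocity = 1.0, rho = 1e3, mu = 1e-3,
    signal_slope = -1, signal_target_r = 0.85,
    curve_window = 50,
    write_meshes = FALSE,
    voxel_pitch = NULL, ds_out = 0.5,
    seed = as.integer(seed)
  )
}

perturb_from_config <- function(p, seed) {
  perturbation_spec(
    radial_bias_fraction = p$bias %||% 0,
    noise_amplitude = p$noise_amplitude %||% 0,
    noise_correlation_length = p$noise_correlation_length %||% 5,
    local_features = p$local_features %||% list(),
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the phantom study end to end
#'
#' For each requested phantom: generate the paired perturbed meshes, extract
#' both centerlines, profile cross-sectional area at `delta_s` intervals
#' from the shared origin, and compare the pair (error metric, mean diameter
#' difference, Bland-Altman).  A wall-shear error column is derived by
#' pushing both area profiles through the Darcy-Weisbach chain at the
#' phantom's nominal flow (laminar friction when the nominal Reynolds number
#' is laminar, constant friction factor otherwise).  Signal profiles with
#' the configured curvature dependence are generated along each centerline
#' and correlated with the flow-direction derivative.
#'
#' Writes `table1.csv`, `bland_altman_<phantom>.csv`,
#' `signal_correlations.csv` and a `manifest.txt` config echo to
#' `config$out_dir`.
#'
#' @param config a list as produced by [phantom_study_config()], or a path
#'   to a YAML file with the same fields.
#' @return invisibly, a list with the report table, per-phantom Bland-Altman
#'   objects and signal correlations.
#' @export
run_phantom_study <- function(config = phantom_study_config()) {
  config <- load_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- phantom_set(length = config$length,
                       n_circumferential = config$n_circumferential,
                       n_axial = config$n_axial)
  specs <- specs[config$phantoms]
  rows <- list()
  ba_all <- list()
  sig_rows <- list()
  for (k in seq_along(specs)) {
    name <- names(specs)[k]
    spec <- specs[[k]]
    stage_fail <- function(stage, e) {
      stop(sprintf("stage '%s' failed for phantom '%s': %s", stage, name,
                   conditionMessage(e)), call. = FALSE)
    }
    log_stage("generate", "phantom %s (D = %g mm, %s)", name,
              spec$internal_diameter, spec$path_kind)
    pair <- tryCatch(
      generate_paired_meshes(
        spec,
        perturb_from_config(config$perturb_A, config$seed + 100L * k + 1L),
        perturb_from_config(config$perturb_B, config$seed + 100L * k + 2L)
      ),
      error = function(e) stage_fail("generate", e)
    )
    log_stage("generate", "A: %s | B: %s", mesh_audit(pair$A),
              mesh_audit(pair$B))
    if (isTRUE(config$write_meshes)) {
      write_stl(pair$A, file.path(config$out_dir, paste0(name, "_A.stl")))
      write_stl(pair$B, file.path(config$out_dir, paste0(name, "_B.stl")))
    }
    path <- phantom_path(spec)
    p0 <- path$points[1, ]
    p1 <- path$points[nrow(path$points), ]
    cls <- tryCatch(
      list(A = extract_centerline(pair$A, p0, p1,
                                  voxel_pitch = config$voxel_pitch,
                                  ds_out = config$ds_out),
           B = extract_centerline(pair$B, p0, p1,
                                  voxel_pitch = config$voxel_pitch,
                                  ds_out = config$ds_out)),
      error = function(e) stage_fail("centerline", e)
    )
    curved <- spec$path_kind != "straight"
    mid <- path$points[ceiling(nrow(path$points) / 2), ]
    org <- if (curved) {
      origin_spec("explicit_point", point = mid)
    } else {
      origin_spec("explicit_point", point = p0)
    }
    profs <- tryCatch(
      list(A = compute_area_profile(pair$A, cls$A, org, config$delta_s),
           B = compute_area_profile(pair$B, cls$B, org, config$delta_s)),
      error = function(e) stage_fail("area_profile", e)
    )
    if (curved) {
      w <- config$curve_window / 2
      profs <- lapply(profs, function(p) p[abs(p$s_mm) <= w, ])
    }
    paired_area <- tryCatch(
      resample_to_common_grid(
        list(s = profs$A$s_mm, value = profs$A$area_mm2),
        list(s = profs$B$s_mm, value = profs$B$area_mm2),
        delta_s = config$delta_s, quantity = "area"
      ),
      error = function(e) stage_fail("compare", e)
    )
    E_A <- error_metric(paired_area$f_A, paired_area$f_B)
    dA <- equivalent_diameter(paired_area$f_A)
    dB <- equivalent_diameter(paired_area$f_B)
    ba <- bland_altman(dA, dB)
    ba_all[[name]] <- ba
    # wall-shear chain at nominal flow: Q fixed by the nominal diameter and
    # configured velocity; per-sample WSS from each measured area
    fl <- flow_conditions(rho = config$rho, mu = config$mu,
                          D = spec$internal_diameter / 1000,
                          v = config$velocity)
    Re <- reynolds(fl)
    wss_of <- function(a_mm2) {
      A_m2 <- a_mm2 * 1e-6
      if (Re < 2100) {
        d_eq <- sqrt(4 * A_m2 / pi)
        fd <- laminar_friction_factor(
          (4 / pi) * fl$rho * fl$Q / (fl$mu * d_eq))
      } else {
        fd <- 0.04
      }
      darcy_weisbach_wss(fd, fl, A_m2)
    }
    E_WSS <- error_metric(wss_of(paired_area$f_A), wss_of(paired_area$f_B))
    mean_diff <- mean(dA - dB)
    sd_diff <- stats::sd(dA - dB)
    rows[[name]] <- data.frame(
      phantom = name, D_mm = spec$internal_diameter, E_A = E_A,
      E_WSS = E_WSS, mean_diff_mm = mean_diff, sd_diff_mm = sd_diff,
      n_slices = length(paired_area$s_grid), Re = Re,
      stringsAsFactors = FALSE
    )
    write_table_exact(
      data.frame(mean_mm = ba$pair_means, diff_mm = ba$pair_differences),
      file.path(config$out_dir, paste0("bland_altman_", name, ".csv"))
    )
    # signal profile along centerline A; a straight vessel has (numerically
    # near-)constant Gamma', leaving no defined signal-curvature correlation
    gp_range <- diff(range(gamma_derivative(gamma_metric(cls$A$tangents),
                                            cls$A$s)))
    if (gp_range < 1e-6) {
      noise_sd <- 0
      sc <- list(r = NA_real_, p = NA_real_, n = nrow(cls$A$points))
    } else {
      noise_sd <- calibrate_signal_noise(cls$A, config$signal_slope,
                                         config$signal_target_r)
      sig <- generate_signal_profile(cls$A, slope = config$signal_slope,
                                     noise_sd = noise_sd,
                                     seed = config$seed + 100L * k + 3L)
      sc <- signal_gamma_correlation(sig)
    }
    sig_rows[[name]] <- data.frame(
      phantom = name, spearman_r = sc$r, p_value = sc$p, n = sc$n,
      noise_sd = noise_sd, stringsAsFactors = FALSE
    )
    log_stage("compare", "%s: E_A = %.4f, E_WSS = %.4f, mean diff %.3f mm",
              name, E_A, E_WSS, mean_diff)
  }
  table1 <- do.call(rbind, rows)
  sigtab <- do.call(rbind, sig_rows)
  write_table_exact(table1, file.path(config$out_dir, "table1.csv"))
  write_table_exact(sigtab,
                    file.path(config$out_dir, "signal_correlations.csv"))
  writeLines(config_echo(config), file.path(config$out_dir, "manifest.txt"))
  invisible(list(table1 = table1, bland_altman = ba_all,
                 signal = sigtab, config = config))
}

config_echo <- function(config, prefix = "") {
  unlist(lapply(names(config), function(nm) {
    v <- config[[nm]]
    if (is.list(v)) {
      c(paste0(prefix, nm, ":"), config_echo(v, paste0(prefix, "  ")))
    } else {
      paste0(prefix, nm, ": ", paste(format(v, digits = 15), collapse = " "))
    }
  }))
}

#' Load a run configuration
#'
#' Accepts a config list (returned unchanged) or a path to a YAML file.
#'
#' @param config list or file path.
#' @return config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

# Mean TAWSS/OSI per arclength bin: wall points registered by arclength s_mm
# are averaged within delta_s bins, giving profile curves comparable to the
# area profile.
shear_profiles <- function(series, s_mm, delta_s) {
  summ <- wall_field_summary(series)
  bins <- round(s_mm / delta_s) * delta_s
  tw <- tapply(summ$tawss_Pa, bins, mean)
  os <- tapply(summ$osi, bins, mean)
  s <- as.numeric(names(tw))
  ord <- order(s)
  list(tawss = list(s = s[ord], value = as.numeric(tw)[ord]),
       osi = list(s = s[ord], value = as.numeric(os)[ord]))
}

#' Run a paired-geometry comparison
#'
#' The patient-style workflow on two reconstructions of the same vessel:
#' extract both centerlines, align the measurement origin, profile area and
#' equivalent diameter at `delta_s` intervals, and (when wall-shear series
#' are supplied) summarize TAWSS and OSI into profiles and compare
#' everything between the sources (error metrics, Bland-Altman).
#'
#' @param config a list (or YAML path) with fields:
#'   \describe{
#'     \item{mesh_A, mesh_B}{[surface_mesh()] objects or STL file paths.}
#'     \item{source, target}{3-points at the vessel openings (mm).}
#'     \item{origin}{an [origin_spec()]; defaults to the source point.}
#'     \item{delta_s}{profile spacing, mm (default 1).}
#'     \item{shear_A, shear_B}{optional: lists with `series` (a
#'       [wall_shear_series()] or CSV path) and `s_mm` (arclength of each
#'       wall point on the corresponding centerline).}
#'     \item{out_dir}{output directory.}
#'     \item{vessel}{label for the report row.}
#'   }
#' @return invisibly, a list with the error report, profiles and
#'   Bland-Altman result.
#' @export
run_paired_comparison <- function(config) {
  config <- load_run_config(config)
  config$delta_s <- config$delta_s %||% 1
  config$vessel <- config$vessel %||% "vessel"
  config$out_dir <- config$out_dir %||% tempfile("paired_comparison")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  get_mesh <- function(m, label) {
    if (inherits(m, "surface_mesh")) return(m)
    mesh <- tryCatch(read_stl(m), error = function(e) {
      stop(sprintf("cannot read STL for %s: %s", label, conditionMessage(e)),
           call. = FALSE)
    })
    mesh
  }
  mA <- get_mesh(config$mesh_A, "mesh_A")
  mB <- get_mesh(config$mesh_B, "mesh_B")
  for (m in list(A = mA, B = mB)) {
    if (!is_watertight(m)) stop("input mesh is not watertight: ", m$source)
  }
  log_stage("input", "A: %s | B: %s", mesh_audit(mA), mesh_audit(mB))
  clA <- extract_centerline(mA, config$source, config$target,
                            voxel_pitch = config$voxel_pitch,
                            ds_out = config$ds_out %||% 0.5)
  clB <- extract_centerline(mB, config$source, config$target,
                            voxel_pitch = config$voxel_pitch,
                            ds_out = config$ds_out %||% 0.5)
  org <- config$origin %||% origin_spec("explicit_point",
                                        point = config$source)
  profA <- compute_area_profile(mA, clA, org, config$delta_s)
  profB <- compute_area_profile(mB, clB, org, config$delta_s)
  write_area_profile(profA, file.path(config$out_dir, "area_profile_A.csv"))
  write_area_profile(profB, file.path(config$out_dir, "area_profile_B.csv"))
  pairs <- list(area = resample_to_common_grid(
    list(s = profA$s_mm, value = profA$area_mm2),
    list(s = profB$s_mm, value = profB$area_mm2),
    delta_s = config$delta_s, quantity = "area"
  ))
  one_shear <- function(sh, cl) {
    if (is.null(sh)) return(NULL)
    series <- sh$series
    if (is.character(series)) series <- read_wall_shear_series(series)
    if (length(sh$s_mm) != dim(series$shear)[1]) {
      stop("wall-shear points are not registered: s_mm length must match ",
           "the number of wall points")
    }
    shear_profiles(series, sh$s_mm, config$delta_s)
  }
  spA <- one_shear(config$shear_A, clA)
  spB <- one_shear(config$shear_B, clB)
  if (!is.null(spA) && !is.null(spB)) {
    pairs$tawss <- resample_to_common_grid(spA$tawss, spB$tawss,
                                           delta_s = config$delta_s,
                                           quantity = "TAWSS")
    pairs$osi <- resample_to_common_grid(spA$osi, spB$osi,
                                         delta_s = config$delta_s,
                                         quantity = "OSI")
  }
  report <- build_error_report(pairs, vessel = config$vessel)
  ba <- bland_altman(equivalent_diameter(pairs$area$f_A),
                     equivalent_diameter(pairs$area$f_B))
  write_table_exact(report, file.path(config$out_dir, "error_report.csv"))
  write_table_exact(
    data.frame(mean_mm = ba$pair_means, diff_mm = ba$pair_differences),
    file.path(config$out_dir, "bland_altman.csv")
  )
  log_stage("compare", "%s: E_A = %.4f%s", config$vessel, report$E_A,
            if (!is.na(report$E_TAWSS)) {
              sprintf(", E_TAWSS = %.4f, E_OSI = %.4f", report$E_TAWSS,
                      report$E_OSI)
            } else "")
  invisible(list(report = report, profiles = list(A = profA, B = profB),
                 pairs = pairs, bland_altman = ba,
                 centerlines = list(A = clA, B = clB)))
}
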