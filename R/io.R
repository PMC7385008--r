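# CSV readers/writers for the package's tabular interchange formats.
# Numeric columns are printed with %.17g so that written values survive a
# read-back bit-exactly (round-trip identity), and output is fully
# deterministic for fixed inputs.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_table_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an area profile CSV
#'
#' Columns: `s_mm`, `area_mm2`, `eq_diameter_mm`.
#'
#' @param profile an `area_profile` (see [compute_area_profile()]).
#' @param path file path.
#' @return `path` (write) or an `area_profile` data.frame (read).
#' @export
write_area_profile <- function(profile, path) {
  write_table_exact(profile[, c("s_mm", "area_mm2", "eq_diameter_mm")], path)
}

#' @rdname write_area_profile
#' @export
read_area_profile <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("s_mm", "area_mm2", "eq_diameter_mm") %in% names(out)))
  class(out) <- c("area_profile", "data.frame")
  out
}

#' Write / read a signal profile CSV
#'
#' Columns: `s_mm`, `gamma`, `gamma_prime`, `intensity_raw`,
#' `intensity_norm`.
#'
#' @param profile a `signal_profile` (see [generate_signal_profile()]).
#' @param path file path.
#' @return `path` (write) or a `signal_profile` data.frame (read).
#' @export
write_signal_profile <- function(profile, path) {
  cols <- c("s_mm", "gamma", "gamma_prime", "intensity_raw", "intensity_norm")
  write_table_exact(profile[, cols], path)
}

#' @rdname write_signal_profile
#' @export
read_signal_profile <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("s_mm", "gamma_prime", "intensity_raw") %in% names(out)))
  class(out) <- c("signal_profile", "data.frame")
  out
}

#' Write / read a wall-shear series as long-format CSV
#'
#' Columns: `point_id`, `t_s`, `tau_x_Pa`, `tau_y_Pa`, `tau_z_Pa`; the pulse
#' period and window start are recorded in `# key: value` comment lines at
#' the top of the file.
#'
#' @param series a [wall_shear_series()].
#' @param path file path.
#' @return `path` (write) or a [wall_shear_series()] (read).
#' @export
write_wall_shear_series <- function(series, path) {
  stopifnot(inherits(series, "wall_shear_series"))
  np <- dim(series$shear)[1]
  nt <- dim(series$shear)[2]
  df <- data.frame(
    point_id = rep(series$point_ids, times = nt),
    t_s = rep(series$times, each = np),
    tau_x_Pa = as.vector(series$shear[, , 1]),
    tau_y_Pa = as.vector(series$shear[, , 2]),
    tau_z_Pa = as.vector(series$shear[, , 3])
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pulse_period: %.17g", series$pulse_period),
               sprintf("# t0: %.17g", series$t0)), con)
  out <- df
  for (j in 2:5) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wall_shear_series
#' @export
read_wall_shear_series <- function(path) {
  head2 <- readLines(path, n = 2L)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), head2, value = TRUE)
    if (length(ln) != 1L) stop("missing '# ", key, ":' header in ", path)
    as.numeric(sub(paste0("^# ", key, ": *"), "", ln))
  }
  T_pulse <- getv("pulse_period")
  t0 <- getv("t0")
  df <- utils::read.csv(path, comment.char = "#")
  ids <- unique(df$point_id)
  times <- sort(unique(df$t_s))
  np <- length(ids)
  nt <- length(times)
  if (nrow(df) != np * nt) stop("wall-shear table is not a complete grid")
  df <- df[order(match(df$t_s, times), match(df$point_id, ids)), ]
  shear <- array(0, dim = c(np, nt, 3))
  shear[, , 1] <- df$tau_x_Pa
  shear[, , 2] <- df$tau_y_Pa
  shear[, , 3] <- df$tau_z_Pa
  wall_shear_series(shear, times, T_pulse, t0 = t0, point_ids = ids)
}
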