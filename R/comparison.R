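#' Resample two profiles onto a common uniform grid
#'
#' Paired measurements from two reconstructions of the same vessel rarely
#' share a grid or even a field of view; both profiles are linearly
#' interpolated onto a uniform grid restricted to the overlap of their
#' arclength ranges.
#'
#' @param profileA,profileB data.frames (or lists) with numeric `s` (mm) and
#'   `value` fields; `s` must be increasing.
#' @param delta_s grid spacing in mm (default 1).
#' @param quantity label for the paired quantity
#'   (`"area"`, `"eq_diameter"`, `"TAWSS"`, `"OSI"`, ...).
#' @return a `paired_profiles` object: `s_grid`, `f_A`, `f_B`, `quantity`.
#' @export
resample_to_common_grid <- function(profileA, profileB, delta_s = 1,
                                    quantity = "area") {
  if (delta_s <= 0) stop("delta_s must be > 0")
  ra <- range(profileA$s)
  rb <- range(profileB$s)
  lo <- max(ra[1], rb[1])
  hi <- min(ra[2], rb[2])
  if (hi - lo < 3 * delta_s) {
    stop(sprintf(
      "profiles do not overlap enough: A spans [%.2f, %.2f] mm, B spans [%.2f, %.2f] mm",
      ra[1], ra[2], rb[1], rb[2]
    ))
  }
  s_grid <- seq(ceiling(lo / delta_s) * delta_s, hi, by = delta_s)
  fa <- stats::approx(profileA$s, profileA$value, xout = s_grid)$y
  fb <- stats::approx(profileB$s, profileB$value, xout = s_grid)$y
  structure(list(s_grid = s_grid, f_A = fa, f_B = fb, quantity = quantity),
            class = "paired_profiles")
}

#' Normalized summed-difference error metric
#'
#' `E_f = (2/n) * sum_i |(f_A,i - f_B,i) / (f_A,i + f_B,i)|` for nonnegative
#' paired quantities: zero for identical measurements, bounded above by 2,
#' symmetric in its arguments, and invariant under common rescaling.
#'
#' @param f_A,f_B numeric vectors of equal length (nonnegative quantities).
#' @return the error metric value in `[0, 2]`.
#' @export
error_metric <- function(f_A, f_B) {
  n <- length(f_A)
  if (length(f_B) != n || n < 1L) stop("f_A and f_B must have equal length >= 1")
  ssum <- f_A + f_B
  bad <- which(ssum == 0 & (f_A != 0 | f_B != 0))
  zz <- which(ssum == 0 & f_A == 0 & f_B == 0)
  if (length(bad) > 0L) {
    stop("zero pairwise sum at indices: ", paste(bad, collapse = ", "))
  }
  term <- abs((f_A - f_B) / ssum)
  term[zz] <- 0 # identical (zero) measurements contribute no error
  (2 / n) * sum(term)
}

#' Bland-Altman agreement analysis
#'
#' For each pair, the mean `(a + b)/2` and difference `a - b` (first argument
#' minus second); summarized by the bias (mean difference), the sample
#' standard deviation of the differences, and the 95% limits of agreement
#' `bias +/- 1.96 sd`.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return a `bland_altman` object: `pair_means`, `pair_differences`, `bias`,
#'   `sd_difference`, `limits_of_agreement` (length 2), `n`.
#' @export
bland_altman <- function(a, b) {
  n <- length(a)
  if (length(b) != n || n < 2L) stop("need equal-length vectors, n >= 2")
  diffs <- a - b
  means <- (a + b) / 2
  bias <- mean(diffs)
  sdd <- stats::sd(diffs)
  structure(
    list(pair_means = means, pair_differences = diffs, bias = bias,
         sd_difference = sdd,
         limits_of_agreement = bias + c(-1.96, 1.96) * sdd, n = n),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.4g, SD %.4g, limits [%.4g, %.4g]\n",
    x$n, x$bias, x$sd_difference, x$limits_of_agreement[1],
    x$limits_of_agreement[2]
  ))
  invisible(x)
}

#' Mean paired difference in equivalent diameter
#'
#' Mean and sample SD of the per-position diameter difference
#' (first source minus second) over the common grid.
#'
#' @param paired a `paired_profiles` object of equivalent diameters (mm).
#' @return list with `mean` and `sd`, both mm.
#' @export
mean_diameter_difference <- function(paired) {
  stopifnot(inherits(paired, "paired_profiles"))
  d <- paired$f_A - paired$f_B
  list(mean = mean(d), sd = stats::sd(d))
}

#' Equivalent diameter of a cross-sectional area
#'
#' `d_eq = 2 sqrt(A / pi)`: the diameter of the circle with the same area.
#'
#' @param area cross-sectional area, mm^2.
#' @return equivalent diameter, mm.
#' @export
equivalent_diameter <- function(area) 2 * sqrt(area / pi)

#' Assemble a per-vessel error report
#'
#' Builds one report row per vessel from its paired profiles: the error
#' metric for each available quantity (area, TAWSS, OSI) plus the mean
#' diameter difference.  Missing quantities are reported as `NA`, never as
#' zero.
#'
#' @param pairs named list with elements among `area`, `tawss`, `osi`,
#'   `eq_diameter`, each a `paired_profiles` object (the `area` pair is
#'   required; `eq_diameter` is derived from `area` when absent).
#' @param vessel vessel label for the report row.
#' @return data.frame with columns `vessel`, `E_A`, `E_TAWSS`, `E_OSI`,
#'   `mean_diff_mm`, `sd_diff_mm`.
#' @export
build_error_report <- function(pairs, vessel = "vessel") {
  if (is.null(pairs$area)) stop("the area pair is required")
  ea <- error_metric(pairs$area$f_A, pairs$area$f_B)
  et <- if (!is.null(pairs$tawss)) {
    error_metric(pairs$tawss$f_A, pairs$tawss$f_B)
  } else NA_real_
  eo <- if (!is.null(pairs$osi)) {
    error_metric(pairs$osi$f_A, pairs$osi$f_B)
  } else NA_real_
  dpair <- pairs$eq_diameter
  if (is.null(dpair)) {
    dpair <- structure(
      list(s_grid = pairs$area$s_grid,
           f_A = equivalent_diameter(pairs$area$f_A),
           f_B = equivalent_diameter(pairs$area$f_B),
           quantity = "eq_diameter"),
      class = "paired_profiles"
    )
  }
  dd <- mean_diameter_difference(dpair)
  data.frame(vessel = vessel, E_A = ea, E_TAWSS = et, E_OSI = eo,
             mean_diff_mm = dd$mean, sd_diff_mm = dd$sd,
             stringsAsFactors = FALSE)
}
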