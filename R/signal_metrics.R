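#' Flow-direction metric relative to the main field axis
#'
#' For each centerline tangent, the signed cosine of the angle to the main
#' magnetic field direction (B0, the scanner z-axis by default):
#' `Gamma = t . B0`.  It is 1 where flow runs parallel to B0 and 0 where flow
#' is perpendicular.  Set `absolute = TRUE` when the centerline traversal
#' direction is arbitrary and only the angle magnitude is meaningful.
#'
#' @param tangents n x 3 matrix of unit tangent vectors.
#' @param b0_axis unit 3-vector, default `c(0, 0, 1)`.
#' @param absolute return `|Gamma|` instead of the signed value.
#' @return numeric vector in `[-1, 1]` (or `[0, 1]` when `absolute`).
#' @export
gamma_metric <- function(tangents, b0_axis = c(0, 0, 1), absolute = FALSE) {
  tangents <- rbind(tangents)
  tn <- sqrt(rowSums(tangents^2))
  bn <- sqrt(sum(b0_axis^2))
  if (any(abs(tn - 1) > 1e-6) || abs(bn - 1) > 1e-6) {
    stop("tangents and b0_axis must be unit vectors (within 1e-6)")
  }
  g <- as.vector(tangents %*% b0_axis)
  if (absolute) abs(g) else g
}

#' Spatial derivative of the flow-direction metric
#'
#' First derivative of Gamma with respect to arclength — a proxy for the
#' instantaneous curvature of the vessel relative to B0.  Uses second-order
#' central differences at interior points and one-sided differences at the
#' ends.
#'
#' @param gamma numeric vector of Gamma values.
#' @param s_grid arclength positions in mm, strictly increasing.
#' @return numeric vector, units 1/mm.
#' @export
gamma_derivative <- function(gamma, s_grid) {
  n <- length(gamma)
  if (n < 3L) stop("need at least 3 samples")
  if (length(s_grid) != n || any(diff(s_grid) <= 0)) {
    stop("s_grid must be strictly increasing and match gamma in length")
  }
  d <- numeric(n)
  d[1] <- (gamma[2] - gamma[1]) / (s_grid[2] - s_grid[1])
  d[n] <- (gamma[n] - gamma[n - 1]) / (s_grid[n] - s_grid[n - 1])
  i <- 2:(n - 1)
  d[i] <- (gamma[i + 1] - gamma[i - 1]) / (s_grid[i + 1] - s_grid[i - 1])
  d
}

#' Min-max normalization to [0, 1]
#'
#' Constant input cannot be rescaled; by convention it maps to all zeros and
#' a warning is raised.
#'
#' @param values numeric vector.
#' @return numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  rng <- range(values)
  if (diff(rng) == 0) {
    warning("constant input: min-max normalization returns all zeros")
    return(rep(0, length(values)))
  }
  (values - rng[1]) / diff(rng)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties.  For n <= 8 with untied data
#' the p-value comes from full enumeration of all permutations; otherwise the
#' large-sample t approximation is used.  Constant input has no defined rank
#' correlation and is reported as `NA` with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `r`, `p`, `n`, `method`, `degenerate`.
#' @export
spearman_correlation <- function(x, y,
                                 alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (length(y) != n || n < 3L) stop("x and y must have equal length >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(r = NA_real_, p = NA_real_, n = n, method = "degenerate",
                degenerate = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  r <- if (!ties) {
    # tie-free closed form: exact (gives +/-1 exactly on monotone pairs)
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    stats::cor(rx, ry)
  }
  if (n <= 8L && !ties) {
    perms <- permutations_of(n)
    ry_sorted <- ry[order(rx)]
    rs <- apply(perms, 1, function(p) stats::cor(seq_len(n), ry_sorted[p]))
    p <- switch(alternative,
      two.sided = mean(abs(rs) >= abs(r) - 1e-12),
      less = mean(rs <= r + 1e-12),
      greater = mean(rs >= r - 1e-12)
    )
    method <- "exact permutation"
  } else {
    if (abs(r) == 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- switch(alternative,
        two.sided = 2 * stats::pt(-abs(tstat), df = n - 2),
        less = stats::pt(tstat, df = n - 2),
        greater = stats::pt(tstat, df = n - 2, lower.tail = FALSE)
      )
    }
    method <- "t approximation"
  }
  list(r = r, p = p, n = n, method = method, degenerate = FALSE)
}

# All permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, ] <- cbind(k, sub + (sub >= k))
  }
  out
}
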