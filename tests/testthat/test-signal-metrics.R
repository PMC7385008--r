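test_that("Gamma is the signed cosine of the angle to B0", {
  expect_identical(gamma_metric(c(1, 0, 0)), 0)
  expect_identical(gamma_metric(c(0, 0, 1)), 1)
  expect_equal(gamma_metric(c(sin(pi / 4), 0, cos(pi / 4))), sqrt(2) / 2)
  expect_equal(gamma_metric(c(0, 0, -1)), -1)
  expect_equal(gamma_metric(c(0, 0, -1), absolute = TRUE), 1)
  expect_error(gamma_metric(c(1, 1, 0)), "unit")
})

test_that("Gamma is invariant under simultaneous rotation of tangents and B0", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      tg <- matrix(rnorm(30), 10, 3)
      tg <- tg / sqrt(rowSums(tg^2))
      RR <- rotation_matrix(runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
      g1 <- gamma_metric(tg)
      g2 <- gamma_metric(tg %*% t(RR), as.vector(RR %*% c(0, 0, 1)))
      expect_equal(g2, g1, tolerance = 1e-9)
      expect_true(all(abs(g1) <= 1 + 1e-12))
    }
  })
})

test_that("Gamma' differentiates correctly on known fields", {
  s <- seq(0, 10, by = 0.5)
  expect_equal(gamma_derivative(rep(0.3, length(s)), s),
               rep(0, length(s)))
  expect_equal(gamma_derivative(s / 10, s), rep(1 / 10, length(s)))
  # circular arc: Gamma(s) = cos(s / R), derivative -sin(s / R) / R
  R <- 20
  s <- seq(0, 50, by = 1)
  gp <- gamma_derivative(cos(s / R), s)
  interior <- 2:(length(s) - 1)
  expect_equal(gp[interior], (-sin(s / R) / R)[interior], tolerance = 0.01)
})

test_that("min-max normalization maps to [0,1] and is affine-invariant", {
  expect_identical(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(out <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_identical(out, c(0, 0, 0))
  withr::with_seed(7, {
    for (rep in 1:10) {
      x <- rnorm(20)
      a <- runif(1, 0.1, 5)
      b <- rnorm(1)
      expect_equal(minmax_normalize(a * x + b), minmax_normalize(x),
                   tolerance = 1e-12)
    }
  })
})

test_that("Spearman correlation handles monotone, hand-computed and degenerate cases", {
  expect_identical(spearman_correlation(1:10, (1:10)^3)$r, 1)
  expect_identical(spearman_correlation(1:10, -(1:10))$r, -1)
  # hand-ranked example: d = (-1,1,-1,1,0), sum d^2 = 4, r = 1 - 24/120
  res <- spearman_correlation(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8)
  expect_identical(res$method, "exact permutation")
  # exhaustive-permutation p cross-checked against cor.test's exact p
  ct <- stats::cor.test(1:5, c(2, 1, 4, 3, 5), method = "spearman",
                        exact = TRUE)
  expect_equal(res$p, unname(ct$p.value), tolerance = 1e-12)
  expect_true(is.na(spearman_correlation(rep(1, 5), 1:5)$r))
})

test_that("Spearman r is invariant under strictly monotone transforms", {
  withr::with_seed(3, {
    x <- rnorm(30)
    y <- rnorm(30)
    r0 <- spearman_correlation(x, y)$r
    expect_equal(spearman_correlation(exp(x), y)$r, r0)
    expect_equal(spearman_correlation(x, y^3 + 2 * y)$r, r0)
  })
  # large-sample branch agrees with cor.test's t approximation
  withr::with_seed(4, {
    x <- rnorm(40)
    y <- x + rnorm(40)
    res <- spearman_correlation(x, y)
    ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  })
})
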