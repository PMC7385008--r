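test_that("common-grid resampling respects overlap and linear exactness", {
  # identical grids pass through unchanged
  p <- list(s = 0:10, value = (0:10)^2)
  rp <- resample_to_common_grid(p, p, delta_s = 1)
  expect_equal(rp$f_A, p$value)
  expect_equal(rp$f_B, p$value)
  # linear ramps interpolate exactly from offset grids
  a <- list(s = seq(-0.5, 50.5, by = 1), value = 2 * seq(-0.5, 50.5, by = 1))
  b <- list(s = seq(0, 50, by = 1), value = 2 * seq(0, 50, by = 1))
  rp <- resample_to_common_grid(a, b, delta_s = 1)
  expect_equal(rp$f_A, rp$f_B, tolerance = 1e-12)
  # overlap of [0,50] and [10,60] at 1 mm: grid spans [10,50], 41 points
  a <- list(s = 0:50, value = rep(1, 51))
  b <- list(s = 10:60, value = rep(1, 51))
  rp <- resample_to_common_grid(a, b, delta_s = 1)
  expect_length(rp$s_grid, 41L)
  expect_equal(range(rp$s_grid), c(10, 50))
  # disjoint ranges are rejected with both ranges reported
  expect_error(
    resample_to_common_grid(list(s = 0:10, value = 0:10),
                            list(s = 20:30, value = 20:30), 1),
    "spans"
  )
})

test_that("error metric matches hand-computed values and its invariants", {
  expect_identical(error_metric(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(error_metric(3, 1), 1)        # 2 * |2/4|
  expect_identical(error_metric(c(1, 1), c(1, 3)), 0.5) # (2/2)(0 + 1/2)
  expect_identical(error_metric(c(1, 0), c(1, 0)), 0) # 0/0 pairs are no-ops
  expect_error(error_metric(c(2, 1), c(-2, 1)), "indices: 1")
  withr::with_seed(5, {
    for (rep in 1:20) {
      n <- sample(3:50, 1)
      fa <- runif(n, 0, 10)
      fb <- runif(n, 0, 10)
      e <- error_metric(fa, fb)
      expect_gte(e, 0)
      expect_lte(e, 2)
      expect_identical(error_metric(fb, fa), e)
      c0 <- runif(1, 0.1, 7)
      expect_equal(error_metric(c0 * fa, c0 * fb), e, tolerance = 1e-12)
    }
  })
})

test_that("Bland-Altman bias, SD and limits follow the A-minus-B convention", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(ba0$bias, 0)
  expect_identical(ba0$limits_of_agreement, c(0, 0))
  ba <- bland_altman(c(1, 3), c(2, 4))
  expect_identical(ba$pair_means, c(1.5, 3.5))
  expect_identical(ba$pair_differences, c(-1, -1))
  expect_identical(ba$bias, -1)
  expect_identical(ba$sd_difference, 0)
  expect_error(bland_altman(1, 1), "n >= 2")
  # bias of (x, x + delta) is exactly -delta
  withr::with_seed(8, {
    x <- rnorm(30)
    expect_equal(bland_altman(x, x + 0.37)$bias, -0.37, tolerance = 1e-12)
  })
})

test_that("Bland-Altman recovers an injected offset at the expected precision", {
  n <- 40
  delta <- 0.25
  sigma <- 0.1
  recovered <- vapply(1:100, function(seed) {
    withr::with_seed(seed, {
      x <- runif(n, 2, 5)
      bland_altman(x + delta + rnorm(n, sd = sigma), x)$bias
    })
  }, numeric(1))
  expect_true(all(abs(recovered - delta) < 3 * sigma / sqrt(n)))
})

test_that("mean diameter difference reports the analytic bias", {
  mk_pair <- function(dA, dB) {
    structure(list(s_grid = seq_along(dA), f_A = dA, f_B = dB,
                   quantity = "eq_diameter"),
              class = "paired_profiles")
  }
  same <- mean_diameter_difference(mk_pair(rep(5, 10), rep(5, 10)))
  expect_identical(same$mean, 0)
  expect_identical(same$sd, 0)
  biased <- mean_diameter_difference(mk_pair(rep(5, 10), rep(5 * 0.95, 10)))
  expect_equal(biased$mean, 0.25, tolerance = 1e-12)
})

test_that("error reports carry all quantities, mark missing ones NA, and stay in bounds", {
  mk <- function(fa, fb, q) {
    structure(list(s_grid = seq_along(fa), f_A = fa, f_B = fb, quantity = q),
              class = "paired_profiles")
  }
  # identical pairs: all zero
  a <- rep(pi * 2.5^2, 20)
  rep0 <- build_error_report(list(area = mk(a, a, "area"),
                                  tawss = mk(a, a, "TAWSS"),
                                  osi = mk(a / 100, a / 100, "OSI")))
  expect_identical(rep0$E_A, 0)
  expect_identical(rep0$E_TAWSS, 0)
  expect_identical(rep0$E_OSI, 0)
  # missing quantities are NA, not zero
  rep1 <- build_error_report(list(area = mk(a, 0.9 * a, "area")))
  expect_true(is.na(rep1$E_TAWSS))
  expect_true(is.na(rep1$E_OSI))
  expect_gt(rep1$E_A, 0)
  expect_error(build_error_report(list()), "area")
  withr::with_seed(9, {
    for (rep in 1:10) {
      fa <- runif(15, 0.1, 10)
      fb <- runif(15, 0.1, 10)
      r <- build_error_report(list(area = mk(fa, fb, "area")))
      expect_true(r$E_A >= 0 && r$E_A <= 2)
    }
  })
})

test_that("identical sources yield zero error and zero bias regardless of grids", {
  a <- list(s = seq(0, 50, by = 0.8), value = 5 + sin(seq(0, 50, by = 0.8)))
  b <- list(s = seq(0.3, 49, by = 1.1),
            value = 5 + sin(seq(0.3, 49, by = 1.1)))
  # same underlying smooth function sampled on different grids
  rp <- resample_to_common_grid(a, b, delta_s = 1)
  expect_lt(error_metric(rp$f_A, rp$f_B), 0.01)
  # exactly identical sources
  rp2 <- resample_to_common_grid(a, a, delta_s = 1)
  expect_identical(error_metric(rp2$f_A, rp2$f_B), 0)
  expect_identical(bland_altman(rp2$f_A, rp2$f_B)$bias, 0)
})

test_that("the laminar WSS chain amplifies area error (E_TAWSS >= E_A)", {
  # at fixed flow, tau ~ A^-1.5: relative differences grow 1.5-fold, so the
  # error metric of the chained quantity dominates the area error
  withr::with_seed(21, {
    for (rep in 1:10) {
      a0 <- pi * 2.5^2
      fa <- a0 * (1 + rnorm(30, sd = 0.05))
      fb <- a0 * (1 + rnorm(30, sd = 0.05))
      expect_gte(error_metric(fa^-1.5, fb^-1.5), error_metric(fa, fb))
    }
  })
})
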