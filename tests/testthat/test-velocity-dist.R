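test_that("normalization solve reproduces the reference constants and the exponential limit", {
  sol <- solve_normalization(3.8, 5e-3, 1e-3)
  expect_equal(sol[["p0"]], 1015.24, tolerance = 1e-5)
  expect_equal(sol[["lam"]], 1017.36, tolerance = 1e-5)
  # residual contract
  expect_lt(max(abs(attr(sol, "residuals"))), 1e-10)
  # with lam*v_min >> 1 the tail mass vanishes: pure exponential,
  # p0 = lam = 1/v_moy
  sol2 <- solve_normalization(3.8, 1.0, 1e-3)
  expect_equal(sol2[["p0"]], 1000, tolerance = 1e-6)
  expect_equal(sol2[["lam"]], 1000, tolerance = 1e-6)
  expect_error(solve_normalization(0.9, 5e-3, 1e-3), "alpha")
  expect_error(velocity_dist(1, 5e-3, 1e-3), "alpha")
})

test_that("every solved distribution has unit mass and the requested mean (quadrature oracle)", {
  for (a in sweep_alphas) {
    for (k in sweep_scales) {
      d <- velocity_dist(a, k * 5e-3, k * 1e-3)
      expect_lt(abs(quad_moment(d, 0) - 1), 1e-6)
      expect_lt(abs(quad_moment(d, 1) / d$v_moy - 1), 1e-6)
    }
  }
})

test_that("density has the stated branch values and is continuous at the threshold", {
  d <- ref_dist
  expect_identical(dvel(0, d), d$p0)
  at_thresh <- d$p0 * exp(-d$lam * d$v_min)
  expect_equal(dvel(d$v_min, d), at_thresh)          # both branches agree
  expect_equal(dvel(d$v_min, d), 6.268, tolerance = 1e-3)
  expect_equal(dvel(2 * d$v_min, d), at_thresh * 2^(-4.8), tolerance = 1e-12)
  expect_equal(dvel(1e-2, d), 0.225, tolerance = 1e-2)
  # continuity: approach the threshold from both sides
  eps <- 1e-12
  expect_equal(dvel(d$v_min - eps, d), dvel(d$v_min + eps, d),
               tolerance = 1e-6)
  expect_error(dvel(-1e-3, d), ">= 0")
})

test_that("cdf and quantile function are exact inverses on both branches", {
  d <- ref_dist
  expect_identical(pvel(0, d), 0)
  rc <- d$p0 / d$lam * (1 - exp(-d$lam * d$v_min))
  expect_equal(pvel(d$v_min, d), rc)
  expect_equal(rc, 0.9918, tolerance = 1e-4)
  expect_equal(qvel(0, d), 0)
  expect_equal(qvel(rc, d), d$v_min, tolerance = 1e-12)
  # round-trip on a grid covering bulk and tail
  r <- seq(1e-6, 1 - 1e-6, length.out = 1000)
  expect_lt(max(abs(pvel(qvel(r, d), d) - r)), 1e-12)
  # v-space round trip: the deep tail loses a few digits because the
  # quantile bracket is a difference of probabilities that are nearly 1
  v <- c(1e-5, 1e-4, 1e-3, 4.9e-3, 5e-3, 6e-3, 0.05)
  expect_lt(max(abs(qvel(pvel(v, d), d) / v - 1)), 1e-9)
  # monotone non-decreasing cdf, strictly increasing quantiles
  expect_true(all(diff(pvel(seq(0, 0.1, length.out = 500), d)) >= 0))
  expect_true(all(diff(qvel(seq(0, 0.999, length.out = 500), d)) > 0))
  expect_error(pvel(-1, d), ">= 0")
  expect_error(qvel(1.2, d), "probabilities")
})

test_that("scaling both velocity parameters by k rescales the law exactly", {
  for (k in c(0.5, 2, 3)) {
    d1 <- velocity_dist(3.8, 5e-3, 1e-3)
    dk <- velocity_dist(3.8, k * 5e-3, k * 1e-3)
    expect_equal(dk$lam, d1$lam / k, tolerance = 1e-12)
    expect_equal(dk$p0, d1$p0 / k, tolerance = 1e-12)
    v <- c(1e-4, 1e-3, 5e-3, 2e-2)
    expect_equal(pvel(k * v, dk), pvel(v, d1), tolerance = 1e-13)
  }
})

test_that("sampled magnitudes have the right mean, sign symmetry and distribution", {
  d <- ref_dist
  set.seed(42)
  n <- 1e6
  v <- rvel(n, d)
  mag <- abs(v)
  se <- sqrt((vdist_moment(d, 2) - d$v_moy^2) / n)
  expect_lt(abs(mean(mag) - d$v_moy), 3 * se)
  expect_lt(abs(mean(v)), 3 * sqrt(vdist_moment(d, 2) / n))
  expect_lt(ks_stat(mag, d), 1.63 / sqrt(n))  # 1% asymptotic critical value
  # reproducibility and magnitude/sign draw order
  set.seed(7); a <- rvel(10, d)
  set.seed(7); b <- rvel(10, d)
  expect_identical(a, b)
  set.seed(7); m <- qvel(runif(10), d); s <- ifelse(runif(10) < 0.5, -1, 1)
  expect_identical(a, m * s)
})

test_that("sampled magnitudes pass KS across the parameter sweep", {
  n <- 2e5
  i <- 0
  for (a in sweep_alphas) {
    for (k in c(0.5, 3)) {
      i <- i + 1
      d <- velocity_dist(a, k * 5e-3, k * 1e-3)
      set.seed(100 + i)
      expect_lt(ks_stat(rvel(n, d, signed = FALSE), d), 1.63 / sqrt(n))
    }
  }
})

test_that("speed cap redraws the magnitudes above it", {
  d <- ref_dist
  set.seed(3)
  v <- rvel(5e4, d, signed = FALSE, cap = 0.02)
  expect_lte(max(v), 0.02)
  # capped sample is the conditional law below the cap
  p_below <- pvel(0.02, d)
  expect_lt(ks_stat_cond <- max(abs(pvel(sort(v), d) / p_below -
                                      seq_along(v) / length(v))),
            1.63 / sqrt(length(v)))
  expect_error(rvel(10, d, cap = -1), "cap")
})

test_that("closed-form moments match quadrature", {
  d <- ref_dist
  expect_equal(vdist_moment(d, 0), 1, tolerance = 1e-12)
  expect_equal(vdist_moment(d, 1), 1e-3, tolerance = 1e-12)
  expect_equal(vdist_moment(d, 2), quad_moment(d, 2), tolerance = 1e-9)
  expect_equal(vdist_moment(d, 2), 2.14e-6, tolerance = 2e-3)
  d_levy <- velocity_dist(1.8, 5e-3, 1e-3)
  expect_error(vdist_moment(d_levy, 2), "diverges")
})

test_that("parameter files round-trip and re-solve when constants are missing", {
  d <- ref_dist
  path <- tempfile(fileext = ".txt")
  write_vdist(d, path)
  d2 <- read_vdist(path)
  expect_equal(d2[c("alpha", "v_min", "v_moy", "p0", "lam")],
               d[c("alpha", "v_min", "v_moy", "p0", "lam")])
  writeLines(c("alpha = 3.8", "v_min = 5e-3", "v_moy = 1e-3"), path)
  d3 <- read_vdist(path)
  expect_equal(d3$p0, d$p0, tolerance = 1e-10)
  writeLines(c("alpha = 3.8", "v_min = 5e-3"), path)
  expect_error(read_vdist(path), "v_moy")
})
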