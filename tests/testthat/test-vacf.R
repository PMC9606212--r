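ve_from_list <- function(v, dt = 1e-5) {
  structure(list(v = v, dt = dt), class = "velocity_ensemble")
}

test_that("VACF of constant-velocity records is the squared speed at every lag", {
  set.seed(12)
  c0 <- 2e-3
  v <- lapply(1:20, function(i) rep(sample(c(-c0, c0), 1), 200))
  curve <- vacf(ve_from_list(v), max_lag = 20)
  expect_equal(curve$value, rep(c0^2, 21), tolerance = 1e-12)
  expect_equal(curve$lag, (0:20) * 1e-5)
  expect_equal(curve$n_pairs, 20 * (200 - 0:20))
})

test_that("VACF of independent steps vanishes beyond lag zero", {
  set.seed(13)
  v <- lapply(1:50, function(i) rvel(2000, ref_dist))
  curve <- vacf(ve_from_list(v), max_lag = 10)
  m2 <- vdist_moment(ref_dist, 2)
  expect_equal(curve$value[1], m2, tolerance = 0.1)
  # each lagged product has variance ~ m2^2; 3 SE bound
  se <- sqrt(curve$value[1]^2 / curve$n_pairs[-1])
  expect_true(all(abs(curve$value[-1]) < 3.5 * se))
})

test_that("renewal (piecewise-constant) velocities give the triangular VACF", {
  # velocities redrawn every m steps -> VACF(k) = <v^2> (1 - k/m), 0 beyond
  set.seed(14)
  m <- 50L
  v <- lapply(1:300, function(i) {
    phase <- sample.int(m, 1) - 1L
    n_ep <- 12L
    rep(rvel(n_ep, ref_dist), each = m)[(phase + 1):(phase + 500)]
  })
  curve <- vacf(ve_from_list(v), max_lag = 2 * m)
  m2 <- curve$value[1]
  k <- 0:(2 * m)
  expected <- m2 * pmax(1 - k / m, 0)
  expect_lt(max(abs(curve$value - expected)) / m2, 0.05)
})

test_that("VACF pairs never straddle record boundaries", {
  # two records with opposite constant velocities: any cross-boundary
  # product would be negative; correct handling keeps VACF exactly c^2
  v <- list(rep(1e-3, 50), rep(-1e-3, 50))
  curve <- vacf(ve_from_list(v), max_lag = 5)
  expect_equal(curve$value, rep(1e-6, 6), tolerance = 1e-12)
})

test_that("lags beyond the longest record are dropped with a warning", {
  v <- list(rep(1e-3, 10))
  expect_warning(curve <- vacf(ve_from_list(v), max_lag = 20), "dropped")
  expect_equal(nrow(curve), 10)
})

test_that("power-law fit recovers a noiseless curve exactly and scales correctly", {
  curve <- synth_vacf(a = 0.017e-3, b = 0.808)
  # noiseless fixture: lm warns about an essentially perfect fit
  fit <- suppressWarnings(fit_vacf_powerlaw(curve, fit_window = c(1e-5, 1e-3)))
  expect_equal(fit$a, 0.017e-3, tolerance = 1e-10)
  expect_equal(fit$b, 0.808, tolerance = 1e-10)
  # doubling the curve doubles a, leaves b unchanged
  curve2 <- curve
  curve2$value <- 2 * curve2$value
  fit2 <- suppressWarnings(fit_vacf_powerlaw(curve2, fit_window = c(1e-5, 1e-3)))
  expect_equal(fit2$a, 2 * fit$a, tolerance = 1e-10)
  expect_equal(fit2$b, fit$b, tolerance = 1e-10)
  expect_error(fit_vacf_powerlaw(curve[1:2, ], c(0, 1)), "3")
})

test_that("fitted exponent recovers the generating value under 5% noise", {
  set.seed(15)
  curve <- synth_vacf(a = 0.017e-3, b = 0.808, noise_sd_rel = 0.05)
  fit <- fit_vacf_powerlaw(curve, fit_window = c(1e-5, 1e-3))
  expect_lt(abs(fit$b - 0.808), 2.5 * fit$sd_b)
  expect_lt(abs(fit$a / 0.017e-3 - 1), 0.1)
})

test_that("fit standard error shrinks like one over sqrt(number of lags)", {
  ses <- vapply(c(50, 200, 800), function(nl) {
    reps <- vapply(1:20, function(i) {
      curve <- synth_vacf(0.017e-3, 0.808,
                          lags = 10^seq(-5, -3, length.out = nl),
                          noise_sd_rel = 0.05, seed = 1000 + i * nl)
      fit_vacf_powerlaw(curve, c(1e-5, 1e-3))$sd_b
    }, 0)
    mean(reps)
  }, 0)
  # nl x 4 -> SE / 2, within 25%
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.25)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.25)
})

test_that("decorrelation time finds the noise-floor crossing", {
  # monotone decay to zero, with an alternating-sign noise floor of known
  # spread in the tail window: sigma ~ 0.01, so the crossing is at the
  # first lag where the ramp 1 - k/100 falls to 0.01, i.e. k = 99
  lags <- (0:200) * 1e-5
  vals <- pmax(1 - (0:200) / 100, 0)
  vals[151:201] <- 0.01 * rep_len(c(1, -1), 51)
  curve <- structure(data.frame(lag = lags, value = vals, n_pairs = NA),
                     class = c("vacf_curve", "data.frame"))
  res <- decorrelation_time(curve, tail_window = c(1.5e-3, 2e-3))
  expect_equal(res$delta_t, 99e-5, tolerance = 0.02)
  expect_equal(res$sigma_tail, 0.01, tolerance = 0.02)
  # scale invariance: multiplying the curve rescales sigma identically
  curve2 <- curve
  curve2$value <- 7 * curve2$value
  res2 <- decorrelation_time(curve2, tail_window = c(1.5e-3, 2e-3))
  expect_equal(res2$delta_t, res$delta_t)
  expect_equal(res2$sigma_tail, 7 * res$sigma_tail, tolerance = 1e-12)
  # error when the curve never reaches the floor
  curve3 <- curve
  curve3$value <- curve3$value + 10
  expect_error(decorrelation_time(curve3, c(1.5e-3, 2e-3)), "noise floor")
})
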