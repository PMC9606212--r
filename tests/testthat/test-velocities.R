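make_traj <- function(y, dt = 1e-5, L = 5e-5, id = "a") {
  trajectory_set(rep(id, length(y)), (seq_along(y) - 1) * dt, y,
                 dt_sample = dt, L = L)
}

test_that("finite-difference velocities follow the forward-difference definition", {
  ts <- make_traj(c(1.0e-6, 1.5e-6))
  ve <- extract_velocities(ts)
  expect_equal(ve$v[[1]], 0.05)
  expect_equal(ve$dt, 1e-5)
  # linear trajectory: every velocity equals the slope
  c0 <- 3.2e-4
  ts2 <- make_traj(c0 * (0:50) * 1e-5)
  expect_equal(unique(round(extract_velocities(ts2)$v[[1]], 12)), c0)
  # stride s: effective interval s * dt, last samples yield no velocity
  ve3 <- extract_velocities(ts2, stride = 7)
  expect_equal(ve3$dt, 7e-5)
  expect_length(ve3$v[[1]], 7)  # floor(50/7)
  expect_error(extract_velocities(make_traj(1e-6), stride = 1), "stride")
})

test_that("mean absolute velocity averages per platelet first, then over platelets", {
  v <- list(a = rep(2e-3, 10), b = rep(-4e-3, 1000))
  # per-platelet means 2e-3 and 4e-3 -> 3e-3, not the pooled mean
  expect_equal(mean_abs_velocity(v), 3e-3)
  expect_equal(mean_abs_velocity(list(rep(5e-4, 3))), 5e-4)
  expect_error(mean_abs_velocity(list()), "no velocities")
})

test_that("wall-exclusion band keeps [margin, L - margin] and splits crossing records", {
  # 50 um domain with 10 um margins -> band [10, 40] um
  L <- 50e-6
  y <- c(5, 15, 20, 45, 30, 25, 8, 12) * 1e-6
  ts <- make_traj(y, L = L)
  out <- exclusion_filter(ts, margin = 10e-6)
  expect_true(all(out$y >= 10e-6 & out$y <= 40e-6))
  # in-band samples: 15,20 | 30,25 | 12 -> three segments, 5 samples
  expect_equal(nrow(out), 5)
  expect_equal(length(unique(out$platelet_id)), 3)
  seg_len <- table(out$platelet_id)
  expect_equal(sum(seg_len), sum(y >= 10e-6 & y <= 40e-6))
  # an entirely in-band trajectory is untouched
  ts_in <- make_traj(seq(15e-6, 35e-6, length.out = 20), L = L)
  out_in <- exclusion_filter(ts_in, margin = 10e-6)
  expect_equal(out_in$y, ts_in$y)
  expect_error(exclusion_filter(ts, margin = 30e-6), "empty")
})

test_that("log-binned densities integrate to the in-range fraction", {
  # all mass inside one bin of width w -> density 1/w
  v <- rep(1.05e-3, 500)
  db <- log_binned_density(v, bins_per_decade = 4, range = c(1e-4, 1e-2))
  hot <- db[db$count > 0, ]
  expect_equal(nrow(hot), 1)
  expect_equal(hot$density, 1 / hot$width)
  # integral equals the fraction of the sample inside the binned range
  d <- ref_dist
  set.seed(11)
  s <- rvel(5e4, d, signed = FALSE)
  db2 <- log_binned_density(s, bins_per_decade = 8, range = c(1e-5, 0.3))
  expect_equal(sum(db2$density * db2$width),
               mean(s >= 1e-5 & s <= 0.3), tolerance = 1e-12)
  expect_error(log_binned_density(s, range = c(-1, 1)), "positive")
})

test_that("stride coarsening suppresses the power-law tail of the velocity histogram", {
  d <- ref_dist
  # renewal trajectories with 0.5 ms memory, sampled at 1e-5 s
  ts <- synth_trajectories(d, n_platelets = 60, duration = 0.25, seed = 21)
  v_fine <- abs(unlist(extract_velocities(ts, stride = 1)$v))
  v_coarse <- abs(unlist(extract_velocities(ts, stride = 100)$v))
  tail_fine <- mean(v_fine > d$v_min)
  tail_coarse <- mean(v_coarse > d$v_min)
  expect_lt(tail_coarse, tail_fine)
})

test_that("wall profiles are flat for homogeneous ensembles and mask rare bins", {
  # deterministic drift: velocity c everywhere -> flat mean, zero variance
  c0 <- 1e-4
  ids <- rep(sprintf("p%d", 1:20), each = 51)
  y0 <- rep(seq(5e-6, 30e-6, length.out = 20), each = 51)
  tt <- rep((0:50) * 1e-5, times = 20)
  ts <- trajectory_set(ids, tt, y0 + c0 * tt, dt_sample = 1e-5, L = 5e-5)
  prof <- wall_profiles(ts, bin_width = 1e-6, min_freq = 1e-3)
  expect_true(all(abs(prof$mean - c0) < 1e-9))
  expect_true(all(prof$var < 1e-18, na.rm = TRUE))
  expect_equal(attr(prof, "global_mean"), c0, tolerance = 1e-9)
  # bins visited by fewer than min_freq of the samples are absent
  prof2 <- wall_profiles(ts, bin_width = 1e-6, min_freq = 0.2)
  expect_lt(nrow(prof2), nrow(prof))
  n_samples <- sum(table(ts$platelet_id) - 1L)
  expect_true(all(prof2$n >= 0.2 * n_samples))
})

test_that("per-bin means of a y-independent ensemble match the global mean (chi-square)", {
  # memoryless steps (memory = sampling interval) so that the velocities
  # entering each position bin are independent draws
  ts <- synth_trajectories(ref_dist, n_platelets = 40, duration = 0.1,
                           memory_time = 1e-5, seed = 31,
                           confinement = "reflecting")
  prof <- wall_profiles(ts, bin_width = 5e-6, min_freq = 1e-3)
  v_all <- unlist(extract_velocities(ts)$v)
  gm <- mean(v_all)
  # chi-square over bins: sum of squared z-scores of bin means
  z2 <- (prof$mean - gm)^2 / (prof$var / prof$n)
  pval <- stats::pchisq(sum(z2), df = nrow(prof), lower.tail = FALSE)
  expect_gt(pval, 0.001)
})
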