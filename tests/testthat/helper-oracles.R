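# Shared fixtures and independent numerical oracles.

# reference parameter set: alpha 3.8, threshold 5e-3 m/s, mean 1e-3 m/s
ref_dist <- velocity_dist(3.8, 5e-3, 1e-3)

# quadrature oracle for the first moments, independent of the closed forms;
# the integrand spans many scales, so integrate() is split at the threshold
quad_moment <- function(dist, k = 0) {
  f <- function(v) v^k * dvel(v, dist)
  stats::integrate(f, 0, dist$v_min, rel.tol = 1e-10)$value +
    stats::integrate(f, dist$v_min, Inf, rel.tol = 1e-10)$value
}

# one-sample KS statistic against the model CDF (magnitudes)
ks_stat <- function(v, dist) {
  v <- sort(v)
  n <- length(v)
  fitted <- pvel(v, dist)
  max(abs(fitted - seq_len(n) / n), abs(fitted - (seq_len(n) - 1) / n))
}

# parameter sweep used by several property tests: tail exponents crossing
# the infinite-variance boundary, joint velocity scalings
sweep_alphas <- c(1.8, 2, 3, 3.8, 4, 5)
sweep_scales <- c(0.5, 1, 2, 3)
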