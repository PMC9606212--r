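#' Synthetic platelet trajectories with a known velocity law and memory
#'
#' Generates trajectory ensembles with the statistical structure the
#' analysis pipeline assumes, so every stage can be validated against a
#' known truth without high-fidelity simulation data. Velocities follow a
#' renewal process: each platelet draws a signed velocity from `dist` and
#' keeps it for one memory time, then redraws independently. The
#' piecewise-constant construction makes the marginal of the fine-grained
#' velocities *exactly* the generating distribution (what the
#' distribution-fitting stages need), and its autocorrelation is the
#' triangle \eqn{\langle v^2\rangle\,(1 - \tau/\Delta m)} for
#' \eqn{\tau < \Delta m}, zero beyond — so the decorrelation-time
#' estimator should recover `memory_time`. Renewal epochs are
#' phase-randomised per platelet (first redraw at a uniform offset) to
#' avoid ensemble-synchronised artefacts in the VACF.
#'
#' Defaults emulate the recording protocol of a wall-bounded high-fidelity
#' shear-flow simulation: positions sampled at `1e-5` s for 1 s in a 50 um
#' gap, with a 0.5 ms velocity memory.
#'
#' @param dist A [velocity_dist()]. Default: the reference parameter set
#'   `alpha = 3.8`, `v_min = 5e-3`, `v_moy = 1e-3` (m/s).
#' @param n_platelets Number of platelets. Default 200.
#' @param duration Record length, s. Default 1.
#' @param memory_time Velocity renewal interval, s. Default `0.5e-3`.
#' @param fine_dt Output sampling interval, s (must not exceed
#'   `memory_time`). Default `1e-5`.
#' @param L Domain height, m. Default `50e-6`.
#' @param seed Optional integer seed.
#' @param jitter_sd Standard deviation of additive Gaussian positional
#'   noise, m. Default 0. Jitter of order `fine_dt * v_moy` or larger
#'   visibly distorts the finite-difference velocity marginal (a warning
#'   is issued beyond that scale).
#' @param confinement `"none"` (free space) or `"reflecting"` (positions
#'   folded back into `(0, L)` at both walls).
#' @param phase_randomize Start each platelet's renewal clock at an
#'   independent uniform offset (default), avoiding ensemble-synchronised
#'   redraw artefacts in the VACF. With `FALSE` every platelet redraws at
#'   exact multiples of `memory_time`, so `memory_time = duration` gives
#'   a single straight-line segment.
#' @return A [trajectory_set()] with generation parameters attached as
#'   attribute `"truth"`.
#' @export
synth_trajectories <- function(dist = velocity_dist(3.8, 5e-3, 1e-3),
                               n_platelets = 200L, duration = 1,
                               memory_time = 0.5e-3, fine_dt = 1e-5,
                               L = 50e-6, seed = NULL, jitter_sd = 0,
                               confinement = c("none", "reflecting"),
                               phase_randomize = TRUE) {
  stopifnot(inherits(dist, "velocity_dist"))
  confinement <- match.arg(confinement)
  if (fine_dt > memory_time) stop("'fine_dt' must not exceed 'memory_time'")
  if (duration < memory_time) stop("'duration' must cover one memory time")
  if (jitter_sd < 0) stop("'jitter_sd' must be >= 0")
  if (jitter_sd > 0.5 * fine_dt * dist$v_moy) {
    warning("positional jitter is large relative to fine_dt * v_moy; ",
            "finite-difference velocities will be noise-dominated")
  }
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration / fine_dt)
  tt <- (0:n_steps) * fine_dt
  ids <- sprintf("p%03d", seq_len(n_platelets))
  y_all <- vector("list", n_platelets)
  for (i in seq_len(n_platelets)) {
    y0 <- stats::runif(1, 0, L)
    offset <- if (phase_randomize) {
      stats::runif(1, 0, memory_time)
    } else {
      memory_time
    }
    # renewal epoch index (0-based) of each fine step midpoint
    step_t <- (seq_len(n_steps) - 1L) * fine_dt
    epoch <- findInterval(step_t, c(0, offset + memory_time *
                                      (0:ceiling(duration / memory_time))))
    n_epochs <- max(epoch)
    v_epoch <- rvel(n_epochs, dist, signed = TRUE)
    v <- v_epoch[epoch]
    y <- y0 + c(0, cumsum(v * fine_dt))
    if (confinement == "reflecting") {
      # fold the free path into (0, L): triangle map, period 2L
      y <- abs(((y + L) %% (2 * L)) - L)
    }
    if (jitter_sd > 0) y <- y + stats::rnorm(n_steps + 1L, 0, jitter_sd)
    y_all[[i]] <- y
  }
  out <- trajectory_set(
    platelet_id = rep(ids, each = n_steps + 1L),
    t = rep(tt, times = n_platelets),
    y = unlist(y_all, use.names = FALSE),
    dt_sample = fine_dt, L = L)
  attr(out, "truth") <- list(
    alpha = dist$alpha, v_min = dist$v_min, v_moy = dist$v_moy,
    memory_time = memory_time, fine_dt = fine_dt, L = L,
    jitter_sd = jitter_sd, confinement = confinement, seed = seed)
  out
}

#' Synthetic power-law VACF curve
#'
#' Generates a velocity-autocorrelation curve
#' \eqn{a\,(\tau/1\,\mathrm{ms})^{-b}} with independent multiplicative
#' log-normal noise per lag — the fixture for validating
#' [fit_vacf_powerlaw()].
#'
#' @param a Amplitude: VACF value at a 1 ms lag, m^2/s^2.
#' @param b Decay exponent (dimensionless).
#' @param lags Strictly positive lags, s. Default: 100 log-spaced lags in
#'   `[0.01, 1]` ms.
#' @param noise_sd_rel Standard deviation of the log-noise. Default 0.
#' @param seed Optional integer seed.
#' @return A `"vacf_curve"` (see [vacf()]); `n_pairs` is `NA` for
#'   synthetic curves.
#' @export
synth_vacf <- function(a, b, lags = NULL, noise_sd_rel = 0, seed = NULL) {
  if (is.null(lags)) lags <- 10^seq(log10(1e-5), log10(1e-3),
                                    length.out = 100L)
  if (any(lags <= 0)) stop("'lags' must be strictly positive")
  if (!is.null(seed)) set.seed(seed)
  vals <- a * (lags * 1e3)^(-b)
  if (noise_sd_rel > 0) {
    vals <- vals * exp(stats::rnorm(length(lags), 0, noise_sd_rel))
  }
  structure(data.frame(lag = lags, value = vals, n_pairs = NA_integer_),
            class = c("vacf_curve", "data.frame"))
}

#' Deterministic miniature datasets for tests and examples
#'
#' Writes a small synthetic trajectory ensemble (fixed seed) as a
#' trajectory TSV plus the generating distribution's parameter file, so
#' analyses can be demonstrated and round-tripped from disk. `"small"` is
#' 10 platelets over 0.05 s (fast, for I/O and unit checks); `"medium"`
#' is 200 platelets over 1 s (full recording protocol; large on disk and
#' slow — intended for recovery studies, not routine tests).
#'
#' @param name `"small"` or `"medium"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector with paths `trajectories` and `params`,
#'   invisibly.
#' @export
make_fixture <- function(name = c("small", "medium"), dir = tempdir()) {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dist <- velocity_dist(3.8, 5e-3, 1e-3)
  cfg <- switch(name,
                small = list(n = 10L, dur = 0.05, seed = 101L),
                medium = list(n = 200L, dur = 1, seed = 102L))
  traj <- synth_trajectories(dist, n_platelets = cfg$n, duration = cfg$dur,
                             seed = cfg$seed)
  paths <- c(trajectories = file.path(dir, paste0("fixture_", name, ".tsv")),
             params = file.path(dir, paste0("fixture_", name, "_dist.txt")))
  write_trajectories(traj, paths[["trajectories"]])
  write_vdist(dist, paths[["params"]])
  invisible(paths)
}
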