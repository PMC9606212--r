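#' Memory-time random walk of platelets between walls
#'
#' Propagates `N` independent platelets in a 1-D wall-bounded domain: at
#' every update interval `dt_step` (the velocity decorrelation time) each
#' platelet draws a fresh signed velocity from the magnitude distribution
#' (`+`/`-` equally likely) and moves ballistically,
#' \eqn{y \leftarrow y + v\,\Delta t}. An absorbing wall removes the
#' platelet (deposition) the moment its position crosses it; a reflecting
#' wall maps the overshoot specularly (\eqn{y \to -y} at the bottom,
#' \eqn{y \to 2L - y} at the top). Boundary handling per step: draw, move,
#' test absorption, reflect, then test absorption once more for walkers
#' reflected across the whole domain (and clamp any still outside).
#'
#' One RNG stream drives the whole run; within each step the magnitude
#' uniforms for all surviving walkers are consumed first, then the sign
#' uniforms, in storage order. Runs are bit-reproducible for a fixed
#' `seed`.
#'
#' @param dist A [velocity_dist()].
#' @param L Domain height, m.
#' @param N Initial platelet count.
#' @param dt_step Update interval \eqn{\Delta t}, s.
#' @param t_end Simulated duration, s.
#' @param seed Optional integer seed (set before placement).
#' @param bottom,top Boundary rules: `"absorb"` or `"reflect"`. Defaults:
#'   absorbing bottom (deposition surface), reflecting top.
#' @param cap Optional maximum speed, m/s, passed to the sampler.
#' @param init_y Optional vector of `N` initial positions in `(0, L)`;
#'   default uniform random placement on `(0, L)`.
#' @param record `"deposition"` (default; cumulative absorbed counts per
#'   step), `"positions"` (full position history, memory heavy), or
#'   `"none"`.
#' @return An object of class `"platelet_walk"`: list with `deposition`
#'   (data frame `t`, `absorbed`, `survivors`), `absorption_times`,
#'   `final_y`, `traj` (a [trajectory_set()] of never-absorbed platelets
#'   when `record = "positions"`, else `NULL`) and `config`.
#' @examples
#' d <- velocity_dist(3.8, 5e-3, 1e-3)
#' w <- simulate_walk(d, L = 5e-5, N = 100, dt_step = 5e-4, t_end = 0.1,
#'                    seed = 1)
#' tail(w$deposition, 1)
#' @export
simulate_walk <- function(dist, L, N, dt_step, t_end, seed = NULL,
                          bottom = c("absorb", "reflect"),
                          top = c("reflect", "absorb"),
                          cap = NULL, init_y = NULL,
                          record = c("deposition", "positions", "none")) {
  stopifnot(inherits(dist, "velocity_dist"))
  bottom <- match.arg(bottom)
  top <- match.arg(top)
  record <- match.arg(record)
  if (L <= 0 || N < 1 || dt_step <= 0 || t_end < dt_step) {
    stop("need L > 0, N >= 1, 0 < dt_step <= t_end")
  }
  if (!is.null(cap) && cap <= 0) stop("'cap' must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init_y)) {
    y <- stats::runif(N, 0, L)
  } else {
    if (length(init_y) != N || any(init_y <= 0 | init_y >= L)) {
      stop("'init_y' must give N positions strictly inside (0, L)")
    }
    y <- as.numeric(init_y)
  }
  n_steps <- round(t_end / dt_step)
  alive <- seq_len(N)
  absorption_times <- rep(NA_real_, N)
  cum_absorbed <- integer(n_steps)
  pos <- NULL
  if (record == "positions") {
    pos <- matrix(NA_real_, nrow = n_steps + 1L, ncol = N)
    pos[1L, ] <- y
  }
  # sampler constants hoisted out of the step loop
  p0 <- dist$p0; lam <- dist$lam; vm <- dist$v_min; a <- dist$alpha
  e <- exp(-lam * vm)
  rc <- p0 / lam * (1 - e)
  tailc <- a / (p0 * vm * e)
  n_absorbed <- 0L
  for (s in seq_len(n_steps)) {
    na <- length(alive)
    if (na > 0L) {
      r <- pmin(stats::runif(na), 1 - 1e-12)
      tl <- r >= rc
      mag <- numeric(na)
      mag[!tl] <- -log1p(-lam * r[!tl] / p0) / lam
      mag[tl] <- vm * (1 - tailc * (r[tl] - rc))^(-1 / a)
      if (!is.null(cap)) {
        over <- which(mag > cap)
        while (length(over) > 0L) {
          r2 <- pmin(stats::runif(length(over)), 1 - 1e-12)
          m2 <- ifelse(r2 >= rc,
                       vm * (1 - tailc * (r2 - rc))^(-1 / a),
                       -log1p(-lam * r2 / p0) / lam)
          mag[over] <- m2
          over <- over[m2 > cap]
        }
      }
      sgn <- ifelse(stats::runif(na) < 0.5, -1, 1)
      y <- y + mag * sgn * dt_step
      gone <- rep(FALSE, na)
      if (bottom == "absorb") gone <- gone | y <= 0
      if (top == "absorb") gone <- gone | y >= L
      if (bottom == "reflect") y[y <= 0] <- -y[y <= 0]
      if (top == "reflect") y[y > L] <- 2 * L - y[y > L]
      # reflected across the whole domain: absorb if the far wall absorbs
      if (bottom == "absorb") gone <- gone | y <= 0
      if (top == "absorb") gone <- gone | y >= L
      y <- pmin(pmax(y, 0), L)  # numerical safety after double reflection
      if (any(gone)) {
        absorption_times[alive[gone]] <- s * dt_step
        n_absorbed <- n_absorbed + sum(gone)
        alive <- alive[!gone]
        y <- y[!gone]
      }
      if (record == "positions" && length(alive) > 0L) {
        pos[s + 1L, alive] <- y
      }
    }
    cum_absorbed[s] <- n_absorbed
  }
  deposition <- data.frame(t = seq_len(n_steps) * dt_step,
                           absorbed = cum_absorbed,
                           survivors = N - cum_absorbed)
  traj <- NULL
  if (record == "positions") {
    survivors <- which(is.na(absorption_times))
    if (length(survivors) > 0L) {
      tt <- (0:n_steps) * dt_step
      traj <- trajectory_set(
        platelet_id = rep(as.character(survivors), each = n_steps + 1L),
        t = rep(tt, times = length(survivors)),
        y = as.numeric(pos[, survivors]),
        dt_sample = dt_step, L = L)
    }
  }
  final_y <- rep(NA_real_, N)
  final_y[alive] <- y
  structure(
    list(deposition = deposition, absorption_times = absorption_times,
         final_y = final_y, traj = traj,
         config = list(L = L, N = N, dt_step = dt_step, t_end = t_end,
                       seed = seed, bottom = bottom, top = top, cap = cap,
                       record = record,
                       dist = dist[c("alpha", "v_min", "v_moy", "p0", "lam")])),
    class = "platelet_walk")
}

#' @export
print.platelet_walk <- function(x, ...) {
  cfg <- x$config
  nd <- utils::tail(x$deposition$absorbed, 1L)
  cat(sprintf(
    "Platelet random walk: N = %d, L = %g m, dt = %g s, t_end = %g s (%s bottom / %s top)\n",
    cfg$N, cfg$L, cfg$dt_step, cfg$t_end, cfg$bottom, cfg$top))
  cat(sprintf("  deposited: %d   surviving: %d\n", nd, cfg$N - nd))
  invisible(x)
}

#' Reference deposition experiment
#'
#' The standard deposition protocol: 4800 platelets uniformly distributed
#' over a gap of 0.82 mm, velocity redrawn every 0.5 ms, absorbing bottom
#' wall (deposition surface) and reflecting top, run for 20 s — the scale
#' of a cone-and-plate platelet-function test. For a uniform initial
#' condition above a single absorbing wall the cumulative deposit of
#' independent diffusing walkers grows as \eqn{\sqrt{t}}; the fitted
#' log-log growth exponent of the cumulative count is returned alongside
#' the curve.
#'
#' @param dist A [velocity_dist()].
#' @param seed Optional integer seed.
#' @param N,L,dt_step,t_end Protocol parameters; defaults are the
#'   reference protocol.
#' @param growth_window Two times (s) over which the growth exponent is
#'   fitted. Default `c(1, t_end)`.
#' @return A `"platelet_walk"` with an extra element `growth_exponent`
#'   (log-log slope of the cumulative absorbed count vs time).
#' @export
deposition_experiment <- function(dist, seed = NULL, N = 4800L,
                                  L = 0.82e-3, dt_step = 0.5e-3,
                                  t_end = 20, growth_window = c(1, t_end)) {
  w <- simulate_walk(dist, L = L, N = N, dt_step = dt_step, t_end = t_end,
                     seed = seed, bottom = "absorb", top = "reflect",
                     record = "deposition")
  dep <- w$deposition
  sel <- dep$t >= growth_window[1L] & dep$t <= growth_window[2L] &
    dep$absorbed > 0
  fit <- stats::lm(log(dep$absorbed[sel]) ~ log(dep$t[sel]))
  w$growth_exponent <- unname(stats::coef(fit)[2L])
  w$growth_window <- growth_window
  w
}

#' Sensitivity of transport to the distribution parameters
#'
#' Re-solves the velocity distribution over a grid of tail exponents and
#' joint scalings of `(v_min, v_moy)`, and for every cell runs (i) the
#' deposition experiment and (ii) an unbounded (reflecting, large-box)
#' walk whose mode-"in" MSD yields a diffusion coefficient. Because the
#' walk steps are independent, scaling both velocity parameters by `k`
#' scales every velocity by `k` and hence `D` by `k^2` exactly in
#' expectation. Cells with `alpha <= 2` have infinite velocity variance
#' (Levy-flight regime) and are flagged; their `D` estimate is
#' cutoff-sensitive and reported as measured.
#'
#' @param alphas Tail exponents to scan (> 1).
#' @param scale_factors Joint multipliers applied to `(v_min, v_moy)`.
#' @param base Named base values `c(v_min = , v_moy = )`, m/s.
#' @param seed Integer seed; each cell uses `seed + cell index`.
#' @param dep_N,dep_t_end Deposition protocol size and duration.
#' @param msd_N,msd_t_end,msd_L Unbounded MSD run: walkers, duration and
#'   box size (large enough that no walker feels the walls).
#' @param dt_step Update interval, s.
#' @param cap Optional speed cap, m/s (recorded in the output); applied
#'   to every cell, mainly relevant for `alpha <= 2`.
#' @return Data frame with one row per cell: `alpha`, `scale`, `D`
#'   (m^2/s), `absorbed_end`, `levy` (logical), `seed`.
#' @export
sensitivity_sweep <- function(alphas, scale_factors,
                              base = c(v_min = 5e-3, v_moy = 1e-3),
                              seed = 1L, dep_N = 4800L, dep_t_end = 20,
                              msd_N = 500L, msd_t_end = 1, msd_L = 1,
                              dt_step = 0.5e-3, cap = NULL) {
  if (any(alphas <= 1)) stop("all 'alphas' must exceed 1")
  if (any(scale_factors <= 0)) stop("all 'scale_factors' must be positive")
  grid <- expand.grid(alpha = alphas, scale = scale_factors,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- grid$alpha[i]; k <- grid$scale[i]
    d <- velocity_dist(a, k * base[["v_min"]], k * base[["v_moy"]])
    cell_seed <- seed + i - 1L
    dep <- simulate_walk(d, L = 0.82e-3, N = dep_N, dt_step = dt_step,
                         t_end = dep_t_end, seed = cell_seed,
                         bottom = "absorb", top = "reflect", cap = cap,
                         record = "deposition")
    wm <- simulate_walk(d, L = msd_L, N = msd_N, dt_step = dt_step,
                        t_end = msd_t_end, seed = cell_seed + 10000L,
                        bottom = "reflect", top = "reflect", cap = cap,
                        init_y = rep(msd_L / 2, msd_N),
                        record = "positions")
    mc <- msd(wm$traj, mode = "in", domain = c(0, msd_L))
    D <- diffusion_coefficient(mc, method = "slope")$D
    rows[[i]] <- data.frame(
      alpha = a, scale = k, D = D,
      absorbed_end = utils::tail(dep$deposition$absorbed, 1L),
      levy = a <= 2, seed = cell_seed)
  }
  do.call(rbind, rows)
}
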