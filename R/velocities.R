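#' Extract finite-difference velocities from trajectories
#'
#' Computes signed wall-normal velocities by forward differences,
#' \eqn{v_i(t) = [y_i(t + s\,\delta t) - y_i(t)] / (s\,\delta t)} with
#' stride \eqn{s}: consecutive samples at `stride = 1`, coarser effective
#' sampling (`stride * dt_sample`) otherwise. Coarsening matters
#' physically: sampling a velocity with short-time memory at intervals
#' much longer than the memory time averages out the fast excursions and
#' suppresses the heavy tail of the magnitude distribution.
#'
#' The last `stride` samples of each record yield no velocity. Records
#' shorter than `stride + 1` samples are dropped.
#'
#' @param traj A [trajectory_set()].
#' @param stride Positive integer subsampling factor. Default 1.
#' @return An object of class `"velocity_ensemble"`: a list with `v` (a
#'   named list of signed velocity vectors, one per record, m/s) and `dt`
#'   (the effective sampling interval `stride * dt_sample`, s).
#' @export
extract_velocities <- function(traj, stride = 1L) {
  stopifnot(inherits(traj, "trajectory_set"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("'stride' must be >= 1")
  validate_trajectory_set(traj)  # rejects non-uniform sampling, names platelet
  dt_eff <- stride * attr(traj, "dt_sample")
  ys <- traj_split(traj)
  ys <- ys[vapply(ys, length, 1L) >= stride + 1L]
  if (length(ys) == 0L) {
    stop("no record has at least stride + 1 samples")
  }
  v <- lapply(ys, function(y) {
    n <- length(y)
    idx <- seq(1L, n - stride, by = stride)
    (y[idx + stride] - y[idx]) / dt_eff
  })
  structure(list(v = v, dt = dt_eff), class = "velocity_ensemble")
}

#' @export
print.velocity_ensemble <- function(x, ...) {
  cat(sprintf(
    "Velocity ensemble: %d record(s), %d velocities, effective dt = %g s\n",
    length(x$v), sum(lengths(x$v)), x$dt))
  invisible(x)
}

#' Mean absolute velocity of an ensemble
#'
#' Double average of the velocity magnitude: first over time within each
#' platelet record, then over records. With records of unequal length this
#' differs from the pooled mean — every platelet carries the same weight.
#'
#' @param ve A `"velocity_ensemble"` (see [extract_velocities()]) or a
#'   plain list of velocity vectors.
#' @return Mean absolute velocity, m/s.
#' @export
mean_abs_velocity <- function(ve) {
  v <- if (inherits(ve, "velocity_ensemble")) ve$v else ve
  if (!is.list(v)) v <- list(v)
  v <- v[lengths(v) > 0L]
  if (length(v) == 0L) stop("no velocities supplied")
  mean(vapply(v, function(x) mean(abs(x)), 0))
}

#' Restrict trajectories to a band away from the walls
#'
#' Wall proximity distorts platelet motion (margination traps platelets in
#' the red-cell-depleted layer), so transport statistics are computed in
#' an interior band `[margin, L - margin]`. Samples outside the band are
#' dropped and each platelet record is split into contiguous in-band
#' segments; every segment becomes an independent record (ids suffixed
#' `.1`, `.2`, ...) so that downstream differences and autocorrelations
#' never straddle an excursion outside the band.
#'
#' @param traj A [trajectory_set()].
#' @param margin Width of the excluded layer at each wall, m. Default
#'   `1e-5` (about one red-blood-cell diameter).
#' @return A `trajectory_set` of in-band segments.
#' @export
exclusion_filter <- function(traj, margin = 1e-5) {
  stopifnot(inherits(traj, "trajectory_set"))
  L <- attr(traj, "L")
  if (2 * margin >= L) stop("exclusion band is empty: 2*margin >= L")
  keep <- traj$y >= margin & traj$y <= L - margin
  if (!any(keep)) stop("no samples inside the band")
  ids <- unique(traj$platelet_id)
  fid <- factor(traj$platelet_id, levels = ids)
  idx_by_id <- split(seq_len(nrow(traj)), fid)
  pieces <- lapply(ids, function(id) {
    idx <- idx_by_id[[id]]
    k <- keep[idx]
    if (!any(k)) return(NULL)
    r <- rle(k)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- which(r$values)
    rows <- unlist(lapply(segs, function(j) idx[starts[j]:ends[j]]),
                   use.names = FALSE)
    lens <- r$lengths[segs]
    list(rows = rows,
         id = rep(paste0(id, ".", seq_along(segs)), times = lens))
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  rows <- unlist(lapply(pieces, `[[`, "rows"), use.names = FALSE)
  trajectory_set(unlist(lapply(pieces, `[[`, "id"), use.names = FALSE),
                 traj$t[rows], traj$y[rows],
                 dt_sample = attr(traj, "dt_sample"), L = L)
}

#' Logarithmically binned empirical density
#'
#' Histogram density on log-spaced bins, the standard way to display a
#' distribution whose bulk is exponential and whose tail is a power law:
#' on log-log axes the bulk bends and the tail is a straight line of slope
#' \eqn{-(1+\alpha)}. Densities are counts divided by the total sample
#' size times the *linear* bin width, so that summing `density * width`
#' over bins gives the fraction of samples inside `range`.
#'
#' @param v Velocity magnitudes, m/s (positive).
#' @param bins_per_decade Bins per factor of 10. Default 8.
#' @param range Two positive numbers, the binned interval. Default
#'   `c(1e-5, 0.3)` m/s.
#' @return Data frame with `center` (geometric bin centre, m/s), `width`
#'   (linear width, m/s), `count` and `density` (s/m). Empty bins have
#'   density 0.
#' @export
log_binned_density <- function(v, bins_per_decade = 8, range = c(1e-5, 0.3)) {
  if (any(range <= 0) || range[2] <= range[1]) {
    stop("'range' must be positive and increasing")
  }
  v <- v[is.finite(v)]
  if (any(v <= 0)) v <- v[v > 0]
  n_total <- length(v)
  if (n_total == 0L) stop("no positive velocities to bin")
  n_bins <- ceiling(log10(range[2] / range[1]) * bins_per_decade)
  edges <- 10^seq(log10(range[1]), log10(range[2]), length.out = n_bins + 1L)
  counts <- graphics::hist(v[v >= range[1] & v <= range[2]],
                           breaks = edges, plot = FALSE)$counts
  width <- diff(edges)
  data.frame(center = sqrt(edges[-length(edges)] * edges[-1L]),
             width = width, count = counts,
             density = counts / (n_total * width))
}

#' Velocity mean and variance profiles along the wall direction
#'
#' Bins the signed stride-1 velocities by the position at which they are
#' measured and reports per-bin mean and variance, masking bins visited by
#' fewer than `min_freq` of all samples. In a plane shear flow the
#' red-cell density is uniform across the gap, so away from the walls both
#' profiles should be flat; deviations localise wall effects. The global
#' mean and variance over the interior band (after [exclusion_filter()]
#' with `margin`) are attached as attributes `global_mean` and
#' `global_var`.
#'
#' @param traj A [trajectory_set()].
#' @param bin_width Position bin width, m. Default `1e-7` (0.1 um).
#' @param min_freq Minimum occupancy fraction for a bin to be reported.
#'   Default `1e-3`.
#' @param margin Band margin used for the global statistics, m.
#' @return Data frame with `y` (bin centre, m), `n`, `mean` (m/s) and
#'   `var` (m^2/s^2), plus the global attributes.
#' @export
wall_profiles <- function(traj, bin_width = 1e-7, min_freq = 1e-3,
                          margin = 1e-5) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (bin_width <= 0) stop("'bin_width' must be > 0")
  dt <- attr(traj, "dt_sample")
  ys <- traj_split(traj)
  ys <- ys[vapply(ys, length, 1L) >= 2L]
  yv <- unlist(lapply(ys, function(y) y[-length(y)]), use.names = FALSE)
  vv <- unlist(lapply(ys, function(y) diff(y) / dt), use.names = FALSE)
  bin <- floor(yv / bin_width)
  n <- tapply(vv, bin, length)
  keep <- n >= min_freq * length(vv)
  m <- tapply(vv, bin, mean)[keep]
  s2 <- tapply(vv, bin, stats::var)[keep]
  centers <- (as.numeric(names(n)[keep]) + 0.5) * bin_width
  out <- data.frame(y = centers, n = as.integer(n[keep]),
                    mean = as.numeric(m), var = as.numeric(s2))
  out <- out[order(out$y), , drop = FALSE]
  L <- attr(traj, "L")
  band <- yv >= margin & yv <= L - margin
  attr(out, "global_mean") <- mean(vv[band])
  attr(out, "global_var") <- stats::var(vv[band])
  out
}
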