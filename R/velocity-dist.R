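#' Exponential-bulk / power-law-tail velocity distribution
#'
#' Constructs the five-parameter probability density used to describe the
#' magnitude of the transverse (wall-normal) velocity of platelets in a
#' sheared red-blood-cell suspension:
#' \deqn{P(v) = p_0 e^{-\lambda v} \quad (v \le v_{min}), \qquad
#'       P(v) = p_0 e^{-\lambda v_{min}} (v/v_{min})^{-1-\alpha} \quad
#'       (v \ge v_{min}).}
#' The bulk decays exponentially up to the threshold `v_min`; beyond it the
#' density follows a power law with tail exponent `alpha` (density
#' proportional to \eqn{v^{-(1+\alpha)}}). Given `alpha`, `v_min` and the
#' mean magnitude `v_moy`, the normalisation constants `p0` and `lam`
#' (\eqn{\lambda}) are determined by requiring unit mass and mean `v_moy`;
#' they are solved numerically by [solve_normalization()] unless supplied.
#'
#' @param alpha Tail exponent (dimensionless, must exceed 1 so the tail mean
#'   is finite; `alpha <= 2` gives infinite variance, the Levy-flight
#'   regime).
#' @param v_min Velocity threshold separating bulk from tail, m/s.
#' @param v_moy Mean velocity magnitude, m/s.
#' @param p0,lam Optional pre-solved normalisation constants (s/m). When
#'   omitted they are computed from the two integral constraints.
#' @return An object of class `"velocity_dist"`: a list with fields
#'   `alpha`, `v_min`, `v_moy`, `p0`, `lam` and the solver residuals.
#' @examples
#' d <- velocity_dist(alpha = 3.8, v_min = 5e-3, v_moy = 1e-3)
#' d$p0   # ~1015.24
#' d$lam  # ~1017.36
#' @seealso [dvel()], [pvel()], [qvel()], [rvel()], [vdist_moment()]
#' @export
velocity_dist <- function(alpha, v_min, v_moy, p0 = NULL, lam = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 1) {
    stop("'alpha' must exceed 1: the power-law tail mean diverges otherwise")
  }
  if (!is.numeric(v_min) || length(v_min) != 1L || v_min <= 0) {
    stop("'v_min' must be a single positive velocity (m/s)")
  }
  if (!is.numeric(v_moy) || length(v_moy) != 1L || v_moy <= 0) {
    stop("'v_moy' must be a single positive velocity (m/s)")
  }
  if (is.null(p0) || is.null(lam)) {
    sol <- solve_normalization(alpha, v_min, v_moy)
    p0 <- sol[["p0"]]
    lam <- sol[["lam"]]
    resid <- attr(sol, "residuals")
  } else {
    if (p0 <= 0 || lam <= 0) stop("'p0' and 'lam' must be positive")
    resid <- vdist_residuals(alpha, v_min, v_moy, p0, lam)
  }
  structure(
    list(alpha = alpha, v_min = v_min, v_moy = v_moy,
         p0 = p0, lam = lam, residuals = resid),
    class = "velocity_dist"
  )
}

# Residuals of the unit-mass and mean constraints, relative scale.
# Mass:  p0 (1 - e^{-lam v_min})/lam + p0 e^{-lam v_min} v_min/alpha = 1
# Mean:  p0/lam^2 + p0 e^{-lam v_min} [v_min^2/(alpha-1) - v_min/lam
#                                      - 1/lam^2] = v_moy
# Both are the exact integrals of the two-branch density.
vdist_residuals <- function(alpha, v_min, v_moy, p0, lam) {
  e <- exp(-lam * v_min)
  mass <- p0 * (1 - e) / lam + p0 * e * v_min / alpha
  mn <- p0 / lam^2 + p0 * e * (v_min^2 / (alpha - 1) - v_min / lam - 1 / lam^2)
  c(mass = mass - 1, mean = mn / v_moy - 1)
}

#' Solve the normalisation constraints of the velocity distribution
#'
#' Determines the constants \eqn{p_0} and \eqn{\lambda} of the
#' exponential/power-law velocity density from the two conditions
#' \eqn{\int_0^\infty P(v)\,dv = 1} and
#' \eqn{\int_0^\infty v\,P(v)\,dv = v_{moy}}.
#'
#' The unit-mass constraint is linear in \eqn{p_0} and is eliminated
#' analytically, leaving a single smooth equation in \eqn{\lambda} that is
#' bracketed around the pure-exponential limit \eqn{\lambda_0 = 1/v_{moy}}
#' and solved with [stats::uniroot()], then polished with Newton steps to a
#' relative residual below `1e-12`. In the limit
#' \eqn{\lambda v_{min} \gg 1} the tail carries no mass and the solution
#' tends to \eqn{p_0 = \lambda = 1/v_{moy}}.
#'
#' @inheritParams velocity_dist
#' @return Named numeric vector `c(p0 = , lam = )` (s/m), with the
#'   constraint residuals attached as attribute `"residuals"`.
#' @examples
#' solve_normalization(3.8, 5e-3, 1e-3)  # p0 = 1015.24, lam = 1017.36
#' @export
solve_normalization <- function(alpha, v_min, v_moy) {
  if (alpha <= 1) stop("'alpha' must exceed 1 for a finite tail mean")
  if (v_min <= 0 || v_moy <= 0) stop("'v_min' and 'v_moy' must be positive")
  # p0 implied by the unit-mass constraint at a given lambda
  p0_of <- function(lam) {
    e <- exp(-lam * v_min)
    1 / ((1 - e) / lam + e * v_min / alpha)
  }
  mean_res <- function(lam) {
    p0 <- p0_of(lam)
    e <- exp(-lam * v_min)
    p0 / lam^2 + p0 * e * (v_min^2 / (alpha - 1) - v_min / lam - 1 / lam^2) -
      v_moy
  }
  lam0 <- 1 / v_moy
  lo <- lam0 / 50
  hi <- lam0 * 50
  root <- tryCatch(
    stats::uniroot(mean_res, lower = lo, upper = hi, extendInt = "yes",
                   tol = .Machine$double.eps^0.75, maxiter = 2000L),
    error = function(e) {
      stop("normalization solve failed to converge: ", conditionMessage(e),
           sprintf(" [residual at lambda=1/v_moy: %.3e]", mean_res(lam0)))
    }
  )
  lam <- root$root
  # Newton polish on the 1-d reduced equation
  for (i in 1:8) {
    f <- mean_res(lam)
    h <- lam * 1e-7
    df <- (mean_res(lam + h) - mean_res(lam - h)) / (2 * h)
    if (!is.finite(df) || df == 0) break
    step <- f / df
    lam_new <- lam - step
    if (!is.finite(lam_new) || lam_new <= 0) break
    lam <- lam_new
    if (abs(step) < 1e-14 * lam) break
  }
  p0 <- p0_of(lam)
  resid <- vdist_residuals(alpha, v_min, v_moy, p0, lam)
  if (max(abs(resid)) > 1e-10) {
    stop(sprintf(
      "normalization solve did not reach tolerance: mass residual %.3e, mean residual %.3e",
      resid[["mass"]], resid[["mean"]]))
  }
  structure(c(p0 = p0, lam = lam), residuals = resid)
}

#' @export
print.velocity_dist <- function(x, ...) {
  cat("Platelet velocity-magnitude distribution (exponential bulk + power-law tail)\n")
  cat(sprintf("  alpha = %g   v_min = %g m/s   v_moy = %g m/s\n",
              x$alpha, x$v_min, x$v_moy))
  cat(sprintf("  p0 = %.6g s/m   lambda = %.6g s/m\n", x$p0, x$lam))
  cat(sprintf("  constraint residuals: mass %.2e, mean %.2e\n",
              x$residuals[["mass"]], x$residuals[["mean"]]))
  if (x$alpha <= 2) {
    cat("  note: alpha <= 2, infinite-variance (Levy-flight) regime\n")
  }
  invisible(x)
}

#' Density, distribution function, quantile function and sampling
#'
#' `dvel`, `pvel` and `qvel` evaluate the density, the cumulative
#' distribution function and its exact inverse for a
#' [velocity_dist()] object; all three are closed-form on both branches.
#' `rvel` draws velocities by inversion: magnitudes via `qvel` applied to
#' uniforms, and (when `signed = TRUE`) an independent sign, +1 or -1 with
#' probability 1/2 each, from a second uniform drawn after the magnitude.
#'
#' @param x,q Vector of velocity magnitudes, m/s (non-negative).
#' @param p Vector of probabilities in `[0, 1)`.
#' @param n Number of draws.
#' @param dist A `"velocity_dist"` object.
#' @param signed Draw a random sign for each magnitude? Default `TRUE`.
#' @param cap Optional maximum speed, m/s: magnitudes above `cap` are
#'   redrawn. Mainly useful in the infinite-variance regime
#'   (`alpha <= 2`); no cap is applied by default.
#' @return `dvel`: densities (s/m). `pvel`: probabilities. `qvel`:
#'   velocities (m/s). `rvel`: `n` signed (or absolute) velocities, m/s.
#' @details Probabilities within `1e-12` of 1 are clamped before inversion
#'   so the power-law bracket stays positive; the affected quantiles are at
#'   the extreme numerical cut-off of the tail and carry negligible mass.
#' @examples
#' d <- velocity_dist(3.8, 5e-3, 1e-3)
#' dvel(0, d)            # equals p0
#' pvel(d$v_min, d)      # bulk mass, ~0.992
#' qvel(pvel(0.002, d), d)
#' mean(abs(rvel(1e4, d)))  # ~ v_moy
#' @export
dvel <- function(x, dist) {
  stopifnot(inherits(dist, "velocity_dist"))
  if (any(x < 0, na.rm = TRUE)) stop("velocity magnitudes must be >= 0")
  ifelse(x <= dist$v_min,
         dist$p0 * exp(-dist$lam * x),
         dist$p0 * exp(-dist$lam * dist$v_min) *
           (x / dist$v_min)^(-1 - dist$alpha))
}

#' @rdname dvel
#' @export
pvel <- function(q, dist) {
  stopifnot(inherits(dist, "velocity_dist"))
  if (any(q < 0, na.rm = TRUE)) stop("velocity magnitudes must be >= 0")
  p0 <- dist$p0; lam <- dist$lam; vm <- dist$v_min; a <- dist$alpha
  e <- exp(-lam * vm)
  rc <- p0 / lam * (1 - e)               # mass of the exponential bulk
  tail_mass <- p0 * e * vm / a
  out <- ifelse(q <= vm,
                p0 / lam * (1 - exp(-lam * q)),
                rc + tail_mass * (1 - (q / vm)^(-a)))
  pmin(out, 1)
}

#' @rdname dvel
#' @export
qvel <- function(p, dist) {
  stopifnot(inherits(dist, "velocity_dist"))
  if (any(p < 0 | p >= 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1)")
  }
  p0 <- dist$p0; lam <- dist$lam; vm <- dist$v_min; a <- dist$alpha
  e <- exp(-lam * vm)
  rc <- p0 / lam * (1 - e)
  p <- pmin(p, 1 - 1e-12)  # clamp: keeps the tail bracket positive
  out <- numeric(length(p))
  bulk <- p < rc
  out[bulk] <- -log1p(-lam * p[bulk] / p0) / lam
  out[!bulk] <- vm * (1 - a * (p[!bulk] - rc) / (p0 * vm * e))^(-1 / a)
  out[is.na(p)] <- NA_real_
  out
}

#' @rdname dvel
#' @export
rvel <- function(n, dist, signed = TRUE, cap = NULL) {
  stopifnot(inherits(dist, "velocity_dist"), n >= 1)
  if (!is.null(cap)) {
    if (!is.numeric(cap) || length(cap) != 1L || cap <= 0) {
      stop("'cap' must be a single positive speed (m/s)")
    }
  }
  mag <- qvel(stats::runif(n), dist)
  if (!is.null(cap)) {
    over <- which(mag > cap)
    it <- 0L
    while (length(over) > 0L && it < 1000L) {
      mag[over] <- qvel(stats::runif(length(over)), dist)
      over <- over[mag[over] > cap]
      it <- it + 1L
    }
    if (length(over) > 0L) mag[over] <- cap
  }
  if (!signed) return(mag)
  sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
  mag * sgn
}

#' Closed-form moments of the velocity-magnitude distribution
#'
#' Raw moments \eqn{\int_0^\infty v^k P(v)\,dv} for k = 0, 1, 2, combining
#' the (incomplete-gamma form) bulk integral and the power-law tail
#' integral. The second moment exists only for `alpha > 2`; together with
#' the walk update interval it gives the analytic diffusion coefficient
#' \eqn{D = \langle v^2\rangle \Delta t / 2} of the independent-step walk.
#'
#' @param dist A `"velocity_dist"` object.
#' @param k Moment order: 0, 1 or 2.
#' @return The raw moment, units \eqn{(m/s)^k}.
#' @examples
#' d <- velocity_dist(3.8, 5e-3, 1e-3)
#' vdist_moment(d, 1)  # = v_moy by construction
#' vdist_moment(d, 2)  # ~2.14e-6 m^2/s^2
#' @export
vdist_moment <- function(dist, k) {
  stopifnot(inherits(dist, "velocity_dist"))
  if (!k %in% c(0, 1, 2)) stop("'k' must be 0, 1 or 2")
  p0 <- dist$p0; lam <- dist$lam; vm <- dist$v_min; a <- dist$alpha
  e <- exp(-lam * vm)
  if (k == 0) {
    bulk <- p0 * (1 - e) / lam
    tail <- p0 * e * vm / a
  } else if (k == 1) {
    bulk <- p0 * (1 - e * (1 + lam * vm)) / lam^2
    tail <- p0 * e * vm^2 / (a - 1)
  } else {
    if (a <= 2) {
      stop("second moment diverges for alpha <= 2 (Levy-flight regime)")
    }
    bulk <- p0 * (2 / lam^3 -
                    e * (vm^2 / lam + 2 * vm / lam^2 + 2 / lam^3))
    tail <- p0 * e * vm^3 / (a - 2)
  }
  bulk + tail
}

#' Read / write velocity-distribution parameter files
#'
#' Flat key/value text files with keys `alpha`, `v_min`, `v_moy` and,
#' once solved, `p0` and `lam` (SI units). `write_vdist` always emits the
#' solved constants and records the constraint residuals as `#` comments;
#' `read_vdist` re-solves the constraints when `p0`/`lam` are absent.
#'
#' @param dist A `"velocity_dist"` object.
#' @param path File path.
#' @return `read_vdist`: a `"velocity_dist"` object. `write_vdist`: the
#'   path, invisibly.
#' @export
write_vdist <- function(dist, path) {
  stopifnot(inherits(dist, "velocity_dist"))
  lines <- c(
    "# velocity-magnitude distribution parameters (SI units)",
    sprintf("# constraint residuals: mass %.3e, mean %.3e",
            dist$residuals[["mass"]], dist$residuals[["mean"]]),
    sprintf("alpha = %.17g", dist$alpha),
    sprintf("v_min = %.17g", dist$v_min),
    sprintf("v_moy = %.17g", dist$v_moy),
    sprintf("p0 = %.17g", dist$p0),
    sprintf("lam = %.17g", dist$lam)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vdist
#' @export
read_vdist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed parameter line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  names(vals) <- keys
  need <- c("alpha", "v_min", "v_moy")
  if (!all(need %in% keys)) {
    stop("parameter file must define: ", paste(need, collapse = ", "))
  }
  velocity_dist(
    alpha = vals[["alpha"]], v_min = vals[["v_min"]], v_moy = vals[["v_moy"]],
    p0 = if ("p0" %in% keys) vals[["p0"]] else NULL,
    lam = if ("lam" %in% keys) vals[["lam"]] else NULL
  )
}
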