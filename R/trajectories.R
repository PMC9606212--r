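#' Platelet trajectory ensemble
#'
#' A `trajectory_set` stores the wall-normal position of each platelet (or
#' trajectory segment) sampled at a uniform interval, together with the
#' domain metadata needed by the analysis: the sampling interval
#' `dt_sample` and the wall-to-wall height `L`.
#'
#' Internally it is a data frame with columns `platelet_id` (character),
#' `t` (s) and `y` (m), carrying `dt_sample` and `L` as attributes. Each
#' `platelet_id` must have strictly increasing, uniformly spaced times
#' (checked to 1e-9 s) and finite positions.
#'
#' @param platelet_id Character or integer labels, one per sample.
#' @param t Sampling times, s.
#' @param y Wall-normal positions, m.
#' @param dt_sample Sampling interval, s.
#' @param L Domain height, m.
#' @return An object of class `c("trajectory_set", "data.frame")`.
#' @export
trajectory_set <- function(platelet_id, t, y, dt_sample, L) {
  stopifnot(length(platelet_id) == length(t), length(t) == length(y))
  if (!is.numeric(dt_sample) || dt_sample <= 0) stop("'dt_sample' must be > 0")
  if (!is.numeric(L) || L <= 0) stop("'L' must be > 0")
  df <- data.frame(platelet_id = as.character(platelet_id),
                   t = as.numeric(t), y = as.numeric(y),
                   stringsAsFactors = FALSE)
  out <- structure(df, dt_sample = dt_sample, L = L,
                   class = c("trajectory_set", "data.frame"))
  validate_trajectory_set(out)
  out
}

validate_trajectory_set <- function(traj, tol = 1e-9) {
  dt <- attr(traj, "dt_sample")
  if (anyNA(traj$y) || any(!is.finite(traj$y))) {
    stop("trajectory positions must be finite")
  }
  ids <- unique(traj$platelet_id)
  tt <- split(traj$t, factor(traj$platelet_id, levels = ids))
  for (id in ids) {
    d <- diff(tt[[id]])
    if (length(d) > 0L && (any(d <= 0) || any(abs(d - dt) > tol))) {
      stop(sprintf(
        "platelet '%s': times must be strictly increasing with constant spacing dt_sample = %g s",
        id, dt))
    }
  }
  invisible(traj)
}

#' @export
print.trajectory_set <- function(x, ...) {
  ids <- unique(x$platelet_id)
  cat(sprintf(
    "Trajectory set: %d platelet record(s), %d samples, dt = %g s, L = %g m\n",
    length(ids), nrow(x), attr(x, "dt_sample"), attr(x, "L")))
  invisible(x)
}

# split y vectors by platelet, preserving first-appearance order
traj_split <- function(traj) {
  ids <- unique(traj$platelet_id)
  split(traj$y, factor(traj$platelet_id, levels = ids))
}

#' Read and write trajectory tables
#'
#' Trajectories are exchanged as UTF-8 tab-separated text with columns
#' `platelet_id`, `t`, `y` (SI units: seconds and metres). Lines starting
#' with `#` are comments; the writer records `dt_sample` and `L` in header
#' comments of the form `# dt_sample = <s>` / `# L = <m>`, which the
#' reader requires. Values round-trip at full double precision.
#'
#' @param traj A [trajectory_set()].
#' @param path File path.
#' @return `read_trajectories`: a `trajectory_set`. `write_trajectories`:
#'   the path, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dt_sample = %.17g", attr(traj, "dt_sample")),
    sprintf("# L = %.17g", attr(traj, "L")),
    "platelet_id\tt\ty"), con)
  utils::write.table(
    data.frame(traj$platelet_id, sprintf("%.17g", traj$t),
               sprintf("%.17g", traj$y)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*=", key), hdr, value = TRUE)
    if (length(m) == 0L) stop("header comment '# ", key, " = ...' missing")
    as.numeric(sub(".*=\\s*", "", m[[1L]]))
  }
  dt_sample <- get_meta("dt_sample")
  L <- get_meta("L")
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body_idx) < 2L) stop("no data rows found")
  header <- strsplit(lines[body_idx[[1L]]], "\t", fixed = TRUE)[[1L]]
  need <- c("platelet_id", "t", "y")
  if (!all(need %in% header)) {
    stop("missing column(s): ", paste(setdiff(need, header), collapse = ", "))
  }
  rows <- strsplit(lines[body_idx[-1L]], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad) > 0L) {
    stop("malformed row(s) at line(s): ",
         paste(body_idx[-1L][utils::head(bad, 5L)], collapse = ", "))
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  tvals <- as.numeric(mat[, "t"])
  yvals <- as.numeric(mat[, "y"])
  if (anyNA(tvals) || anyNA(yvals)) {
    first_bad <- body_idx[-1L][which(is.na(tvals) | is.na(yvals))[1L]]
    stop("non-numeric t/y value at line ", first_bad)
  }
  trajectory_set(mat[, "platelet_id"], tvals, yvals,
                 dt_sample = dt_sample, L = L)
}
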