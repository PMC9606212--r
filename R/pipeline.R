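#' Run the full characterisation pipeline from a configuration file
#'
#' Executes the stages of the platelet-transport characterisation in
#' dependency order: (1) obtain trajectories (from a TSV on disk or the
#' synthetic generator); (2) extract velocities inside the wall-exclusion
#' band and estimate the distribution parameters (mean magnitude, tail
#' threshold and exponent); (3) solve the normalisation constraints;
#' (4) run the deposition experiment with the fitted distribution;
#' (5) estimate MSD-based diffusion coefficients in both censoring modes.
#' Every stage's parameters and seeds are logged in a JSON manifest
#' written next to the outputs, and all output files echo the
#' configuration in `#` comments, so a rerun with the same configuration
#' reproduces identical files.
#'
#' @param config A configuration list, or path to a YAML file with
#'   sections `input`, `fit`, `simulate`, `msd` (all optional except
#'   `input`). `input` needs either `trajectories: <path>` or
#'   `synth: {n_platelets, duration, seed, ...}` entries; `fit` may set
#'   `margin`, `stride`, `min_tail`; `simulate` may set `L`, `N`,
#'   `dt_step`, `t_end`, `seed`; `msd` may set `mode`, `method`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fitted distribution, the tail fit,
#'   the deposition walk, the diffusion estimates and the manifest path.
#' @export
run_pipeline <- function(config, out_dir = tempdir()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$input)) {
    stop("config must be a list (or YAML file) with an 'input' section")
  }
  fit_cfg <- config$fit %||% list()
  sim_cfg <- config$simulate %||% list()
  msd_cfg <- config$msd %||% list()
  if (!is.null(sim_cfg$alpha) && sim_cfg$alpha <= 1) {
    stop("stage 'simulate': alpha must exceed 1")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # -- stage 1: trajectories ------------------------------------------------
  traj <- tryCatch({
    if (!is.null(config$input$trajectories)) {
      read_trajectories(config$input$trajectories)
    } else if (!is.null(config$input$synth)) {
      sy <- config$input$synth
      synth_trajectories(
        dist = velocity_dist(sy$alpha %||% 3.8, sy$v_min %||% 5e-3,
                             sy$v_moy %||% 1e-3),
        n_platelets = sy$n_platelets %||% 200L,
        duration = sy$duration %||% 1,
        memory_time = sy$memory_time %||% 0.5e-3,
        fine_dt = sy$fine_dt %||% 1e-5,
        L = sy$L %||% 50e-6, seed = sy$seed %||% 1L)
    } else {
      stop("input section needs 'trajectories' (path) or 'synth' (list)")
    }
  }, error = function(e) {
    stop("stage 'input' failed: ", conditionMessage(e))
  })

  # -- stage 2: velocity statistics and distribution fit --------------------
  fit_res <- tryCatch({
    banded <- exclusion_filter(traj, margin = fit_cfg$margin %||% 1e-5)
    ve <- extract_velocities(banded, stride = fit_cfg$stride %||% 1L)
    vabs <- abs(unlist(ve$v, use.names = FALSE))
    tf <- fit_tail(vabs, min_tail = fit_cfg$min_tail %||% 50L)
    list(v_moy_hat = mean_abs_velocity(ve), tail = tf, ve = ve)
  }, error = function(e) {
    stop("stage 'fit' failed: ", conditionMessage(e))
  })

  # -- stage 3: normalisation ----------------------------------------------
  dist_hat <- tryCatch(
    velocity_dist(fit_res$tail$alpha_hat, fit_res$tail$v_min_hat,
                  fit_res$v_moy_hat),
    error = function(e) stop("stage 'normalize' failed: ",
                             conditionMessage(e)))
  write_vdist(dist_hat, file.path(out_dir, "fitted_dist.txt"))

  # -- stage 4: deposition -------------------------------------------------
  sim_seed <- sim_cfg$seed %||% 1L
  walk <- tryCatch(
    deposition_experiment(
      dist_hat, seed = sim_seed,
      N = sim_cfg$N %||% 4800L, L = sim_cfg$L %||% 0.82e-3,
      dt_step = sim_cfg$dt_step %||% 0.5e-3,
      t_end = sim_cfg$t_end %||% 20),
    error = function(e) stop("stage 'simulate' failed: ",
                             conditionMessage(e)))
  dep_path <- file.path(out_dir, "deposition.csv")
  write_result_csv(walk$deposition, dep_path, params = c(
    walk$config[c("L", "N", "dt_step", "t_end", "bottom", "top")],
    list(seed = sim_seed, growth_exponent = walk$growth_exponent)))

  # -- stage 5: diffusion --------------------------------------------------
  diff_res <- tryCatch({
    modes <- c("in", "in_and_out")
    margin <- fit_cfg$margin %||% 1e-5
    band <- c(margin, attr(traj, "L") - margin)
    ests <- lapply(modes, function(m) {
      curve <- msd(traj, mode = m, domain = band)
      diffusion_coefficient(curve, method = msd_cfg$method %||% "slope")
    })
    names(ests) <- modes
    ests
  }, error = function(e) stop("stage 'msd' failed: ", conditionMessage(e)))

  manifest <- list(
    package = "plateletwalk",
    version = as.character(utils::packageVersion("plateletwalk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = list(fitted_dist = "fitted_dist.txt",
                   deposition = "deposition.csv",
                   manifest = "manifest.json"),
    results = list(
      v_moy_hat = fit_res$v_moy_hat,
      alpha_hat = fit_res$tail$alpha_hat,
      v_min_hat = fit_res$tail$v_min_hat,
      p0 = dist_hat$p0, lam = dist_hat$lam,
      absorbed_end = utils::tail(walk$deposition$absorbed, 1L),
      growth_exponent = walk$growth_exponent,
      D_in = diff_res[["in"]]$D,
      D_in_and_out = diff_res$in_and_out$D))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(dist = dist_hat, tail_fit = fit_res$tail, walk = walk,
                 diffusion = diff_res, manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# CSV writer with a '#'-prefixed parameter echo (seeds included)
write_result_csv <- function(df, path, params = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(params) > 0L) {
    writeLines(sprintf("# %s = %s", names(params),
                       vapply(params, function(p) paste(format(p),
                                                        collapse = ","), "")),
               con)
  }
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
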