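# End-to-end orchestration: generate (or read) trajectories for a grid of
# state points, compute per-frame observables and hydration statistics,
# fit the temperature sigmoids at a reference pressure, derive the
# classification cutoffs, and assemble the phase map. Outputs are TSV
# tables plus a provenance file; a re-run on the same inputs reproduces
# the tables byte for byte.

#' Pipeline run configuration
#'
#' Either `ensemble` (an [ensemble_spec()], to generate synthetic input) or
#' `trajectories` (a data.frame with columns `pressure`, `temperature`,
#' `path`) plus `topology` (sidecar path) must be provided.
#'
#' @param ensemble Optional [ensemble_spec()].
#' @param trajectories Optional data.frame of per-state-point trajectory
#'   paths.
#' @param topology Topology sidecar path (required with `trajectories`).
#' @param out_dir Output directory.
#' @param window Analysis window passed to [analysis_window()] (default
#'   1/3: the last third of frames).
#' @param hbond An [hbond_criterion()].
#' @param r_philic,r_phobic Hydration-shell radii, nm.
#' @param probe,n_sphere_points SASA settings.
#' @param rg_cutoff,hyd_cutoff Classification cutoffs; `NULL` derives them
#'   from the sigmoid inflection points at the reference pressure.
#' @param alt_rg_cutoff Sensitivity cutoff for the phase map (default 1.1).
#' @param reference_pressure Pressure (MPa) whose temperature series is
#'   fitted; default: the lowest pressure on the grid.
#' @param compute_sasa Logical; SASA is the slowest observable and can be
#'   disabled when only R_G/hydration are needed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(ensemble = NULL, trajectories = NULL, topology = NULL,
                       out_dir = "coilglobule_run", window = 1 / 3,
                       hbond = hbond_criterion(), r_philic = 0.35, r_phobic = 0.55,
                       probe = 0.14, n_sphere_points = 960,
                       rg_cutoff = NULL, hyd_cutoff = NULL, alt_rg_cutoff = 1.1,
                       reference_pressure = NULL, compute_sasa = TRUE) {
  if (is.null(ensemble) && is.null(trajectories)) {
    stop("run_config needs either an ensemble spec or a trajectory table", call. = FALSE)
  }
  if (!is.null(trajectories)) {
    need <- c("pressure", "temperature", "path")
    miss <- setdiff(need, names(trajectories))
    if (length(miss)) stop("trajectory table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
    if (is.null(topology)) stop("a topology sidecar path is required with external trajectories", call. = FALSE)
    bad <- trajectories$path[!file.exists(trajectories$path)]
    if (length(bad)) stop("missing trajectory file(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- list(
    ensemble = ensemble, trajectories = trajectories, topology = topology,
    out_dir = out_dir, window = window, hbond = hbond,
    r_philic = r_philic, r_phobic = r_phobic,
    probe = probe, n_sphere_points = n_sphere_points,
    rg_cutoff = rg_cutoff, hyd_cutoff = hyd_cutoff, alt_rg_cutoff = alt_rg_cutoff,
    reference_pressure = reference_pressure, compute_sasa = compute_sasa
  )
  class(cfg) <- "run_config"
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full coil-to-globule analysis pipeline
#'
#' Stages: (1) generate or locate the per-state-point trajectories;
#' (2) per-frame observables (R_G after unwrapping, SASA, hydrogen-bond
#' counts) and hydration-shell statistics; (3) window averages per state
#' point; (4) sigmoid fits of R_G, SASA and hydration vs temperature at
#' the reference pressure, transition temperature, and inflection-point
#' cutoffs; (5) phase-map assembly with the 1.1 nm sensitivity rerun.
#' Any stage failure is reported with the stage and state point.
#'
#' @param config A [run_config()].
#' @return A result bundle (list): `state_points` (window means per (T,P)),
#'   `fits`, `tc`, `cutoffs`, `phase` (from [build_phase_map()]), and
#'   `paths` of all written tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$ensemble)) {
    sim_dir <- file.path(config$out_dir, "sim")
    manifest <- generate_ensemble(config$ensemble, sim_dir)
    traj <- manifest$files
    top <- read_topology(manifest$topology)
  } else {
    traj <- config$trajectories
    top <- read_topology(config$topology)
  }
  rows <- list()
  paths <- character(0)
  for (i in seq_len(nrow(traj))) {
    p <- traj$pressure[i]
    Tk <- traj$temperature[i]
    tag <- sprintf("P%g_T%g", p, Tk)
    res <- tryCatch(
      .analyse_state_point(traj$path[i], top, config),
      error = function(e) {
        stop(sprintf(
          "pipeline stage 'observables' failed at state point (T = %g K, P = %g MPa): %s",
          Tk, p, conditionMessage(e)
        ), call. = FALSE)
      }
    )
    obs_path <- file.path(config$out_dir, paste0("obs_", tag, ".tsv"))
    hyd_path <- file.path(config$out_dir, paste0("hyd_", tag, ".tsv"))
    .write_tsv(res$obs, obs_path)
    .write_tsv(res$hyd, hyd_path)
    paths <- c(paths, obs_path, hyd_path)
    rows[[i]] <- data.frame(
      pressure = p, temperature = Tk,
      mean_rg = res$means[["R_G"]], sd_rg = res$sds[["R_G"]],
      mean_sasa = res$means[["SASA"]], sd_sasa = res$sds[["SASA"]],
      mean_hydration = res$means[["n_per_residue"]], sd_hydration = res$sds[["n_per_residue"]],
      mean_hb_pp = res$means[["n_hb_pp"]], mean_F = res$means[["F"]],
      n_frames = res$n_window
    )
  }
  state_points <- do.call(rbind, rows)
  sp_path <- file.path(config$out_dir, "state_points.tsv")
  .write_tsv(state_points, sp_path)
  paths <- c(paths, sp_path)

  ref_p <- if (is.null(config$reference_pressure)) min(state_points$pressure) else config$reference_pressure
  ref <- state_points[state_points$pressure == ref_p, ]
  ref <- ref[order(ref$temperature), ]
  fits <- list()
  tc <- NULL
  if (nrow(ref) >= 4L) {
    mk <- function(obs, m, s) {
      temperature_series(obs, ref$temperature, ref[[m]], ref[[s]], pressure = ref_p)
    }
    fits$rg <- tryCatch(fit_sigmoid(mk("R_G", "mean_rg", "sd_rg")), error = function(e) e)
    if (config$compute_sasa) {
      fits$sasa <- tryCatch(fit_sigmoid(mk("SASA", "mean_sasa", "sd_sasa")), error = function(e) e)
    }
    fits$hydration <- tryCatch(fit_sigmoid(mk("hydration", "mean_hydration", "sd_hydration")), error = function(e) e)
    if (inherits(fits$rg, "sigmoid_fit") && inherits(fits$sasa, "sigmoid_fit")) {
      tc <- estimate_tc(fits$rg, fits$sasa)
    }
  }
  rg_cut <- config$rg_cutoff
  if (is.null(rg_cut)) {
    rg_cut <- if (inherits(fits$rg, "sigmoid_fit")) derive_cutoff(fits$rg) else 1.2
  }
  hyd_cut <- config$hyd_cutoff
  if (is.null(hyd_cut)) {
    hyd_cut <- if (inherits(fits$hydration, "sigmoid_fit")) derive_cutoff(fits$hydration) else 12.5
  }
  phase <- NULL
  if (length(unique(state_points$pressure)) >= 2L && length(unique(state_points$temperature)) >= 2L) {
    phase <- build_phase_map(state_points,
      rg_cutoff = rg_cut, hyd_cutoff = hyd_cut,
      alt_rg_cutoff = config$alt_rg_cutoff
    )
    map_path <- file.path(config$out_dir, "phase_map.tsv")
    bnd_path <- file.path(config$out_dir, "phase_boundary.tsv")
    .write_tsv(phase$map[, c("pressure", "temperature", "mean_rg", "mean_hydration", "label", "alt_label")], map_path)
    .write_tsv(phase$boundary, bnd_path)
    paths <- c(paths, map_path, bnd_path)
  }

  fit_path <- file.path(config$out_dir, "fits.txt")
  .write_fit_report(fits, tc, rg_cut, hyd_cut, fit_path)
  prov_path <- file.path(config$out_dir, "provenance.txt")
  .write_provenance(config, prov_path)
  paths <- c(paths, fit_path, prov_path)

  list(
    state_points = state_points, fits = fits, tc = tc,
    cutoffs = c(rg = rg_cut, hydration = hyd_cut),
    phase = phase, paths = paths
  )
}

.analyse_state_point <- function(path, top, config) {
  tr <- read_trajectory(path)
  frames <- tr$frames
  n <- length(frames)
  obs <- vector("list", n)
  hydr <- vector("list", n)
  for (f in seq_len(n)) {
    fr <- unwrap_polymer(frames[[f]], top)
    rg <- radius_of_gyration(fr, top)
    sa <- if (config$compute_sasa) sasa(fr, top, config$probe, config$n_sphere_points) else NA_real_
    hb <- find_hbonds(frames[[f]], top, config$hbond)
    a <- classify_shell(frames[[f]], top, config$r_philic, config$r_phobic)
    obs[[f]] <- data.frame(
      time = frames[[f]]$time, R_G = rg, SASA = sa,
      n_hb_pp = sum(hb$category == "polymer-polymer"),
      n_hb_pw = sum(hb$category == "polymer-water")
    )
    hydr[[f]] <- data.frame(
      time = frames[[f]]$time, n_shell = a$n_shell,
      n_per_residue = a$n_per_residue, n_philic = a$n_philic,
      n_phobic = a$n_phobic,
      F = if (a$n_shell > 0L) a$n_phobic / a$n_shell else NA_real_
    )
  }
  obs <- do.call(rbind, obs)
  hydr <- do.call(rbind, hydr)
  idx <- analysis_window(n, config$window)
  both <- cbind(obs[idx, c("R_G", "SASA", "n_hb_pp")], hydr[idx, c("n_per_residue", "F")])
  means <- vapply(both, function(v) mean(v, na.rm = TRUE), numeric(1))
  sds <- vapply(both, function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  list(obs = obs, hyd = hydr, means = means, sds = sds, n_window = length(idx))
}

.write_fit_report <- function(fits, tc, rg_cut, hyd_cut, path) {
  lines <- character(0)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (inherits(f, "sigmoid_fit")) {
      lines <- c(lines, sprintf(
        "fit %s: T_C %.4f K (se %.4f), width %.4f K, A_coil %.5f, A_glob %.5f, resid_norm %.5g",
        nm, f$T_C, f$se[["T_C"]], f$w, f$A_coil, f$A_glob, f$resid_norm
      ))
    } else {
      lines <- c(lines, sprintf("fit %s: failed (%s)", nm, conditionMessage(f)))
    }
  }
  if (!is.null(tc)) {
    lines <- c(lines, sprintf("transition temperature: %.4f +/- %.4f K", tc$tc, tc$uncertainty))
  }
  lines <- c(lines, sprintf("rg_cutoff: %.5f nm", rg_cut), sprintf("hyd_cutoff: %.5f per residue", hyd_cut))
  writeLines(lines, path)
  invisible(path)
}

.write_provenance <- function(config, path) {
  cfg <- config
  cfg$ensemble <- if (!is.null(cfg$ensemble)) unclass(cfg$ensemble) else NULL
  txt <- deparse(cfg, control = "all")
  tmp <- tempfile()
  writeLines(txt, tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  lines <- c(
    sprintf("package: coilglobule %s", as.character(utils::packageVersion("coilglobule"))),
    sprintf("R: %s", R.version.string),
    sprintf("config_md5: %s", h),
    if (!is.null(config$ensemble)) sprintf("ensemble_seed: %d", config$ensemble$seed),
    "config:", paste0("  ", txt)
  )
  writeLines(lines, path)
  invisible(path)
}
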