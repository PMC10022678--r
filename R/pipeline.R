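#' End-to-end diffusion analysis of a trajectory set
#'
#' Runs the full analysis chain on a set of single-molecule trajectories:
#' duration filtering, MSD fit (whole-set `D_M`, `eps_M`),
#' displacement-mixture fitting with AIC selection of the number of
#' diffusion states, HMM segmentation with that state count, per-state
#' MSD (`D_S`, `eps_S`), occupancies, transition rates and exponential
#' lifetimes, optionally with trajectory-level bootstrap confidence
#' intervals on `D_M`. Everything is deterministic given `seed`.
#'
#' @param ts a [traj_set] (e.g. from [read_trackmate_csv()] or the
#'   simulators).
#' @param seed RNG seed driving every stochastic stage.
#' @param min_frames track-duration filter (positions; default 3).
#' @param N_max largest mixture order for AIC selection.
#' @param n_states HMM state count; default `NULL` uses the AIC choice.
#' @param hmm_restarts Baum-Welch restarts.
#' @param mixture_restarts EM restarts per mixture order in the AIC stage.
#' @param bootstrap_B bootstrap replicates for `D_M` (0 disables).
#' @param out_dir if non-`NULL`, per-stage CSV/JSON outputs are written
#'   there.
#' @return an `spt_report` list with elements `msd`, `msd_fit`,
#'   `selection`, `hmm`, `paths`, `state_summary` (per-state `D_S`,
#'   `eps_S`, `p_S`, `tau`), `transition_rates`, and `bootstrap`.
#' @export
run_analysis <- function(ts, seed = 1, min_frames = 3, N_max = 4,
                         n_states = NULL, hmm_restarts = 5,
                         mixture_restarts = 10, bootstrap_B = 0,
                         out_dir = NULL) {
  stopifnot(inherits(ts, "traj_set"))
  ts <- filter_min_duration(ts, min_frames, quiet = TRUE)
  if (n_tracks(ts) == 0) stopf("no tracks remain after duration filtering")
  curve <- compute_msd(ts)
  mfit <- fit_msd(curve)
  ds <- displacements(ts)
  sel <- select_states(ds, N_max = N_max, seed = seed,
                       n_restarts = mixture_restarts)
  N <- n_states %||% sel$chosen_N
  model <- fit_hmm(ts, N = N, seed = seed + 1L, n_restarts = hmm_restarts)
  paths <- viterbi(ts, model)
  smsd <- state_msd_fit(ts, paths)
  occ <- occupancy(paths)
  lt <- fit_lifetimes(extract_dwells(paths))
  summary_tab <- data.frame(
    state = smsd$state, label = smsd$label,
    D_S = smsd$D_S, eps_S = smsd$eps_S,
    p_S = as.numeric(occ), tau = lt$tau,
    stringsAsFactors = FALSE
  )
  boot <- NULL
  if (bootstrap_B > 0) {
    reps <- bootstrap_trajectories(ts, B = bootstrap_B, seed = seed + 2L)
    dm <- vapply(reps, function(r) fit_msd(compute_msd(r))$D, numeric(1))
    boot <- list(D_M = summarize_bootstrap(dm))
  }
  report <- structure(
    list(n_tracks = n_tracks(ts), n_displacements = nrow(ds$steps),
         dt = ts$dt, msd = curve, msd_fit = mfit, selection = sel,
         hmm = model, paths = paths, state_summary = summary_tab,
         transition_rates = transition_rates(model), bootstrap = boot,
         seed = seed),
    class = "spt_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.spt_report <- function(x, ...) {
  cat(sprintf("Diffusion analysis report (%d tracks, %d displacements, dt = %.4g s)\n",
              x$n_tracks, x$n_displacements, x$dt))
  cat(sprintf("  MSD: D_M = %.4g um^2/s, eps_M = %.4g um\n",
              x$msd_fit$D, x$msd_fit$eps))
  cat(sprintf("  AIC-selected number of diffusion states: %d\n",
              x$selection$chosen_N))
  cat("  per-state summary:\n")
  print(cbind(x$state_summary[, c("label", "D_S", "eps_S", "p_S", "tau")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_msd_csv(report$msd, file.path(out_dir, "msd_curve.csv"))
  utils::write.csv(report$state_summary,
                   file.path(out_dir, "state_summary.csv"), row.names = FALSE)
  utils::write.csv(report$paths$steps, file.path(out_dir, "state_paths.csv"),
                   row.names = FALSE)
  summary <- list(
    n_tracks = report$n_tracks,
    n_displacements = report$n_displacements,
    dt = report$dt,
    D_M = report$msd_fit$D, eps_M = report$msd_fit$eps,
    chosen_N = report$selection$chosen_N,
    aic = report$selection$aic,
    hmm = list(p0 = report$hmm$p0, A = report$hmm$A, D = report$hmm$D,
               logL = report$hmm$logL),
    state_summary = report$state_summary,
    seed = report$seed
  )
  if (!is.null(report$bootstrap))
    summary$bootstrap_D_M <- list(mean = report$bootstrap$D_M$mean,
                                  ci95 = report$bootstrap$D_M$ci95)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Simulate a full field-model dataset
#'
#' Builds the mosaic field, simulates particle trajectories with
#' state-dependent localization error, and (optionally) writes the raster,
#' trajectories and a provenance manifest.
#'
#' @param spec a [field_spec()].
#' @param n_traj,n_frames,burn_in,dt simulation scale.
#' @param seed RNG seed.
#' @param out_dir optional output directory.
#' @return list with `field` (the `field_map`) and `ts` (the noisy
#'   [traj_set] with ground truth states).
#' @export
run_simulation <- function(spec = field_spec(), n_traj = 5000, n_frames = 100,
                           burn_in = 100, dt = 1 / 30, seed = 1,
                           out_dir = NULL) {
  map <- build_field(spec, seed = seed)
  ts <- simulate_particles(map, n_traj = n_traj, n_frames = n_frames,
                           burn_in = burn_in, dt = dt, seed = seed + 1L)
  ts <- add_localization_error(ts, spec$eps_um, seed = seed + 2L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_field_csv(map, file.path(out_dir, "field_raster.csv"))
    write_trajectories(ts, file.path(out_dir, "trajectories.csv"))
    manifest <- c(unclass(spec),
                  list(n_traj = n_traj, n_frames = n_frames,
                       burn_in = burn_in, dt = dt, seed = seed))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(field = map, ts = ts)
}

#' Calibrate field occupancies against a measured report
#'
#' Thin wrapper over [calibrate_field()] that takes targets directly from
#' an `spt_report` (or an equivalent list) and returns the calibrated spec
#' with a side-by-side simulated-vs-target table.
#'
#' @param target either an `spt_report` or a list with `D_M`, `p_S`,
#'   `tau`.
#' @param base_spec a [field_spec()].
#' @param ... passed to [calibrate_field()].
#' @return the `field_calibration`, with an extra `comparison` data frame.
#' @export
run_calibration <- function(target, base_spec, ...) {
  if (inherits(target, "spt_report")) {
    target <- list(D_M = target$msd_fit$D,
                   p_S = target$state_summary$p_S,
                   tau = target$state_summary$tau)
  }
  cal <- calibrate_field(target, base_spec, ...)
  if (!is.null(cal$best_metrics)) {
    cal$comparison <- data.frame(
      quantity = c("D_M", paste0("p_S_", state_labels(3)),
                   paste0("tau_", state_labels(3))),
      target = c(target$D_M %||% NA, target$p_S %||% rep(NA, 3),
                 target$tau %||% rep(NA, 3)),
      simulated = c(cal$best_metrics$D_M, cal$best_metrics$occupancy,
                    cal$best_metrics$lifetimes$tau)
    )
  }
  cal
}

#' Fit both membrane-viscosity models to a size table
#'
#' Fits the Saffman-Delbruck and Stokes-Einstein-like models to the same
#' (radius, diffusion coefficient) observations and reports the residual
#' comparison.
#'
#' @param size_table data frame with `R_m` and `D_um2_s` columns (see
#'   [read_size_table()]).
#' @param const a [membrane_constants()] bundle.
#' @param bootstrap_B bootstrap replicates over rows for a `mu_m` CI
#'   (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return list with `SD` and `SE` `viscosity_fit`s, `preferred` (lower
#'   residual) and optional bootstrap summaries.
#' @export
run_viscosity_fit <- function(size_table, const = membrane_constants(),
                              bootstrap_B = 0, seed = 1) {
  stopifnot(all(c("R_m", "D_um2_s") %in% names(size_table)))
  R <- size_table$R_m; D <- size_table$D_um2_s
  fit_sd <- fit_viscosity(R, D, model = "SD", const = const)
  fit_se <- fit_viscosity(R, D, model = "SE", const = const)
  out <- list(SD = fit_sd, SE = fit_se,
              preferred = if (fit_sd$residual <= fit_se$residual) "SD" else "SE")
  if (bootstrap_B > 0) {
    seeds <- derive_seeds(seed, bootstrap_B)
    mus <- vapply(seeds, function(s) with_seed(s, {
      pick <- sample.int(length(R), length(R), replace = TRUE)
      fit_viscosity(R[pick], D[pick], model = out$preferred, const = const)$mu_m
    }), numeric(1))
    out$bootstrap_mu_m <- summarize_bootstrap(mus)
  }
  out
}

#' Load a YAML run configuration
#'
#' Reads a YAML file describing an analysis or simulation run (input
#' paths, `dt`, pixel size, module parameters, seeds) and validates that
#' only known keys are present.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("input", "out_dir", "dt", "pixel_size_um", "units", "min_frames",
             "N_max", "n_states", "hmm_restarts", "bootstrap_B", "seed",
             "field", "n_traj", "n_frames", "burn_in")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg
}
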