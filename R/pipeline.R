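#' Scale presets for production runs
#'
#' `"paper"` mirrors the reference study conditions (N = 135, L = 3 R0,
#' 5e7 steps, 16 replicates) and is provided for completeness: it is
#' cluster-scale.  `"desk"` keeps N = 135 for crowder-free runs but uses a
#' reduced chain (N = 40) and a shorter box (L = 1.5 R0) for crowded runs,
#' 2e6 steps and 4 replicates, sized so the organizational phenomenology is
#' reproducible interactively on one CPU.
#'
#' @param preset `"desk"` or `"paper"`.
#' @return A list of run-scale parameters.
#' @export
scale_preset <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper")
    list(name = "paper", n_monomers_free = 135L, n_monomers_crowded = 135L,
         l_over_r0_free = 3, l_over_r0_crowded = 3,
         n_steps = 5e7, sample_stride = 1000L, replicates = 16L)
  else
    list(name = "desk", n_monomers_free = 135L, n_monomers_crowded = 40L,
         l_over_r0_free = 3, l_over_r0_crowded = 1.5,
         n_steps = 2e6, sample_stride = 1000L, replicates = 4L)
}

#' Sweep specification over (phi_c, eps13)
#'
#' @param phi_c_values crowder volume fractions (reference grid: 0 to 0.35).
#' @param eps13_values monomer-wall strengths (reference grid: 1, 1.5, ... 3).
#' @param replicates independent replicates per cell.
#' @param n_steps steps per replicate.
#' @param sample_stride steps between recorded frames.
#' @param preset scale preset name used for chain/box sizing rules.
#' @param seed base seed.
#' @export
sweep_spec <- function(phi_c_values = seq(0, 0.35, by = 0.05),
                       eps13_values = seq(1, 3, by = 0.5),
                       replicates = NULL, n_steps = NULL,
                       sample_stride = NULL, preset = "desk", seed = 1L) {
  stopifnot(length(phi_c_values) >= 1, length(eps13_values) >= 1)
  ps <- scale_preset(preset)
  out <- structure(list(
    phi_c_values = phi_c_values,
    eps13_values = eps13_values,
    replicates = as.integer(replicates %||% ps$replicates),
    n_steps = n_steps %||% ps$n_steps,
    sample_stride = as.integer(sample_stride %||% ps$sample_stride),
    preset = ps,
    seed = as.integer(seed)), class = "sweep_spec")
  stopifnot(out$replicates >= 1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spec for one sweep cell under the preset's sizing rules.
cell_spec <- function(sw, phi_c, eps13, seed) {
  ps <- sw$preset
  crowded <- phi_c > 0
  n <- if (crowded) ps$n_monomers_crowded else ps$n_monomers_free
  r0 <- suppressWarnings(r0_lookup(n, 5))
  lor <- if (crowded) ps$l_over_r0_crowded else ps$l_over_r0_free
  system_spec(n_monomers = n, phi_c = phi_c, eps13 = eps13,
              geometry = cylinder_geometry(5, lor * r0), seed = seed)
}

#' Run a single experiment and write its bundle
#'
#' Builds the system, integrates, and writes the run bundle into `out_dir`:
#' the echoed configuration (`config.yaml`), per-frame observables
#' (`observables.csv`), the run summary (`summary.json`), the trajectory
#' (`trajectory.xyz`, unless `write_traj = FALSE`) and a short log.
#' Rerunning with the same spec and seed reproduces the observable tables
#' byte-identically.
#'
#' @param spec a [system_spec()].
#' @param out_dir output directory (created if missing).
#' @param n_steps,sample_stride integration scale.
#' @param discard_fraction equilibration fraction dropped in the summary.
#' @param write_traj write the extended-XYZ trajectory (default TRUE).
#' @return Invisibly, a list with the trajectory, observables and summary.
#' @export
run_experiment <- function(spec, out_dir, n_steps = 2e6, sample_stride = 1000,
                           discard_fraction = 0.2, write_traj = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("run started %s\n", format(Sys.time())), file = logf)
  write_config(spec, file.path(out_dir, "config.yaml"))
  sys <- build_system(spec)
  logline("built system: %d monomers, %d crowders",
          spec$n_monomers, sum(sys$state$species == 2L))
  traj <- tryCatch(
    integrate_dynamics(sys$state, spec, n_steps = n_steps,
                       sample_stride = sample_stride, seed = spec$seed),
    error = function(e) {
      logline("integration failure: %s", conditionMessage(e))
      partial <- e$partial
      if (!is.null(partial) && write_traj && length(partial$frames))
        write_trajectory(partial, file.path(out_dir, "trajectory_partial.xyz"))
      stop(e)
    })
  obs <- frame_observables(traj, sys$topology, spec$geometry)
  utils::write.csv(format(obs, digits = 10, trim = TRUE, scientific = FALSE),
                   file.path(out_dir, "observables.csv"), row.names = FALSE,
                   quote = FALSE)
  summ <- summarize_run(traj, discard_fraction = discard_fraction)
  write_summary_json(summ, file.path(out_dir, "summary.json"),
                     extra = list(seed = spec$seed, n_steps = n_steps,
                                  sample_stride = sample_stride,
                                  discard_fraction = discard_fraction,
                                  state = classify_state(summ),
                                  config = spec_to_list(spec)))
  if (write_traj) write_trajectory(traj, file.path(out_dir, "trajectory.xyz"))
  logline("finished: R = %.3f, <r^2> = %.3f, <rL.rR> = %.3f",
          summ$R, summ$mean_sq_r, summ$arm_corr)
  invisible(list(trajectory = traj, observables = obs, summary = summ,
                 topology = sys$topology))
}

#' Run a (phi_c, eps13) sweep with replicate ensembles
#'
#' For every grid cell, runs `replicates` independent replicates (seeds
#' `seed + replicate - 1` within the cell), ensemble-averages them, and
#' classifies the organization state.  Each completed cell's summary is
#' written under `out_dir`; cells whose summary already exists are skipped,
#' so an interrupted sweep resumes where it stopped and yields the same
#' table as an uninterrupted run.  Per-cell failures are recorded and the
#' sweep continues.
#'
#' @param sweep a [sweep_spec()].
#' @param out_dir output directory.
#' @return A `phase_table` data.frame, one row per cell: observable means,
#'   standard errors, and the state label.
#' @export
run_sweep <- function(sweep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(phi_c = sweep$phi_c_values, eps13 = sweep$eps13_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    phi_c <- grid$phi_c[g]; eps13 <- grid$eps13[g]
    tag <- sprintf("phi%0.3f_eps%0.2f", phi_c, eps13)
    cell_file <- file.path(out_dir, paste0("cell_", tag, ".json"))
    if (file.exists(cell_file)) {
      rows[[g]] <- as.data.frame(jsonlite::read_json(cell_file,
                                                     simplifyVector = TRUE))
      next
    }
    cell_seed <- sweep$seed + 1000L * (g - 1L)
    res <- tryCatch({
      summaries <- lapply(seq_len(sweep$replicates), function(k) {
        spec <- cell_spec(sweep, phi_c, eps13, seed = cell_seed + k - 1L)
        sys <- build_system(spec)
        traj <- integrate_dynamics(sys$state, spec, n_steps = sweep$n_steps,
                                   sample_stride = sweep$sample_stride,
                                   seed = spec$seed)
        summarize_run(traj)
      })
      ens <- ensemble_average(summaries, discard_fraction = 0.2)
      data.frame(phi_c = phi_c, eps13 = eps13,
                 R = ens$R, R_over_R0 = ens$R_over_R0,
                 mean_sq_r = ens$mean_sq_r, arm_corr = ens$arm_corr,
                 se_R = ens$se[["R"]], se_mean_sq_r = ens$se[["mean_sq_r"]],
                 se_arm_corr = ens$se[["arm_corr"]],
                 replicates = ens$replicates,
                 state = classify_state(ens), error = NA_character_)
    }, error = function(e)
      data.frame(phi_c = phi_c, eps13 = eps13, R = NA_real_,
                 R_over_R0 = NA_real_, mean_sq_r = NA_real_,
                 arm_corr = NA_real_, se_R = NA_real_,
                 se_mean_sq_r = NA_real_, se_arm_corr = NA_real_,
                 replicates = 0L, state = NA_character_,
                 error = conditionMessage(e)))
    if (is.na(res$error[1]))
      jsonlite::write_json(res, cell_file, auto_unbox = FALSE, digits = NA,
                           dataframe = "columns")
    rows[[g]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("phase_table", "data.frame")
  utils::write.csv(out, file.path(out_dir, "phase_table.csv"), row.names = FALSE)
  out
}

#' Ring polymer in a closed (capped) cylinder without crowders
#'
#' Runs the crowder-free experiment in a cylinder of finite length `L =
#' L_over_R0 * R0(N, D)` closed by repulsive caps, and reports the projected
#' transverse density profile together with the two-peak (bimodality)
#' indicator.  Narrow cylinders (D = 3a) with `L/R0` around 60% or more
#' compress the ring into an arm-separated, bimodal transverse distribution;
#' wider cylinders keep a single central peak.
#'
#' @param d cylinder diameter, in a.
#' @param l_over_r0 cylinder length as a fraction of the relaxed chain size.
#' @param n ring length N (default 135).
#' @param out_dir optional output directory for the profile CSV and summary.
#' @param n_steps,sample_stride,replicates,seed run scale.
#' @param n_bins histogram bins for the profile.
#' @return A list: `profile` (a `transverse_profile`), `bimodal` (logical),
#'   `summary` (ensemble [run_summary]), `r0` used.
#' @export
capped_cylinder_experiment <- function(d, l_over_r0, n = 135, out_dir = NULL,
                                       n_steps = 5e5, sample_stride = 1000,
                                       replicates = 2, seed = 1, n_bins = 41) {
  r0 <- suppressWarnings(r0_lookup(n, d))
  geo <- cylinder_geometry(d, l_over_r0 * r0, mode = "capped")
  frames <- list(); summaries <- list()
  for (k in seq_len(replicates)) {
    spec <- system_spec(n_monomers = n, phi_c = 0, geometry = geo,
                        seed = seed + k - 1L)
    sys <- build_system(spec)
    traj <- integrate_dynamics(sys$state, spec, n_steps = n_steps,
                               sample_stride = sample_stride, seed = spec$seed)
    keep <- keep_frames(length(traj$frames), 0.2)
    frames <- c(frames, traj$frames[keep])
    obs <- frame_observables(traj, sys$topology, geo, discard_fraction = 0.2)
    summaries[[k]] <- summarize_run(obs, discard_fraction = 0, r0 = r0)
  }
  prof <- projected_profile(frames, n_bins = n_bins, geometry = geo)
  res <- list(profile = prof, bimodal = is_bimodal(prof),
              summary = ensemble_average(summaries, discard_fraction = 0.2),
              r0 = r0, d = d, l_over_r0 = l_over_r0, n = n)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(prof)[, c("center", "density")],
                     file.path(out_dir, "profile.csv"), row.names = FALSE)
    jsonlite::write_json(list(d = d, l_over_r0 = l_over_r0, n = n, r0 = r0,
                              bimodal = res$bimodal),
                         file.path(out_dir, "capped_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
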