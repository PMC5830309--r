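#' Run a transient scenario
#'
#' Time-marches a validated scenario from rest at `t = 0` to
#' `solver$t_end`, capturing solution snapshots at the requested times,
#' radial probe traces of `u_z(r)` and `T(r)` at the configured axial
#' stations, and a per-step trace of the inlet pressure and flow rate.
#' When the scenario's `outputs$outdir` is set, VTK snapshots, the probe
#' CSV and a run log (with the resolved-configuration hash) are written
#' there.
#'
#' @param scn A `steno_scenario` from [scenario()], [preset()] or
#'   [load_scenario()].
#' @param quiet Suppress per-step convergence warnings.
#' @param max_steps Optional cap on the number of time steps (smoke runs).
#' @return An object of class `steno_run`: list with `scenario`, `mesh`,
#'   `snapshots` (states at the snapshot times, in order), `probes` (data
#'   frame), `trace` (data frame `t`, `p_in`, `Q`), and `final` state.
#' @export
run_simulation <- function(scn, quiet = FALSE, max_steps = NULL) {
  stopifnot(inherits(scn, "steno_scenario"))
  mesh <- build_mesh(scn$geometry, scn$mesh$nz, scn$mesh$nr)
  props <- scn$fluid; mag <- scn$magnetics; pp <- scn$pressure
  cfg <- scn$solver
  outdir <- scn$outputs$outdir
  log_lines <- character(0)
  logit <- function(...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  logit("run '%s' start: mesh %dx%d, config hash %s", scn$name,
        mesh$nz, mesh$nr, scenario_hash(scn))

  state <- init_state(mesh, props, pp, cfg)
  snap_times <- sort(unique(scn$outputs$snapshot_times))
  stations <- scn$outputs$probe_stations
  snapshots <- list()
  probes <- list()
  trace <- list()

  capture <- function(state) {
    snapshots[[length(snapshots) + 1]] <<- state
    for (zs in stations)
      probes[[length(probes) + 1]] <<- extract_probe(state, mesh, zs)
  }

  nsteps <- ceiling(cfg$t_end / cfg$dt - 1e-9)
  if (!is.null(max_steps)) nsteps <- min(nsteps, max_steps)
  pending <- snap_times
  if (length(pending) && pending[1] <= cfg$dt / 2) {
    capture(state)
    pending <- pending[-1]
  }
  for (k in seq_len(nsteps)) {
    state <- advance(state, mesh, props, mag, pp, cfg, quiet = quiet)
    res <- attr(state, "residuals")
    logit("step %d t=%.4f: %d outer iterations, mass residual %.3e",
          k, state$t, length(res), utils::tail(res, 1))
    trace[[k]] <- data.frame(t = state$t,
                             p_in = inlet_pressure(state$t, pp),
                             Q = flow_rate(state, mesh, 1, props$rho))
    while (length(pending) && state$t >= pending[1] - cfg$dt / 2) {
      capture(state)
      pending <- pending[-1]
    }
  }
  probes <- do.call(rbind, probes)
  trace <- do.call(rbind, trace)
  logit("run '%s' finished at t=%.4f with %d snapshots", scn$name,
        state$t, length(snapshots))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (s in seq_along(snapshots))
      write_snapshot(snapshots[[s]], mesh,
                     file.path(outdir, sprintf("%s_snap%02d.vtk",
                                               scn$name, s)))
    if (!is.null(probes))
      write_probes(probes, file.path(outdir,
                                     sprintf("%s_probes.csv", scn$name)))
    writeLines(log_lines, file.path(outdir,
                                    sprintf("%s_run.log", scn$name)))
  }
  structure(list(scenario = scn, mesh = mesh, snapshots = snapshots,
                 probes = probes, trace = trace, final = state,
                 log = log_lines),
            class = "steno_run")
}

#' @export
print.steno_run <- function(x, ...) {
  cat(sprintf(
    "steno_run '%s': t end %.3g s, %d snapshots, peak |u_z| %.4g m/s, T range [%.2f, %.2f] K\n",
    x$scenario$name, x$final$t, length(x$snapshots),
    max(abs(x$final$u_z)), min(x$final$T), max(x$final$T)))
  invisible(x)
}
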