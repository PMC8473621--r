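#' Full simulation configuration
#'
#' Bundles every run parameter: geometry, rheology, flow, injection and
#' adhesion settings, grid resolution, seeds and the post-fill scenario.
#' All defaults are the published filling conditions.
#'
#' @param scaffold a [scaffold_spec()].
#' @param defect a [defect_spec()].
#' @param rheo a [marrow_rheology()].
#' @param flow a [flow_config()].
#' @param schedule an [injection_schedule()]; its `post_fill_mode` is the
#'   scenario switch.
#' @param adhesion an [adhesion_config()].
#' @param nr,nz grid resolution of the axisymmetric section.
#' @param seeds integer seed(s); one particle ensemble is run per seed over
#'   a single shared flow solution.
#' @param cell_diameter,cell_density,cell_surface_tension particle phase
#'   properties (m, kg/m^3, N/m).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(scaffold = scaffold_spec(),
                              defect = defect_spec(),
                              rheo = marrow_rheology(),
                              flow = flow_config(),
                              schedule = injection_schedule(),
                              adhesion = adhesion_config(),
                              nr = 64, nz = 96, seeds = 1L,
                              cell_diameter = 25e-6, cell_density = 1000,
                              cell_surface_tension = 0.03) {
  structure(list(scaffold = scaffold, defect = defect, rheo = rheo,
                 flow = flow, schedule = schedule, adhesion = adhesion,
                 nr = nr, nz = nz, seeds = as.integer(seeds),
                 cell_diameter = cell_diameter, cell_density = cell_density,
                 cell_surface_tension = cell_surface_tension),
            class = "simulation_config")
}

#' @keywords internal
save_rng <- function() {
  if (!exists(".Random.seed", envir = globalenv())) runif(1)
  get(".Random.seed", envir = globalenv())
}
#' @keywords internal
restore_rng <- function(s) assign(".Random.seed", s, envir = globalenv())

#' Run the coupled filling + cell-attachment simulation
#'
#' Orchestrates geometry, flow, transport and adhesion: the axisymmetric
#' two-phase filling flow is stepped with adaptive CFL dt; each seed's
#' particle ensemble is injected from the inlet faces, advected with drag,
#' and its impingements on the scaffold rings and defect walls are
#' classified and ledgered.  The flow is deterministic, so all ensembles
#' share one flow solution.  Marrow inflow acts during the fill window only;
#' after it, `continued_injection` keeps releasing cells from the boundary
#' faces while `no_injection` stops (the two working conditions).
#'
#' @param config a [simulation_config()].
#' @param scenarios post-fill scenario(s) to run; defaults to the
#'   schedule's `post_fill_mode`.  Because marrow inflow acts only during
#'   the fill window, the flow is identical across scenarios and one flow
#'   solution carries every (scenario, seed) ensemble.
#' @param output_dir optional directory for CSV/VTK outputs and the run
#'   manifest.
#' @param record_series record flow diagnostics per step?
#' @param progress_every print a progress line every so many steps (0 = quiet).
#' @return object of class `simulation_result`: the domain, final flow
#'   state, per-seed ensembles (`cells`, `ledger`, `counts`, attached-mass
#'   time series) and the run `manifest`.
#' @export
run_simulation <- function(config = simulation_config(),
                           scenarios = config$schedule$post_fill_mode,
                           output_dir = NULL, record_series = FALSE,
                           progress_every = 0) {
  stopifnot(inherits(config, "simulation_config"))
  t_start <- Sys.time()
  domain <- build_flow_section(config$scaffold, config$defect,
                               nr = config$nr, nz = config$nz)
  fc <- config$flow
  state <- initialize_flow(domain, fc)
  grid <- expand.grid(seed = config$seeds, scenario = scenarios,
                      stringsAsFactors = FALSE)
  ns <- nrow(grid)
  ens <- vector("list", ns)
  for (s in seq_len(ns)) {
    set.seed(grid$seed[s])
    sched <- config$schedule
    sched$post_fill_mode <- grid$scenario[s]
    ens[[s]] <- list(
      cells = cell_phase(capacity = max(1000L, config$schedule$n_cells * 3L),
                         diameter = config$cell_diameter,
                         density = config$cell_density,
                         surface_tension = config$cell_surface_tension),
      schedule = sched,
      ledger = list(), nled = 0L, rng = save_rng(),
      series = list())
  }
  flow_series <- if (record_series) list() else NULL
  step <- 0L
  next_report <- ceiling(fc$fill_duration + 0.5)
  while (state$time < fc$total_duration - 1e-12) {
    inflow <- state$time < fc$fill_duration - 1e-12
    dt <- if (is.na(fc$dt)) next_dt(state, domain, fc, inflow) else fc$dt
    for (ev in c(fc$fill_duration, fc$total_duration,
                 seq_len(ceiling(fc$total_duration))))
      if (state$time < ev - 1e-12) dt <- min(dt, ev - state$time)
    t0 <- state$time
    state <- flow_step(state, domain, config$rheo, fc, dt, inflow = inflow)
    t1 <- state$time
    attach_active <- t0 >= fc$fill_duration - 1e-9
    fields <- mixture_fields(state, domain, config$rheo, fc)
    for (s in seq_len(ns)) {
      e <- ens[[s]]
      restore_rng(e$rng)
      injecting <- inflow || e$schedule$post_fill_mode == "continued_injection"
      if (injecting)
        inject(e$cells, e$schedule, domain, t0, t1, fc$inlet_speed)
      moved <- advance_cells(e$cells, state, domain, config$rheo, fc, dt,
                             fields = fields)
      events <- detect_impingement(e$cells, moved, domain)
      rec <- resolve_impingements(e$cells, moved, events, config$adhesion,
                                  domain, t1, attach_active,
                                  inflow_active = inflow)
      if (nrow(rec)) {
        e$nled <- e$nled + 1L
        e$ledger[[e$nled]] <- rec
      }
      e$rng <- save_rng()
      ens[[s]] <- e
    }
    if (t1 + 1e-9 >= next_report && next_report <= fc$total_duration) {
      for (s in seq_len(ns)) {
        led <- if (ens[[s]]$nled) do.call(rbind, ens[[s]]$ledger) else
          attachment_record()
        ens[[s]]$series[[length(ens[[s]]$series) + 1L]] <-
          data.frame(time = next_report,
                     scaffold_mass = sum(led$mass[led$surface == "scaffold"]),
                     wall_mass = sum(led$mass[led$surface == "wall"]))
      }
      next_report <- next_report + 1
    }
    if (record_series)
      flow_series[[length(flow_series) + 1L]] <-
        data.frame(time = t1, dt = dt, volume = marrow_volume(state, domain),
                   injected = state$injected_volume,
                   outflow = state$outflow_marrow, max_div = state$max_div,
                   u_max = state$u_max)
    step <- step + 1L
    if (progress_every > 0 && step %% progress_every == 0)
      message(sprintf("t = %.4f s (step %d, dt = %.2e, umax = %.3g)",
                      t1, step, dt, state$u_max))
  }
  results <- lapply(seq_len(ns), function(s) {
    e <- ens[[s]]
    led <- if (e$nled) do.call(rbind, e$ledger) else attachment_record()
    n <- e$cells$n
    list(seed = grid$seed[s], scenario = grid$scenario[s],
         cells = data.frame(id = seq_len(n), x = e$cells$x[seq_len(n)],
                            z = e$cells$z[seq_len(n)],
                            status = c("suspended", "stuck", "spread",
                                       "escaped")[e$cells$status[seq_len(n)] + 1L]),
         ledger = led, counts = cell_counts(e$cells),
         injected_total = e$cells$injected_total,
         injected_window = e$cells$injected_window,
         series = if (length(e$series)) do.call(rbind, e$series) else NULL)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("osteoseed")),
    seeds = config$seeds, nr = config$nr, nz = config$nz,
    scenario = paste(scenarios, collapse = ","),
    n_cells = config$schedule$n_cells,
    inlet_speed = fc$inlet_speed, fill_duration = fc$fill_duration,
    total_duration = fc$total_duration, steps = step,
    wall_clock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  out <- structure(list(domain = domain, state = state, ensembles = results,
                        flow_series = if (record_series)
                          do.call(rbind, flow_series) else NULL,
                        manifest = manifest),
                   class = "simulation_result")
  if (!is.null(output_dir)) write_simulation_outputs(out, output_dir)
  out
}

#' Write simulation outputs (CSV, VTK, manifest) to a directory
#'
#' @param result a `simulation_result`.
#' @param output_dir destination directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_simulation_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (e in result$ensembles) {
    tag <- sprintf("seed%d_%s", e$seed, e$scenario)
    p1 <- file.path(output_dir, sprintf("particles_%s.csv", tag))
    utils::write.csv(e$cells, p1, row.names = FALSE)
    p2 <- file.path(output_dir, sprintf("ledger_%s.csv", tag))
    utils::write.csv(e$ledger, p2, row.names = FALSE)
    for (part in c("radial5", "rows", "boundary")) {
      p3 <- file.path(output_dir,
                      sprintf("regions_%s_%s.csv", part, tag))
      utils::write.csv(region_density(e$ledger, result$domain, part), p3,
                       row.names = FALSE)
      paths <- c(paths, p3)
    }
    paths <- c(paths, p1, p2)
  }
  pf <- file.path(output_dir, "fields.vtk")
  write_vtk_fields(result$state, result$domain, pf)
  pm <- file.path(output_dir, "manifest.json")
  writeLines(manifest_json(result$manifest), pm)
  invisible(c(paths, pf, pm))
}

#' @keywords internal
manifest_json <- function(m) {
  enc <- function(x) {
    if (is.character(x)) paste0("\"", x, "\"") else format(x, digits = 15)
  }
  items <- vapply(names(m), function(k) {
    v <- m[[k]]
    val <- if (length(v) > 1)
      paste0("[", paste(vapply(v, enc, ""), collapse = ", "), "]")
    else enc(v)
    paste0("  \"", k, "\": ", val)
  }, "")
  c("{", paste(items, collapse = ",\n"), "}")
}
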