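#' Flow configuration for the marrow filling simulation
#'
#' Defaults follow the filling protocol: marrow driven in at 1 mm/s from the
#' lateral and bottom defect surfaces for 2.5 s, with the run continuing to
#' 5 s; air initially fills the void and leaves through the annular outlet.
#'
#' @param inlet_speed marrow inflow speed (m/s).
#' @param fill_duration inflow window (s).
#' @param total_duration simulated time (s).
#' @param dt fixed time step (s) or `NA` for adaptive CFL stepping.
#' @param dt_max cap on the adaptive step (s).
#' @param gravity gravitational acceleration along z (m/s^2, negative down).
#' @param air_density,air_viscosity air properties (kg/m^3, Pa s).
#' @param cfl_limit Courant number for adaptive stepping, < 1.
#' @param divergence_tol post-projection divergence tolerance, expressed as a
#'   fraction of the characteristic rate `u_char / min(dr, dz)`.
#' @param u_char characteristic speed for tolerance scaling (defaults to
#'   `inlet_speed` or 1 if that is 0).
#' @param max_cg_iters iteration cap for the inner conjugate-gradient solves.
#' @return object of class `flow_config`.
#' @export
flow_config <- function(inlet_speed = 1e-3, fill_duration = 2.5,
                        total_duration = 5.0, dt = NA, dt_max = 5e-3,
                        gravity = -9.81, air_density = 1.2,
                        air_viscosity = 1.8e-5, cfl_limit = 0.4,
                        divergence_tol = 1e-8,
                        u_char = if (inlet_speed > 0) inlet_speed else 1,
                        max_cg_iters = 4000) {
  stopifnot(fill_duration <= total_duration, cfl_limit > 0, cfl_limit < 1,
            air_density > 0, air_viscosity > 0, divergence_tol > 0)
  if (!is.na(dt)) stopifnot(dt > 0)
  structure(list(inlet_speed = inlet_speed, fill_duration = fill_duration,
                 total_duration = total_duration, dt = dt, dt_max = dt_max,
                 gravity = gravity, air_density = air_density,
                 air_viscosity = air_viscosity, cfl_limit = cfl_limit,
                 divergence_tol = divergence_tol, u_char = u_char,
                 max_cg_iters = max_cg_iters),
            class = "flow_config")
}

#' Physical-parameter bundle passed to the compiled kernels
#' @keywords internal
flow_phys <- function(rheo, config, newtonian = FALSE) {
  list(rho_m = rheo$rho, rho_a = config$air_density,
       mu_a = config$air_viscosity, k = rheo$k, n = if (newtonian) 1 else rheo$n,
       eta_min = rheo$eta_min, eta_max = rheo$eta_max,
       clamp = !newtonian, g_z = config$gravity)
}

#' Initialise the two-phase flow state
#'
#' All void cells start air-filled (marrow fraction 0) at rest at time 0.
#' A domain that has marrow inlets but no outlet is a sealed cavity and is
#' refused: the displaced air would have nowhere to go.
#'
#' @param domain a `flow_domain`.
#' @param config a [flow_config()].
#' @return object of class `flow_state` with staggered velocities `u`
#'   (radial) and `w` (vertical), cell fields `p` and `alpha`, time, and
#'   volume bookkeeping.
#' @export
initialize_flow <- function(domain, config = flow_config()) {
  stopifnot(inherits(domain, "flow_domain"))
  g <- domain$geom
  n_inlet <- sum(g$fx == 2L) + sum(g$fz == 2L)
  if (all(g$ctype != 0L)) stop("domain contains no fluid cells")
  if (n_inlet > 0 && domain$n_outlet_faces == 0 && config$inlet_speed > 0)
    stop("sealed domain: inlets present but no outlet face (no air vent)")
  structure(list(
    u = numeric((domain$nr + 1) * domain$nz),
    w = numeric(domain$nr * (domain$nz + 1)),
    p = numeric(domain$nr * domain$nz),
    alpha = numeric(domain$nr * domain$nz),
    time = 0, injected_volume = 0, outflow_marrow = 0, clipped_volume = 0,
    max_div = 0, u_max = 0), class = "flow_state")
}

#' Divergence tolerance in absolute units (1/s)
#' @keywords internal
div_tolerance <- function(domain, config) {
  config$divergence_tol * config$u_char / min(domain$dr, domain$dz)
}

#' Advance the flow one time step
#'
#' One projection step: mixture properties from the marrow fraction and the
#' power-law viscosity of the local shear rate, explicit hybrid advection,
#' implicit viscous solve, conjugate-gradient pressure projection, and
#' flux-limited conservative advection of the marrow fraction.  Marrow
#' inflow is imposed on inlet faces only while `inflow` is `TRUE`.
#'
#' @param state a `flow_state`.
#' @param domain a `flow_domain`.
#' @param rheo a [marrow_rheology()].
#' @param config a [flow_config()].
#' @param dt time step (s); must respect the CFL limit.
#' @param inflow impose inlet velocities this step?
#' @param lid_u tangential lid velocity on the top wall (benchmark use).
#' @param newtonian force Newtonian viscosity `k` (clamps off).
#' @return updated `flow_state`.
#' @export
flow_step <- function(state, domain, rheo, config, dt,
                      inflow = state$time < config$fill_duration,
                      lid_u = 0, newtonian = FALSE) {
  stopifnot(inherits(state, "flow_state"), dt > 0)
  vmax <- max(state$u_max, if (inflow) config$inlet_speed else 0, abs(lid_u))
  if (vmax > 0 && dt > config$cfl_limit * min(domain$dr, domain$dz) / vmax * 1.0001)
    stop(sprintf("CFL violation: dt = %.3g exceeds %.3g", dt,
                 config$cfl_limit * min(domain$dr, domain$dz) / vmax))
  res <- cpp_flow_step(state$u, state$w, state$alpha, state$p, domain$geom,
                       flow_phys(rheo, config, newtonian), dt,
                       if (inflow) config$inlet_speed else 0, lid_u,
                       div_tolerance(domain, config), config$max_cg_iters)
  st <- state
  st$u <- res$u; st$w <- res$w; st$alpha <- res$alpha; st$p <- res$p
  st$time <- state$time + dt
  st$injected_volume <- state$injected_volume + res$influx
  st$outflow_marrow <- state$outflow_marrow + res$outflux_marrow
  st$clipped_volume <- state$clipped_volume + res$clipped
  st$max_div <- res$max_div
  st$u_max <- res$u_max
  st
}

#' Adaptive time step from the CFL condition
#' @keywords internal
next_dt <- function(state, domain, config, inflow) {
  vmax <- max(state$u_max, if (inflow) config$inlet_speed else 0, 1e-12)
  min(config$cfl_limit * min(domain$dr, domain$dz) / vmax, config$dt_max)
}

#' Cell-centred shear-rate field
#'
#' Finite-difference \eqn{\dot\gamma} of the staggered velocity field;
#' zero inside solid cells.
#'
#' @param state a `flow_state`.
#' @param domain a `flow_domain`.
#' @return matrix `nr x nz` of shear rates (1/s).
#' @export
shear_rate_field <- function(state, domain) {
  matrix(cpp_shear_rate(state$u, state$w, domain$geom), domain$nr, domain$nz)
}

#' Marrow volume currently in the domain
#'
#' @param state a `flow_state`.
#' @param domain a `flow_domain`.
#' @return volume (m^3): integral of the marrow fraction over cell volumes.
#' @export
marrow_volume <- function(state, domain) {
  sum(state$alpha * domain$geom$vol)
}

#' Run the filling flow without particles
#'
#' Convenience driver used by tests and diagnostics: steps the solver to
#' `t_end` with adaptive dt, landing exactly on `fill_duration` and
#' `t_end`, optionally recording a time series.
#'
#' @param domain,rheo,config as in [flow_step()].
#' @param t_end end time (s), default `config$total_duration`.
#' @param record record per-step diagnostics?
#' @param newtonian forwarded to [flow_step()].
#' @return list with final `state` and optionally `series` (data.frame).
#' @export
run_fill <- function(domain, rheo = marrow_rheology(), config = flow_config(),
                     t_end = config$total_duration, record = FALSE,
                     newtonian = FALSE) {
  state <- initialize_flow(domain, config)
  ser <- if (record) list() else NULL
  i <- 0
  while (state$time < t_end - 1e-12) {
    inflow <- state$time < config$fill_duration - 1e-12
    dt <- if (is.na(config$dt)) next_dt(state, domain, config, inflow) else config$dt
    for (ev in c(config$fill_duration, t_end))
      if (state$time < ev - 1e-12) dt <- min(dt, ev - state$time)
    state <- flow_step(state, domain, rheo, config, dt, inflow = inflow,
                       newtonian = newtonian)
    i <- i + 1
    if (record) {
      ser[[i]] <- data.frame(time = state$time, dt = dt,
                             volume = marrow_volume(state, domain),
                             injected = state$injected_volume,
                             outflow = state$outflow_marrow,
                             max_div = state$max_div, u_max = state$u_max)
    }
  }
  list(state = state,
       series = if (record) do.call(rbind, ser) else NULL)
}
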