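#' Lagrangian BMSC ensemble
#'
#' Container for the discrete cell phase: spherical, non-rotating particles
#' (default 25 um diameter, 1000 kg/m^3, surface tension 0.03 N/m) carried
#' by the resolved flow with one-way coupling.  Status codes: 0 suspended,
#' 1 stuck, 2 spread, 3 escaped.
#'
#' @param capacity preallocated particle slots.
#' @param diameter particle diameter (m).
#' @param density particle density (kg/m^3).
#' @param surface_tension particle surface tension (N/m).
#' @return environment of class `cell_phase` with position/velocity/status
#'   vectors and injection counters.
#' @export
cell_phase <- function(capacity = 1000L, diameter = 25e-6, density = 1000,
                       surface_tension = 0.03) {
  stopifnot(diameter > 0, density > 0, surface_tension > 0)
  e <- new.env(parent = emptyenv())
  e$x <- numeric(capacity); e$z <- numeric(capacity)
  e$vx <- numeric(capacity); e$vz <- numeric(capacity)
  e$status <- integer(capacity)
  e$n <- 0L
  e$injected_total <- 0L
  e$injected_window <- 0L
  e$diameter <- diameter; e$density <- density
  e$surface_tension <- surface_tension
  e$mass <- density * pi / 6 * diameter^3
  class(e) <- "cell_phase"
  e
}

#' Status counts of a cell ensemble
#' @param cells a `cell_phase`.
#' @return named integer vector (suspended, stuck, spread, escaped).
#' @export
cell_counts <- function(cells) {
  s <- cells$status[seq_len(cells$n)]
  c(suspended = sum(s == 0L), stuck = sum(s == 1L),
    spread = sum(s == 2L), escaped = sum(s == 3L))
}

#' Injection schedule for the cell phase
#'
#' 50,000 cells are injected uniformly over the inlet faces during the
#' 2.5 s filling window (largest-remainder apportionment across time steps,
#' so the cumulative in-window count is met exactly).  After the window,
#' `continued_injection` keeps injecting at the same number rate with the
#' cells released at `post_fill_speed`; `no_injection` stops.
#'
#' @param n_cells cells injected during the window.
#' @param window injection window `c(start, end)` (s).
#' @param post_fill_mode `"continued_injection"` or `"no_injection"`.
#' @param post_fill_speed release speed after the window (m/s).
#' @return object of class `injection_schedule`.
#' @export
injection_schedule <- function(n_cells = 50000L, window = c(0, 2.5),
                               post_fill_mode = c("continued_injection",
                                                  "no_injection"),
                               post_fill_speed = 1e-3) {
  post_fill_mode <- match.arg(post_fill_mode)
  stopifnot(n_cells >= 0, length(window) == 2, window[2] > window[1])
  structure(list(n_cells = as.integer(n_cells), window = window,
                 post_fill_mode = post_fill_mode,
                 post_fill_speed = post_fill_speed),
            class = "injection_schedule")
}

#' Cumulative injection target at time t
#' @keywords internal
injection_target <- function(schedule, t) {
  w <- schedule$window
  rate <- schedule$n_cells / (w[2] - w[1])
  base <- rate * (min(t, w[2]) - w[1])
  base <- max(base, 0)
  extra <- if (schedule$post_fill_mode == "continued_injection" && t > w[2])
    rate * (t - w[2]) else 0
  floor(base + extra + 1e-9)
}

#' Inject new particles over the interval (t0, t1]
#'
#' Draws injection sites uniformly over the inlet faces (area-weighted; the
#' annular bottom faces with radius-proportional measure) and releases the
#' particles at the faces with the inflow speed along the inward normal.
#' Uses R's global RNG; manage seeds/streams in the caller.
#'
#' @param cells a `cell_phase` (modified in place).
#' @param schedule an [injection_schedule()].
#' @param domain a `flow_domain` with inlet faces.
#' @param t0,t1 interval endpoints (s).
#' @param speed release speed during the window (m/s).
#' @return number of particles injected (invisibly the cells object holds them).
#' @export
inject <- function(cells, schedule, domain, t0, t1, speed = 1e-3) {
  n_new <- as.integer(injection_target(schedule, t1) -
                        injection_target(schedule, t0))
  if (n_new <= 0) return(0L)
  faces <- domain$inlet_faces
  if (is.null(faces) || nrow(faces) == 0) stop("domain has no inlet faces")
  grow_to(cells, cells$n + n_new)
  pick <- sample.int(nrow(faces), n_new, replace = TRUE, prob = faces$area)
  in_window <- t1 <= schedule$window[2] + 1e-9
  v <- if (in_window) speed else schedule$post_fill_speed
  px <- pz <- numeric(n_new)
  fax <- faces$axis[pick]
  isr <- fax == "r"
  if (any(isr)) {
    px[isr] <- faces$x[pick[isr]]
    pz[isr] <- runif(sum(isr), faces$z0[pick[isr]], faces$z1[pick[isr]])
  }
  if (any(!isr)) {
    i0 <- faces$i[pick[!isr]]
    r0 <- i0 * domain$dr; r1 <- (i0 + 1) * domain$dr
    px[!isr] <- sqrt(runif(sum(!isr)) * (r1^2 - r0^2) + r0^2)
    pz[!isr] <- faces$z0[pick[!isr]]
  }
  pvx <- faces$nx_[pick] * v
  pvz <- faces$nz_[pick] * v
  idx <- cells$n + seq_len(n_new)
  cells$x[idx] <- px; cells$z[idx] <- pz
  cells$vx[idx] <- pvx; cells$vz[idx] <- pvz
  cells$status[idx] <- 0L
  cells$n <- cells$n + n_new
  cells$injected_total <- cells$injected_total + n_new
  if (in_window) cells$injected_window <- cells$injected_window + n_new
  n_new
}

#' @keywords internal
grow_to <- function(cells, n_needed) {
  cap <- length(cells$x)
  if (n_needed <= cap) return(invisible(NULL))
  newcap <- max(n_needed, 2 * cap)
  pad <- function(v, fill = 0) c(v, rep(fill, newcap - length(v)))
  cells$x <- pad(cells$x); cells$z <- pad(cells$z)
  cells$vx <- pad(cells$vx); cells$vz <- pad(cells$vz)
  cells$status <- c(cells$status, rep(0L, newcap - length(cells$status)))
  invisible(NULL)
}

#' Mixture viscosity and density fields for particle drag
#' @keywords internal
mixture_fields <- function(state, domain, rheo, config) {
  gam <- cpp_shear_rate(state$u, state$w, domain$geom)
  eta <- apparent_viscosity(rheo, gam)
  a <- pmin(pmax(state$alpha, 0), 1)
  list(mu = a * eta + (1 - a) * config$air_viscosity,
       rho = a * rheo$rho + (1 - a) * config$air_density)
}

#' Advance suspended particles through one step of the resolved flow
#'
#' Semi-analytic drag update: the Stokes response time
#' \eqn{\tau = \rho_p d^2 / (18\mu)} with the Schiller-Naumann finite-Re
#' correction is integrated exactly over the step for the carrier velocity
#' and buoyant gravity frozen at the particle position, then positions are
#' advanced with the updated velocity.  Stuck/spread/escaped particles do
#' not move.  Returns *proposed* positions; impingement handling is
#' separate (see [detect_impingement()] / [resolve_impingements()]).
#'
#' @param cells a `cell_phase`.
#' @param state a `flow_state`.
#' @param domain a `flow_domain`.
#' @param rheo a [marrow_rheology()].
#' @param config a [flow_config()].
#' @param dt time step (s).
#' @param fields optional precomputed [mixture_fields()] result.
#' @return list with `idx` (indices of moved particles) and proposed
#'   `x`, `z`, `vx`, `vz`.
#' @export
advance_cells <- function(cells, state, domain, rheo, config, dt,
                          fields = mixture_fields(state, domain, rheo, config)) {
  idx <- which(cells$status[seq_len(cells$n)] == 0L)
  if (length(idx) == 0)
    return(list(idx = integer(0), x = numeric(0), z = numeric(0),
                vx = numeric(0), vz = numeric(0)))
  res <- cpp_advance_cells(cells$x[idx], cells$z[idx], cells$vx[idx],
                           cells$vz[idx], state$u, state$w, fields$mu,
                           fields$rho, domain$geom, cells$density,
                           cells$diameter, config$gravity, dt)
  list(idx = idx, x = res$x, z = res$z, vx = res$vx, vz = res$vz)
}

#' Detect wall/scaffold impingements along particle paths
#'
#' An impingement is recorded when a particle's straight path over the step
#' enters a solid cell or leaves the domain, or when its end position comes
#' within the capture distance (one particle radius) of a solid surface.
#' Crossing the outlet ring makes a particle `escaped`.  Event kinds:
#' `"scaffold"`, `"wall"`, `"outlet"`, `"inlet"` (contact with a face that
#' injects marrow while inflow is active).
#'
#' @param cells a `cell_phase` (for the capture radius).
#' @param moved result of [advance_cells()] (proposed positions).
#' @param domain a `flow_domain`.
#' @return data.frame of events: `idx` (particle index), `kind`, surface
#'   normal `nx`, `nz`, normal approach speed `vn`, impact point `x`, `z`.
#' @export
detect_impingement <- function(cells, moved, domain) {
  if (length(moved$idx) == 0)
    return(data.frame(idx = integer(0), kind = character(0), nx = numeric(0),
                      nz = numeric(0), vn = numeric(0), x = numeric(0),
                      z = numeric(0)))
  ev <- cpp_detect_impingement(cells$x[moved$idx], cells$z[moved$idx],
                               moved$x, moved$z, moved$vx, moved$vz,
                               domain$geom, cells$diameter / 2)
  kinds <- c("scaffold", "wall", "outlet", "inlet")
  data.frame(idx = moved$idx[ev$idx], kind = kinds[ev$kind], nx = ev$nx,
             nz = ev$nz, vn = ev$vn, x = ev$x, z = ev$z)
}
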