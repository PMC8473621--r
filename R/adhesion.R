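#' Cell impingement (adhesion) configuration
#'
#' Classifies each cell-wall impingement into one of three regimes by the
#' impact Weber number \eqn{We = \rho_p d v_n^2 / \sigma}: stick for
#' `We <= we_stick_max`, rebound in between, spread for
#' `We >= we_spread_min`.  The default thresholds (5 / 10) follow standard
#' droplet-impingement regime maps; at the marrow filling speeds
#' (about 1 mm/s) `We` is of order 1e-6, so impingements stick — cells
#' adhere on first contact.  `restitution` scales the normal velocity of a
#' rebound (1 = elastic).
#'
#' @param we_stick_max upper Weber bound of the stick regime.
#' @param we_spread_min lower Weber bound of the spread regime.
#' @param restitution normal restitution for rebounds, in (0, 1].
#' @param spread_footprint recorded footprint factor for spread events
#'   (spread is treated as an attached cell with a larger contact area).
#' @return object of class `adhesion_config`.
#' @export
adhesion_config <- function(we_stick_max = 5, we_spread_min = 10,
                            restitution = 0.9, spread_footprint = 2) {
  stopifnot(we_stick_max > 0, we_spread_min >= we_stick_max,
            restitution > 0, restitution <= 1)
  structure(list(we_stick_max = we_stick_max, we_spread_min = we_spread_min,
                 restitution = restitution,
                 spread_footprint = spread_footprint),
            class = "adhesion_config")
}

#' Impact Weber number
#'
#' \eqn{We = \rho_p d\, v_n^2 / \sigma}: the ratio of impact inertia to the
#' cell's surface tension.  Vectorised over `v_n`.
#'
#' @param cells a [cell_phase()] (or any list with `density`, `diameter`,
#'   `surface_tension`).
#' @param v_n normal impact speed(s) (m/s), >= 0.
#' @return dimensionless Weber number(s).
#' @export
weber_number <- function(cells, v_n) {
  if (cells$surface_tension <= 0) stop("surface tension must be positive")
  if (any(v_n < 0)) stop("v_n must be non-negative")
  cells$density * cells$diameter * v_n^2 / cells$surface_tension
}

#' Classify impingements into stick / rebound / spread
#'
#' Total and mutually exclusive over the Weber axis: stick on
#' `[0, we_stick_max]`, rebound on `(we_stick_max, we_spread_min)`, spread on
#' `[we_spread_min, Inf)`.
#'
#' @param we Weber number(s).
#' @param config an [adhesion_config()].
#' @return character vector of regimes.
#' @export
classify_impingement <- function(we, config = adhesion_config()) {
  stopifnot(all(we >= 0))
  ifelse(we >= config$we_spread_min, "spread",
         ifelse(we > config$we_stick_max, "rebound", "stick"))
}

#' Resolve impingement events against the cell ensemble
#'
#' Outlet crossings become `escaped`.  Contacts with actively injecting
#' inlet faces, and any scaffold/wall contact before the attachment window
#' opens, rebound elastically.  Within the attachment window stick and
#' spread events bind the cell at the impact point with zero velocity;
#' rebounds reflect the normal velocity scaled by the restitution.
#' Returns the attachment records for the ledger.
#'
#' @param cells a `cell_phase` (modified in place).
#' @param moved proposed positions from [advance_cells()].
#' @param events data.frame from [detect_impingement()].
#' @param config an [adhesion_config()].
#' @param domain a `flow_domain`.
#' @param t current time (s), recorded on attachments.
#' @param attach_active is the attachment window open (t >= fill time)?
#' @param inflow_active are inlet faces currently injecting marrow?
#' @return data.frame of attachment events (possibly 0 rows): `time`, `id`,
#'   `surface`, `regime`, `x`, `z`, `layer`, `ring`, `band`, `mass`.
#' @export
resolve_impingements <- function(cells, moved, events, config, domain, t,
                                 attach_active, inflow_active = !attach_active) {
  # default: accept proposed motion
  if (length(moved$idx)) {
    cells$x[moved$idx] <- moved$x
    cells$z[moved$idx] <- moved$z
    cells$vx[moved$idx] <- moved$vx
    cells$vz[moved$idx] <- moved$vz
  }
  if (nrow(events) == 0)
    return(attachment_record())
  live <- cells$status[events$idx] == 0L    # at most one event per particle
  if (!all(live)) events <- events[live, , drop = FALSE]
  if (nrow(events) == 0) return(attachment_record())
  eps <- 0.51 * cells$diameter
  kind <- events$kind
  is_out <- kind == "outlet"
  capture <- attach_active & !(kind == "inlet" & inflow_active) & !is_out
  regime <- rep("rebound", nrow(events))
  if (any(capture))
    regime[capture] <- classify_impingement(
      weber_number(cells, events$vn[capture]), config)
  attach <- capture & regime != "rebound"
  reb <- !is_out & !attach

  if (any(is_out)) {
    i <- events$idx[is_out]
    cells$status[i] <- 3L
    cells$x[i] <- events$x[is_out]; cells$z[i] <- events$z[is_out]
    cells$vx[i] <- 0; cells$vz[i] <- 0
  }
  if (any(reb)) {
    i <- events$idx[reb]
    e <- ifelse(capture[reb], config$restitution, 1.0)  # elastic pre-window
    nx <- events$nx[reb]; nz <- events$nz[reb]
    vdotn <- cells$vx[i] * nx + cells$vz[i] * nz
    cells$vx[i] <- cells$vx[i] - (1 + e) * vdotn * nx
    cells$vz[i] <- cells$vz[i] - (1 + e) * vdotn * nz
    cells$x[i] <- pmax(events$x[reb] + nx * eps, 0)
    cells$z[i] <- events$z[reb] + nz * eps
  }
  if (!any(attach)) return(attachment_record())
  i <- events$idx[attach]
  cells$status[i] <- ifelse(regime[attach] == "spread", 2L, 1L)
  cells$x[i] <- events$x[attach]; cells$z[i] <- events$z[attach]
  cells$vx[i] <- 0; cells$vz[i] <- 0
  surface <- ifelse(kind[attach] == "scaffold", "scaffold", "wall")
  led <- data.frame(time = t, id = i, surface = surface,
                    regime = regime[attach], x = events$x[attach],
                    z = events$z[attach], layer = NA_integer_,
                    ring = NA_integer_, band = NA_integer_,
                    mass = cells$mass)
  sc <- surface == "scaffold"
  if (any(sc)) {
    loc <- locate_on_scaffold(domain, led$x[sc], led$z[sc])
    led$layer[sc] <- loc$layer; led$ring[sc] <- loc$ring
    led$band[sc] <- loc$band
  }
  led
}

#' @keywords internal
attachment_record <- function() {
  data.frame(time = numeric(0), id = integer(0), surface = character(0),
             regime = character(0), x = numeric(0), z = numeric(0),
             layer = integer(0), ring = integer(0), band = integer(0),
             mass = numeric(0))
}

#' Attached-cell density by scaffold region
#'
#' Aggregates the attachment ledger over a partition of the scaffold:
#' `"radial5"` — the five-part edge-to-middle split (bands 1/5 outer, 3
#' middle; symmetric halves pooled), reporting mean attached mass per beam
#' (ring) and per unit beam area; `"rows"` — per sublayer; `"boundary"` —
#' boundary (defect wall) versus scaffold, with area-normalised density.
#'
#' @param ledger attachment data.frame from [resolve_impingements()] /
#'   [run_simulation()].
#' @param domain a `flow_domain`.
#' @param partition `"radial5"`, `"rows"` or `"boundary"`.
#' @return data.frame of per-region counts, mass and densities.
#' @export
region_density <- function(ledger, domain, partition = c("radial5", "rows",
                                                         "boundary")) {
  partition <- match.arg(partition)
  census <- ring_census(domain)
  sc <- ledger[ledger$surface == "scaffold", , drop = FALSE]
  if (partition == "radial5") {
    out <- do.call(rbind, lapply(sort(unique(census$band)), function(b) {
      rings_b <- census[census$band == b, ]
      mass <- sum(sc$mass[sc$band == b])
      data.frame(band = b, n_beams = nrow(rings_b),
                 count = sum(sc$band == b), mass = mass,
                 mass_per_beam = mass / max(nrow(rings_b), 1),
                 density = mass / sum(rings_b$area))
    }))
    return(out)
  }
  if (partition == "rows") {
    out <- do.call(rbind, lapply(sort(unique(census$layer)), function(l) {
      rings_l <- census[census$layer == l, ]
      mass <- sum(sc$mass[sc$layer == l])
      data.frame(layer = l, n_beams = nrow(rings_l),
                 count = sum(sc$layer == l), mass = mass,
                 mass_per_beam = mass / max(nrow(rings_l), 1),
                 density = mass / sum(rings_l$area))
    }))
    return(out)
  }
  wall <- ledger[ledger$surface == "wall", , drop = FALSE]
  data.frame(
    surface = c("scaffold", "boundary"),
    count = c(nrow(sc), nrow(wall)),
    mass = c(sum(sc$mass), sum(wall$mass)),
    area = c(sum(census$area), domain$wall_area),
    density = c(sum(sc$mass) / sum(census$area),
                sum(wall$mass) / domain$wall_area))
}
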