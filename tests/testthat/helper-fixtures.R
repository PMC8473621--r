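# shared fixtures: tiny geometries and independent oracles

tiny_scaffold <- function(...) {
  scaffold_spec(top_diameter = 3, bottom_diameter = 2.5, n_sublayers = 3,
                layer_pitch = 0.92, ...)
}

# independent double-loop oracle for bone-scaffold contact counting;
# interface = scaffold pixels with a non-scaffold 4-neighbour, numerator
# connectivity as requested
contact_oracle <- function(lab, connectivity) {
  nr <- nrow(lab); nc <- ncol(lab)
  n4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  n8 <- c(n4, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  nbs <- if (connectivity == 8) n8 else n4
  interface <- 0L; contact <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (lab[i, j] != 2L) next
    is_int <- FALSE
    for (o in n4) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && lab[ii, jj] != 2L)
        is_int <- TRUE
    }
    if (!is_int) next
    interface <- interface + 1L
    has_bone <- FALSE
    for (o in nbs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && lab[ii, jj] == 1L)
        has_bone <- TRUE
    }
    if (has_bone) contact <- contact + 1L
  }
  list(interface = interface, contact = contact,
       percentage = 100 * contact / interface)
}

# affine velocity field on a cavity fixture: u = c1 + c2 x + c3 z,
# w = c4 + c5 x + c6 z; the shear rate is the constant
# sqrt(2 c2^2 + 2 c6^2 + (c3 + c5)^2) for any consistent differencing
affine_flow_state <- function(domain, cf) {
  st <- initialize_flow(domain, flow_config(inlet_speed = 0))
  st$alpha <- rep(1, domain$nr * domain$nz)
  nr <- domain$nr; nz <- domain$nz
  xf <- (0:nr) * domain$dr
  zcol <- (seq_len(nz) - 0.5) * domain$dz
  st$u <- as.vector(outer(xf, zcol, function(x, z) cf[1] + cf[2] * x + cf[3] * z))
  xc <- (seq_len(nr) - 0.5) * domain$dr
  zf <- (0:nz) * domain$dz
  st$w <- as.vector(outer(xc, zf, function(x, z) cf[4] + cf[5] * x + cf[6] * z))
  st$u_max <- max(abs(st$u), abs(st$w))
  st
}

# brute-force segment/voxel-face intersection oracle: enumerates every
# crossing of the segment with the grid planes, sorts them, and reports the
# first crossing into a non-fluid cell
impinge_oracle <- function(x0, z0, x1, z1, domain) {
  g <- domain$geom
  ct <- matrix(g$ctype, g$nx, g$nz)
  segx <- x1 - x0; segz <- z1 - z0
  ts <- numeric(0)
  if (segx != 0) {
    tx <- ((0:g$nx) * g$dx - x0) / segx
    ts <- c(ts, tx[tx > 1e-12 & tx <= 1])
  }
  if (segz != 0) {
    tz <- ((0:g$nz) * g$dz - z0) / segz
    ts <- c(ts, tz[tz > 1e-12 & tz <= 1])
  }
  for (t in sort(unique(ts))) {
    tm <- min(t + 1e-9, 1)               # just past the crossing
    cx <- x0 + tm * segx; cz <- z0 + tm * segz
    i <- floor(cx / g$dx); k <- floor(cz / g$dz)
    solidish <- i >= g$nx || k < 0 || k >= g$nz ||
      (i >= 0 && k >= 0 && k < g$nz && i < g$nx && ct[i + 1, k + 1] != 0L)
    if (solidish) return(list(hit = TRUE, cell = c(i, k), t = t))
  }
  list(hit = FALSE)
}

small_section_for_adhesion <- function() {
  build_flow_section(tiny_scaffold(),
                     defect_spec(top_diameter = 3.4, bottom_diameter = 2.6,
                                 depth = 3.3), nr = 16, nz = 24)
}

expect_close <- function(actual, expected, rel = NULL, abs = NULL) {
  if (!is.null(rel))
    expect_lt(abs(actual - expected), rel * abs(expected))
  else expect_lt(abs(actual - expected), abs)
}
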