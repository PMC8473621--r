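#' Titanium scaffold specification
#'
#' Parametric description of the 3D-printed titanium lattice layer: a
#' truncated cone (default 8.0 mm top / 5.9 mm bottom diameter) filled with
#' stacked sublayers of parallel cylindrical beams (0.5 mm diameter on a
#' 1 mm pitch, giving the 1x1 mm pores), each sublayer's beams perpendicular
#' to the previous.  Beams run at half-pitch lateral offsets so the layout is
#' symmetric about the cone axis.
#'
#' The sublayer count and vertical pitch are not part of the published
#' morphometrics; the defaults (9 sublayers at 0.92 mm pitch, height 8.28 mm)
#' were frozen once so that the lattice height plus the 0.5 mm dense cap
#' matches the 8.8 mm defect depth and the analytic porosity
#' \eqn{1 - \pi r_b^2/(p\, h)} lands at 0.787, in line with the 78.6%
#' characterisation of the printed part.
#'
#' @param top_diameter,bottom_diameter cone diameters (mm).
#' @param beam_diameter beam (column) diameter (mm).
#' @param pore_pitch in-plane beam spacing (mm).
#' @param n_sublayers number of beam sublayers (0 gives an empty solid).
#' @param layer_pitch vertical spacing between sublayer centrelines (mm).
#' @param height lattice height (mm); defaults to `n_sublayers * layer_pitch`.
#' @param alternate_orientation alternate beam direction per sublayer.
#' @return object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(top_diameter = 8.0, bottom_diameter = 5.9,
                          beam_diameter = 0.5, pore_pitch = 1.0,
                          n_sublayers = 9, layer_pitch = 0.92,
                          height = n_sublayers * layer_pitch,
                          alternate_orientation = TRUE) {
  stopifnot(top_diameter > 0, bottom_diameter > 0, beam_diameter > 0,
            pore_pitch > 0, layer_pitch > 0, n_sublayers >= 0)
  if (bottom_diameter > top_diameter)
    stop("bottom_diameter must not exceed top_diameter")
  if (n_sublayers > 0 && height <= 0) stop("height must be positive")
  if (beam_diameter >= bottom_diameter)
    stop("beam_diameter must be smaller than the cone bottom diameter")
  structure(list(top_diameter = top_diameter,
                 bottom_diameter = bottom_diameter,
                 beam_diameter = beam_diameter, pore_pitch = pore_pitch,
                 n_sublayers = n_sublayers, layer_pitch = layer_pitch,
                 height = if (n_sublayers > 0) height else 0,
                 alternate_orientation = alternate_orientation),
            class = "scaffold_spec")
}

#' Osteochondral defect specification
#'
#' The drilled truncated-cone defect that receives the scaffold: 8.2 mm top
#' and 5.88 mm bottom diameter, with a 0.1 mm annular gap around the top of
#' the inserted scaffold that serves as the air outlet during marrow filling.
#'
#' @param top_diameter,bottom_diameter defect diameters (mm).
#' @param depth defect depth (mm).
#' @param outlet_gap width of the annular air-outlet ring at the top (mm).
#' @return object of class `defect_spec`.
#' @export
defect_spec <- function(top_diameter = 8.2, bottom_diameter = 5.88,
                        depth = 8.8, outlet_gap = 0.1) {
  stopifnot(top_diameter > 0, bottom_diameter > 0, depth > 0, outlet_gap >= 0)
  structure(list(top_diameter = top_diameter,
                 bottom_diameter = bottom_diameter,
                 depth = depth, outlet_gap = outlet_gap),
            class = "defect_spec")
}

#' Cone radius of the scaffold/defect frustum at height z
#' @keywords internal
frustum_radius <- function(bottom_diameter, top_diameter, height, z) {
  if (height <= 0) return(rep(bottom_diameter / 2, length(z)))
  (bottom_diameter + (top_diameter - bottom_diameter) * pmin(pmax(z / height, 0), 1)) / 2
}

#' Build the titanium lattice as an implicit solid
#'
#' Returns a lattice model whose `contains(x, y, z)` member evaluates exact
#' point membership (union of cylindrical beams clipped to the truncated
#' cone).  z runs upward from the scaffold bottom; units are mm.
#'
#' @param spec a [scaffold_spec()].
#' @return object of class `lattice_model` with elements `spec` and
#'   `contains` (vectorised predicate).
#' @export
build_titanium_lattice <- function(spec) {
  stopifnot(inherits(spec, "scaffold_spec"))
  s <- spec
  rb <- s$beam_diameter / 2
  hp <- s$layer_pitch
  pitch <- s$pore_pitch
  nsub <- s$n_sublayers
  contains <- function(x, y, z) {
    if (nsub == 0) return(rep(FALSE, length(x)))
    rc <- frustum_radius(s$bottom_diameter, s$top_diameter, s$height, z)
    inside <- z >= 0 & z <= s$height & (x * x + y * y) <= rc * rc
    l <- pmin(pmax(floor(z / hp), 0), nsub - 1)
    zl <- (l + 0.5) * hp
    along_x <- if (s$alternate_orientation) (l %% 2 == 0) else rep(TRUE, length(l))
    perp <- ifelse(along_x, y, x)
    u <- perp / pitch
    d <- abs(u - (floor(u) + 0.5)) * pitch  # distance to nearest beam axis
    inside & (d * d + (z - zl)^2) <= rb * rb
  }
  structure(list(spec = s, contains = contains), class = "lattice_model")
}

#' Arbitrary implicit solid for voxel morphometrics
#'
#' Wraps a vectorised point-membership predicate with an explicit bounding
#' box so that [voxelize()] and [surface_area()] can be exercised on
#' analytic reference solids (a cylinder, a cube, a frustum) as well as on
#' lattice models.
#'
#' @param contains function `(x, y, z) -> logical`.
#' @param xlim,ylim,zlim bounding box (mm).
#' @return object of class `implicit_solid`.
#' @export
implicit_solid <- function(contains, xlim, ylim, zlim) {
  stopifnot(is.function(contains), length(xlim) == 2, length(ylim) == 2,
            length(zlim) == 2)
  structure(list(contains = contains, xlim = xlim, ylim = ylim, zlim = zlim),
            class = "implicit_solid")
}

#' Voxelize an implicit solid
#'
#' Deterministic centre-sampling: a voxel is solid iff its centre lies
#' inside the solid.  For a lattice model the grid covers the scaffold
#' bounding box `[-R, R]^2 x [0, height]` (R = top radius); for an
#' [implicit_solid()] its stated box.  `pad` adds voxels of void on every
#' side so that exterior surfaces are resolved.
#'
#' @param lattice a `lattice_model` or an [implicit_solid()].
#' @param spacing voxel edge length (mm), > 0.
#' @param pad void padding in voxels (default 0).
#' @return object of class `voxel_domain`: `spacing`, `origin` (mm),
#'   `dims`, logical array `occupancy`, and the originating `spec` (lattice
#'   models only).
#' @export
voxelize <- function(lattice, spacing, pad = 0) {
  stopifnot(spacing > 0, pad >= 0)
  if (inherits(lattice, "lattice_model")) {
    s <- lattice$spec
    R <- s$top_diameter / 2
    box <- list(x = c(-R, R), y = c(-R, R), z = c(0, max(s$height, spacing)))
  } else if (inherits(lattice, "implicit_solid")) {
    s <- NULL
    box <- list(x = lattice$xlim, y = lattice$ylim, z = lattice$zlim)
  } else stop("need a lattice_model or implicit_solid")
  nd <- function(lim) ceiling(diff(lim) / spacing) + 2 * pad
  nx <- nd(box$x); ny <- nd(box$y); nzc <- nd(box$z)
  origin <- c(box$x[1], box$y[1], box$z[1]) - pad * spacing
  xs <- origin[1] + (seq_len(nx) - 0.5) * spacing
  ys <- origin[2] + (seq_len(ny) - 0.5) * spacing
  zs <- origin[3] + (seq_len(nzc) - 0.5) * spacing
  occ <- array(FALSE, dim = c(nx, ny, nzc))
  xy <- expand.grid(x = xs, y = ys)
  for (k in seq_len(nzc)) {
    occ[, , k] <- lattice$contains(xy$x, xy$y, rep(zs[k], nrow(xy)))
  }
  structure(list(spacing = spacing, origin = origin, dims = c(nx, ny, nzc),
                 occupancy = occ, spec = s),
            class = "voxel_domain")
}

#' Mask of voxels inside the scaffold bounding frustum
#' @keywords internal
frustum_mask <- function(domain) {
  s <- domain$spec
  d <- domain$dims
  xs <- domain$origin[1] + (seq_len(d[1]) - 0.5) * domain$spacing
  zs <- domain$origin[3] + (seq_len(d[3]) - 0.5) * domain$spacing
  r2 <- outer(xs^2, xs^2, `+`)
  m <- array(FALSE, dim = d)
  for (k in seq_len(d[3])) {
    if (zs[k] < 0 || zs[k] > s$height) next
    rc <- frustum_radius(s$bottom_diameter, s$top_diameter, s$height, zs[k])
    m[, , k] <- r2 <= rc * rc
  }
  m
}

#' Scaffold porosity from a voxel domain
#'
#' Void fraction inside the scaffold's bounding frustum:
#' void voxels / total voxels, both restricted to the frustum.  For the
#' default lattice this evaluates to about 0.786 at 0.05 mm spacing.
#'
#' @param domain a `voxel_domain` from [voxelize()].
#' @return porosity in \[0, 1\].
#' @export
porosity <- function(domain) {
  stopifnot(inherits(domain, "voxel_domain"))
  if (is.null(domain$spec))
    stop("porosity needs a lattice-derived domain (bounding frustum unknown)")
  if (domain$spec$height == 0) return(1)   # no material at all
  m <- frustum_mask(domain)
  tot <- sum(m)
  if (tot == 0) stop("empty bounding frustum")
  1 - sum(domain$occupancy & m) / tot
}

#' Surface area of an implicit solid
#'
#' Smoothed-gradient (co-area) estimator: the occupancy indicator is
#' voxelized with void padding, smoothed with a small separable binomial
#' kernel, and the integral of the gradient magnitude approximates the
#' surface area.  Accurate to a few percent for smooth and polyhedral
#' solids; reported with an `estimator` tag.
#'
#' @param lattice a `lattice_model` (or any object accepted by [voxelize()]).
#' @param spacing voxel edge (mm); must be positive.
#' @param smooth_passes binomial smoothing passes per axis.
#' @return list with `area` (mm^2), `spacing`, `estimator`.
#' @export
surface_area <- function(lattice, spacing, smooth_passes = 2) {
  stopifnot(spacing > 0)
  dom <- voxelize(lattice, spacing, pad = 4 + 2 * smooth_passes)
  chi <- dom$occupancy * 1.0
  sm <- function(a, dim_) {
    n <- dim(a)[dim_]
    lo <- seq_len(n); hi <- lo
    shift <- function(off) {
      idx <- pmin(pmax(seq_len(n) + off, 1), n)
      switch(dim_, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
             a[, , idx, drop = FALSE])
    }
    (shift(-1) + 2 * a + shift(1)) / 4
  }
  for (p in seq_len(smooth_passes)) for (d in 1:3) chi <- sm(chi, d)
  grad <- function(a, dim_) {
    n <- dim(a)[dim_]
    idxp <- pmin(seq_len(n) + 1, n); idxm <- pmax(seq_len(n) - 1, 1)
    gp <- switch(dim_, a[idxp, , , drop = FALSE], a[, idxp, , drop = FALSE],
                 a[, , idxp, drop = FALSE])
    gm <- switch(dim_, a[idxm, , , drop = FALSE], a[, idxm, , drop = FALSE],
                 a[, , idxm, drop = FALSE])
    (gp - gm) / (2 * spacing)
  }
  gmag <- sqrt(grad(chi, 1)^2 + grad(chi, 2)^2 + grad(chi, 3)^2)
  list(area = sum(gmag) * spacing^3, spacing = spacing,
       estimator = "smoothed-gradient co-area")
}

#' Assemble the labelled defect domain around a voxelized scaffold
#'
#' The void is the defect frustum minus the scaffold solid.  Boundary faces
#' of void voxels are tagged: the lateral frustum surface `inlet_side`, the
#' bottom disc `inlet_bottom`, the annular top ring of width `outlet_gap`
#' `outlet_gap`, and the remaining top surface `wall` (the dense cap).
#' A sub-voxel interference of the scaffold with the defect wall (the
#' press-fit: scaffold bottom 5.9 mm vs defect bottom 5.88 mm) is shaved
#' off; protrusion beyond `protrusion_tol` mm is an error.
#'
#' @param scaffold a `voxel_domain` of the lattice (from [voxelize()]).
#' @param defect a [defect_spec()].
#' @param protrusion_tol tolerated scaffold protrusion beyond the defect (mm).
#' @return object of class `defect_domain`: `spacing`, `origin`, `dims`,
#'   integer array `occupancy` (0 void, 1 scaffold, 2 exterior), data.frame
#'   `faces` (i, j, k, axis, side, tag, area) and the two specs.
#' @export
build_defect_domain <- function(scaffold, defect,
                                protrusion_tol = 0.05) {
  stopifnot(inherits(scaffold, "voxel_domain"), inherits(defect, "defect_spec"))
  s <- scaffold$spec
  sp <- scaffold$spacing
  if (defect$depth < s$height - 1e-9)
    stop("scaffold is taller than the defect")
  Rtop <- defect$top_diameter / 2
  nx <- ceiling(2 * Rtop / sp)
  nzc <- ceiling(defect$depth / sp)
  origin <- c(-(nx / 2) * sp, -(nx / 2) * sp, 0)
  xs <- origin[1] + (seq_len(nx) - 0.5) * sp
  zs <- (seq_len(nzc) - 0.5) * sp
  lat <- build_titanium_lattice(s)
  occ <- array(2L, dim = c(nx, nx, nzc))
  r2 <- outer(xs^2, xs^2, `+`)
  max_protrusion <- 0
  for (k in seq_len(nzc)) {
    rd <- frustum_radius(defect$bottom_diameter, defect$top_diameter,
                         defect$depth, zs[k])
    inside <- r2 <= rd * rd
    sl <- matrix(0L, nx, nx)
    sl[!inside] <- 2L
    if (zs[k] <= s$height) {
      xy <- expand.grid(x = xs, y = xs)
      solid <- matrix(lat$contains(xy$x, xy$y, rep(zs[k], nrow(xy))), nx, nx)
      if (any(solid & !inside)) {
        pr <- sqrt(max(r2[solid & !inside])) - rd
        max_protrusion <- max(max_protrusion, pr)
      }
      sl[solid & inside] <- 1L
    }
    occ[, , k] <- sl
  }
  if (max_protrusion > protrusion_tol)
    stop(sprintf("scaffold protrudes %.3f mm beyond the defect wall",
                 max_protrusion))
  dom <- structure(list(spacing = sp, origin = origin, dims = c(nx, nx, nzc),
                        occupancy = occ, spec = s, defect = defect),
                   class = "defect_domain")
  dom$faces <- label_boundary_faces(dom)
  dom
}

#' Tag the boundary faces of the void region
#' @keywords internal
label_boundary_faces <- function(dom) {
  occ <- dom$occupancy
  d <- dom$dims
  sp <- dom$spacing
  defect <- dom$defect
  gap_r <- defect$top_diameter / 2 - defect$outlet_gap
  xs <- dom$origin[1] + (seq_len(d[1]) - 0.5) * sp
  res <- vector("list", 6)
  shift_solid <- function(axis, side) {
    # TRUE where the neighbour of a void voxel across (axis, side) is
    # exterior solid (2) or out of the grid
    n <- d[axis]
    idx <- seq_len(n) + side
    out <- idx < 1 | idx > n
    idx <- pmin(pmax(idx, 1), n)
    nb <- switch(axis, occ[idx, , , drop = FALSE], occ[, idx, , drop = FALSE],
                 occ[, , idx, drop = FALSE])
    bad <- nb == 2L
    if (any(out)) {
      sel <- which(out)
      switch(axis, bad[sel, , ] <- TRUE, bad[, sel, ] <- TRUE,
             bad[, , sel] <- TRUE)
    }
    bad
  }
  m <- 1
  for (axis in 1:3) for (side in c(-1L, 1L)) {
    hit <- (occ == 0L) & shift_solid(axis, side)
    if (!any(hit)) { m <- m + 1; next }
    w <- which(hit, arr.ind = TRUE)
    tag <- rep("inlet_side", nrow(w))
    if (axis == 3 && side == -1L) {
      tag[] <- "inlet_side"            # stair-step of the slanted wall
      tag[w[, 3] == 1L] <- "inlet_bottom"
    }
    if (axis == 3 && side == 1L) {
      rr <- sqrt(xs[w[, 1]]^2 + xs[w[, 2]]^2)
      ztop <- (w[, 3]) * sp  # top face height of the voxel
      at_top <- ztop >= dom$dims[3] * sp - sp / 2
      tag[at_top & rr > gap_r] <- "outlet_gap"
      tag[at_top & rr <= gap_r] <- "wall"
      tag[!at_top] <- "inlet_side"  # stair-step of the slanted defect wall
    }
    res[[m]] <- data.frame(i = w[, 1], j = w[, 2], k = w[, 3], axis = axis,
                           side = side, tag = tag, area = sp^2)
    m <- m + 1
  }
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}
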