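#' Write a voxel occupancy as a legacy VTK structured-points file
#'
#' ASCII legacy VTK, one scalar field `occupancy` (0 void / 1 solid, or the
#' integer labels of a defect domain).
#'
#' @param domain a `voxel_domain` or `defect_domain`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_vtk_voxels <- function(domain, path) {
  d <- domain$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "voxel occupancy", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", domain$origin[1], domain$origin[2],
                       domain$origin[3]),
               sprintf("SPACING %g %g %g", domain$spacing, domain$spacing,
                       domain$spacing),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS occupancy int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(domain$occupancy), collapse = "\n"), con)
  invisible(path)
}

#' Write flow-section fields as a legacy VTK structured-points file
#'
#' Cell-centred marrow fraction, pressure and interpolated velocity on the
#' r-z section (written as a flat 3D dataset of one slab).
#'
#' @param state a `flow_state`.
#' @param domain a `flow_domain`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_vtk_fields <- function(state, domain, path) {
  nr <- domain$nr; nz <- domain$nz
  u <- matrix(state$u, nr + 1, nz)
  w <- matrix(state$w, nr, nz + 1)
  uc <- (u[1:nr, ] + u[2:(nr + 1), ]) / 2
  wc <- (w[, 1:nz] + w[, 2:(nz + 1)]) / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "flow section", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nr, nz),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", domain$dr, domain$dz),
               sprintf("POINT_DATA %d", nr * nz),
               "SCALARS marrow_fraction double 1", "LOOKUP_TABLE default"),
             con)
  writeLines(format(state$alpha, digits = 8), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(state$p, digits = 8), con)
  writeLines("VECTORS velocity double", con)
  writeLines(paste(format(as.vector(uc), digits = 8), 0,
                   format(as.vector(wc), digits = 8)), con)
  invisible(path)
}

#' Write a particle snapshot as a legacy VTK point cloud
#'
#' @param cells_df data.frame with columns `x`, `z`, `status` (as produced
#'   in a `simulation_result` ensemble).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_vtk_particles <- function(cells_df, path) {
  n <- nrow(cells_df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cell particles", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(paste(format(cells_df$x, digits = 8), 0,
                   format(cells_df$z, digits = 8)), con)
  writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS status int 1",
               "LOOKUP_TABLE default"), con)
  st <- match(cells_df$status,
              c("suspended", "stuck", "spread", "escaped")) - 1L
  writeLines(paste(st), con)
  invisible(path)
}

#' Morphometrics report for a scaffold lattice
#'
#' Voxelizes the lattice and reports porosity and the surface-area estimate
#' as a one-row data.frame (optionally written as CSV).
#'
#' @param spec a [scaffold_spec()].
#' @param spacing voxel spacing (mm).
#' @param path optional CSV output path.
#' @return data.frame with `porosity`, `surface_area_mm2`, `spacing_mm`,
#'   `estimator`.
#' @export
morphometrics_report <- function(spec = scaffold_spec(), spacing = 0.05,
                                 path = NULL) {
  lat <- build_titanium_lattice(spec)
  dom <- voxelize(lat, spacing)
  sa <- surface_area(lat, max(spacing, 0.02))
  out <- data.frame(porosity = porosity(dom), surface_area_mm2 = sa$area,
                    spacing_mm = spacing, estimator = sa$estimator)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
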