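test_that("degenerate lattices voxelize to the expected extremes", {
  empty <- build_titanium_lattice(scaffold_spec(n_sublayers = 0))
  d <- voxelize(empty, 0.2)
  expect_false(any(d$occupancy))
  expect_equal(porosity(d), 1)
})

test_that("voxel volume of a beam matches the analytic cylinder volume", {
  r <- 0.2
  cyl <- implicit_solid(function(x, y, z)
    x >= 0 & x <= 1 & (y - 0.5)^2 + (z - 0.5)^2 <= r^2,
    c(0, 1), c(0, 1), c(0, 1))
  d <- voxelize(cyl, 0.02)
  vol <- sum(d$occupancy) * 0.02^3
  expect_close(vol, pi * r^2 * 1, rel = 0.02)
})

test_that("full-frustum solid fraction matches the frustum volume formula", {
  fr <- implicit_solid(function(x, y, z) {
    R <- (2.5 + (3 - 2.5) * pmin(pmax(z / 2, 0), 1)) / 2
    z >= 0 & z <= 2 & x^2 + y^2 <= R^2
  }, c(-1.5, 1.5), c(-1.5, 1.5), c(0, 2))
  d <- voxelize(fr, 0.02)
  vfrustum <- pi * 2 / 3 * (1.5^2 + 1.5 * 1.25 + 1.25^2)
  vbox <- prod(d$dims) * 0.02^3
  expect_close(sum(d$occupancy) * 0.02^3 / vbox, vfrustum / vbox, rel = 0.02)
})

test_that("porosity and solid fraction are exact complements", {
  d <- voxelize(build_titanium_lattice(tiny_scaffold()), 0.1)
  m <- osteoseed:::frustum_mask(d)
  solid_frac <- sum(d$occupancy & m) / sum(m)
  expect_identical(porosity(d) + solid_frac, 1)
})

test_that("porosity converges under voxel refinement", {
  lat <- build_titanium_lattice(tiny_scaffold())
  p1 <- porosity(voxelize(lat, 0.1))
  p2 <- porosity(voxelize(lat, 0.05))
  p3 <- porosity(voxelize(lat, 0.025))
  expect_lt(abs(p3 - p2), 0.01)     # halving below 0.05 mm moves < 1 pp
  expect_lt(abs(p2 - p1), 0.05)
})

test_that("surface-area estimator matches closed forms within 5%", {
  cube <- implicit_solid(function(x, y, z)
    x >= 0 & x <= 1 & y >= 0 & y <= 1 & z >= 0 & z <= 1,
    c(0, 1), c(0, 1), c(0, 1))
  expect_close(surface_area(cube, 0.02)$area, 6, rel = 0.05)
  r <- 0.2
  beam <- implicit_solid(function(x, y, z)
    x >= 0 & x <= 1 & (y - 0.5)^2 + (z - 0.5)^2 <= r^2,
    c(0, 1), c(0, 1), c(0, 1))
  expect_close(surface_area(beam, 0.02)$area, 2 * pi * r * 1 + 2 * pi * r^2,
               rel = 0.05)
})

test_that("spec validation rejects impossible geometries", {
  expect_error(scaffold_spec(bottom_diameter = 9), "top_diameter")
  expect_error(scaffold_spec(beam_diameter = 6), "beam_diameter")
  expect_error(defect_spec(depth = -1))
  sc <- voxelize(build_titanium_lattice(tiny_scaffold()), 0.1)
  expect_error(build_defect_domain(sc, defect_spec(depth = 1)), "taller")
})

test_that("defect domain labels partition the boundary with all four tags", {
  sc <- voxelize(build_titanium_lattice(tiny_scaffold()), 0.1)
  dd <- build_defect_domain(sc, defect_spec(top_diameter = 3.4,
                                            bottom_diameter = 2.6,
                                            depth = 3.3, outlet_gap = 0.2))
  f <- dd$faces
  expect_setequal(unique(f$tag),
                  c("inlet_side", "inlet_bottom", "outlet_gap", "wall"))
  # no face doubly labelled: keys are unique
  key <- paste(f$i, f$j, f$k, f$axis, f$side)
  expect_identical(anyDuplicated(key), 0L)
  expect_gt(sum(f$tag == "outlet_gap"), 0)
})

test_that("outlet face count grows monotonically with the gap width", {
  sc <- voxelize(build_titanium_lattice(tiny_scaffold()), 0.1)
  counts <- vapply(c(0.15, 0.3, 0.5), function(gp) {
    dd <- build_defect_domain(sc, defect_spec(top_diameter = 3.4,
                                              bottom_diameter = 2.6,
                                              depth = 3.3, outlet_gap = gp))
    sum(dd$faces$tag == "outlet_gap")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})

test_that("zero outlet gap leaves a sealed cavity the solver refuses", {
  dom <- build_flow_section(tiny_scaffold(),
                            defect_spec(top_diameter = 3.4,
                                        bottom_diameter = 2.6, depth = 3.3,
                                        outlet_gap = 0),
                            nr = 16, nz = 24)
  expect_equal(dom$n_outlet_faces, 0)
  expect_error(initialize_flow(dom, flow_config()), "sealed")
})
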