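test_that("renders are reproducible from config and seed", {
  lat <- build_titanium_lattice(tiny_scaffold())
  a <- render_radiograph(lat, ingrowth_model(seed = 11, noise_sigma = 4), 120)
  b <- render_radiograph(lat, ingrowth_model(seed = 11, noise_sigma = 4), 120)
  expect_identical(a$image, b$image)
  cc <- render_radiograph(lat, ingrowth_model(seed = 12, noise_sigma = 4), 120)
  expect_false(identical(a$image, cc$image))
})

test_that("zero base fraction plants no bone", {
  lat <- build_titanium_lattice(tiny_scaffold())
  s <- render_radiograph(lat, ingrowth_model(base_fraction = 0,
                                             radial_gradient = 0,
                                             vertical_gradient = 0), 120)
  expect_equal(s$planted$n_bone, 0)
  expect_false(any(s$labels == 1L))
})

test_that("planted uniform fraction is recovered exactly at zero noise", {
  lat <- build_titanium_lattice(tiny_scaffold())
  s <- render_radiograph(lat, ingrowth_model(base_fraction = 0.3,
                                             radial_gradient = 0,
                                             vertical_gradient = 0,
                                             noise_sigma = 0, seed = 2), 150)
  # generator plants round(0.3 * n_void) bone pixels exactly
  expect_equal(s$planted$n_bone, round(0.3 * s$planted$n_void))
  # and the quantification recovers precisely the planted labels
  lab <- classify_pixels(s$image)
  expect_identical(unclass(lab), s$labels)
  st <- bone_fraction(lab, partition_grids(lab, 1, 1))
  expect_equal(st$P_b, s$planted$n_bone / s$planted$n_void)
  expect_close(st$P_b, 0.3, abs = 1 / s$planted$n_void + 1e-12)
})

test_that("noisy renders recover the planted global fraction within 1 pp", {
  lat <- build_titanium_lattice(tiny_scaffold())
  s <- render_radiograph(lat, ingrowth_model(base_fraction = 0.3,
                                             radial_gradient = 0,
                                             vertical_gradient = 0,
                                             noise_sigma = 5, seed = 8), 150)
  lab <- classify_pixels(s$image)
  recovered <- sum(lab == 1L) / sum(lab != 2L)
  expect_close(recovered, s$planted$n_bone / s$planted$n_void, abs = 0.01)
})

test_that("ground-truth label counts equal the planted census", {
  lat <- build_titanium_lattice(tiny_scaffold())
  s <- render_radiograph(lat, ingrowth_model(seed = 4), 120)
  expect_identical(sum(s$labels == 1L), s$planted$n_bone)
  expect_identical(sum(s$labels != 2L) - sum(s$labels == 1L) -
                     sum(s$labels == 0L), 0L)
})

test_that("planted radial gradient yields an edge-heavy column profile", {
  lat <- build_titanium_lattice(scaffold_spec())
  s <- render_radiograph(lat, ingrowth_model(base_fraction = 0.3,
                                             radial_gradient = 0.2,
                                             vertical_gradient = 0,
                                             seed = 6), 200)
  lab <- classify_pixels(s$image)
  st <- bone_fraction(lab, partition_grids(lab, 5, 10))
  pr <- grid_profiles(st, "columns", n_groups = 5)
  expect_gt(mean(pr$mean_P_b[c(1, 5)]), pr$mean_P_b[3])
})

test_that("flow fixtures produce their stated shear-rate fields", {
  fu <- make_flow_fixture("uniform", U = 2e-3)
  expect_equal(max(abs(shear_rate_field(fu$state, fu$domain))), 0)
  G <- 25
  fs <- make_flow_fixture("linear_shear", G = G)
  gam <- shear_rate_field(fs$state, fs$domain)
  expect_equal(as.vector(gam), rep(G, length(gam)), tolerance = 1e-10)
  fc <- make_flow_fixture("settling_column")
  expect_equal(max(abs(fc$state$u), abs(fc$state$w)), 0)
})

test_that("radiograph writer round-trips through the PNG reader", {
  lat <- build_titanium_lattice(tiny_scaffold())
  s <- render_radiograph(lat, ingrowth_model(seed = 9), 120)
  td <- withr::local_tempdir()
  stem <- file.path(td, "synthetic_xray")
  write_radiograph(s, stem)
  back <- read_radiograph(paste0(stem, ".png"))
  expect_identical(back, s$image)
})
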