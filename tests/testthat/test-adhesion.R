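test_that("Weber number matches its definition and scaling", {
  cells <- cell_phase(4)  # defaults: rho 1000, d 25 um, sigma 0.03 N/m
  expect_equal(weber_number(cells, 0), 0)
  expect_equal(weber_number(cells, 1e-3), 1000 * 25e-6 * 1e-6 / 0.03,
               tolerance = 1e-12)               # 8.33e-7 at 1 mm/s
  expect_equal(weber_number(cells, 2e-3) / weber_number(cells, 1e-3), 4)
  bad <- cell_phase(4); bad$surface_tension <- 0
  expect_error(weber_number(bad, 1), "surface tension")
})

test_that("regime classification is total, exclusive, and boundary-correct", {
  cfg <- adhesion_config(we_stick_max = 5, we_spread_min = 10)
  expect_equal(classify_impingement(0, cfg), "stick")
  expect_equal(classify_impingement(5, cfg), "stick")        # inclusive
  expect_equal(classify_impingement(5 + 1e-12, cfg), "rebound")
  expect_equal(classify_impingement(10, cfg), "spread")      # inclusive
  set.seed(31)
  we <- c(10^runif(500, -8, 3), 5, 10)
  got <- classify_impingement(we, cfg)
  want <- ifelse(we >= 10, "spread", ifelse(we > 5, "rebound", "stick"))
  expect_identical(got, want)
  # every event classified exactly once
  expect_true(all(got %in% c("stick", "rebound", "spread")))
})

test_that("as surface tension grows all impingements stick", {
  cells <- cell_phase(4)
  cells$surface_tension <- 1e6
  we <- weber_number(cells, 10)          # absurdly fast impact
  expect_equal(classify_impingement(we), "stick")
})

test_that("rebound preserves speed at unit restitution and loses energy below", {
  dom <- build_cavity_domain(8, 1e-3)
  set.seed(17)
  for (e in c(1, 0.6)) {
    cfg <- adhesion_config(restitution = e,
                           we_stick_max = 1e-12, we_spread_min = 1e12)
    for (trial in 1:20) {
      cells <- cell_phase(4)
      cells$n <- 1L
      v <- rnorm(2) * 1e-3
      v[2] <- -abs(v[2])                 # toward the bottom wall
      cells$vx[1] <- v[1]; cells$vz[1] <- v[2]
      cells$x[1] <- 5e-4; cells$z[1] <- 2e-5
      moved <- list(idx = 1L, x = cells$x[1], z = cells$z[1],
                    vx = v[1], vz = v[2])
      ev <- data.frame(idx = 1L, kind = "wall", nx = 0, nz = 1,
                       vn = abs(v[2]), x = 5e-4, z = 0)
      resolve_impingements(cells, moved, ev, cfg, dom, t = 3,
                           attach_active = TRUE, inflow_active = FALSE)
      speed2 <- cells$vx[1]^2 + cells$vz[1]^2
      if (e == 1) expect_equal(speed2, sum(v^2), tolerance = 1e-12)
      else expect_lt(speed2, sum(v^2))
      expect_gt(cells$vz[1], 0)          # reflected away from the wall
    }
  }
})

test_that("stick events move a cell from suspended to attached", {
  dom <- small_section_for_adhesion()
  cells <- cell_phase(4)
  cells$n <- 1L
  cells$x[1] <- 1e-4; cells$z[1] <- 1e-4
  moved <- list(idx = 1L, x = 1e-4, z = 1e-4, vx = 0, vz = -1e-3)
  ev <- data.frame(idx = 1L, kind = "scaffold", nx = 0, nz = 1,
                   vn = 1e-3, x = 1e-4, z = 9e-5)
  led <- resolve_impingements(cells, moved, ev, adhesion_config(), dom,
                              t = 3, attach_active = TRUE,
                              inflow_active = FALSE)
  expect_identical(cells$status[1], 1L)
  expect_equal(nrow(led), 1)
  expect_equal(led$surface, "scaffold")
  expect_equal(unname(cell_counts(cells)["stuck"]), 1L)
  # before the attachment window the same event rebounds instead
  cells2 <- cell_phase(4); cells2$n <- 1L
  cells2$x[1] <- 1e-4; cells2$z[1] <- 1e-4; cells2$vz[1] <- -1e-3
  led2 <- resolve_impingements(cells2, moved, ev, adhesion_config(), dom,
                               t = 1, attach_active = FALSE,
                               inflow_active = TRUE)
  expect_identical(cells2$status[1], 0L)
  expect_equal(nrow(led2), 0)
})

test_that("region densities aggregate the ledger exactly", {
  dom <- small_section_for_adhesion()
  census <- ring_census(dom)
  # empty ledger: all zeros
  z <- region_density(osteoseed:::attachment_record(), dom, "radial5")
  expect_true(all(z$mass == 0))
  # all attachments on one ring: that region carries 100% of the mass
  r1 <- census[1, ]
  led <- do.call(rbind, replicate(7, data.frame(
    time = 3, id = 1L, surface = "scaffold", regime = "stick",
    x = r1$radius, z = 0, layer = r1$layer, ring = r1$ring,
    band = r1$band, mass = 2e-12), simplify = FALSE))
  rd <- region_density(led, dom, "radial5")
  expect_equal(sum(rd$mass), 7 * 2e-12)
  expect_equal(rd$mass[rd$band == r1$band], 7 * 2e-12)
  rows <- region_density(led, dom, "rows")
  expect_equal(rows$mass[rows$layer == r1$layer], 7 * 2e-12)
  expect_equal(sum(rows$count), 7)
  # a uniform synthetic attachment field gives equal per-beam masses
  led_u <- do.call(rbind, lapply(seq_len(nrow(census)), function(i)
    data.frame(time = 3, id = i, surface = "scaffold", regime = "stick",
               x = census$radius[i], z = 0, layer = census$layer[i],
               ring = census$ring[i], band = census$band[i], mass = 1e-12)))
  rd_u <- region_density(led_u, dom, "radial5")
  expect_equal(rd_u$mass_per_beam, rep(1e-12, nrow(rd_u)))
  # partition sums equal the global total
  bd <- region_density(led_u, dom, "boundary")
  expect_equal(sum(rd_u$mass), bd$mass[bd$surface == "scaffold"])
})
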