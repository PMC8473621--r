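small_section <- function(nr = 16, nz = 24) {
  build_flow_section(tiny_scaffold(),
                     defect_spec(top_diameter = 3.4, bottom_diameter = 2.6,
                                 depth = 3.3), nr = nr, nz = nz)
}

test_that("injection apportionment delivers the scheduled count exactly", {
  dom <- small_section()
  sched <- injection_schedule(n_cells = 1234, window = c(0, 2.5),
                              post_fill_mode = "no_injection")
  cells <- cell_phase(2000)
  set.seed(5)
  # irregular step sequence covering the window
  t <- 0
  while (t < 2.5) {
    dt <- min(runif(1, 1e-3, 0.04), 2.5 - t)
    inject(cells, sched, dom, t, t + dt)
    t <- t + dt
  }
  expect_identical(cells$injected_window, 1234L)
  expect_identical(cells$injected_total, 1234L)
  # nothing after the window in no_injection mode
  inject(cells, sched, dom, 2.5, 3.5)
  expect_identical(cells$injected_total, 1234L)
  # continued mode keeps the same number rate
  sched2 <- injection_schedule(n_cells = 1000, window = c(0, 2.5),
                               post_fill_mode = "continued_injection")
  cells2 <- cell_phase(4000)
  inject(cells2, sched2, dom, 0, 2.5)
  inject(cells2, sched2, dom, 2.5, 5)
  expect_identical(cells2$injected_total, 2000L)
  expect_identical(cells2$injected_window, 1000L)
})

test_that("same seed reproduces identical injection positions", {
  dom <- small_section()
  sched <- injection_schedule(n_cells = 500)
  draw <- function() {
    cells <- cell_phase(600)
    set.seed(77)
    inject(cells, sched, dom, 0, 1.0)
    cbind(cells$x[1:cells$n], cells$z[1:cells$n])
  }
  expect_identical(draw(), draw())
})

test_that("injected particles start on inlet faces moving inward", {
  dom <- small_section()
  cells <- cell_phase(600)
  set.seed(3)
  inject(cells, injection_schedule(n_cells = 400), dom, 0, 1.0, speed = 1e-3)
  n <- cells$n
  expect_true(all(sqrt(cells$vx[1:n]^2 + cells$vz[1:n]^2) - 1e-3 < 1e-12))
  # all within the domain box
  expect_true(all(cells$x[1:n] >= 0 & cells$x[1:n] <= dom$nr * dom$dr))
  expect_true(all(cells$z[1:n] >= 0 & cells$z[1:n] <= dom$nz * dom$dz))
})

test_that("a neutrally buoyant particle in still fluid stays put", {
  fx <- make_flow_fixture("settling_column")
  cfg <- flow_config(inlet_speed = 0, gravity = -9.81)
  rh <- marrow_rheology(k = 0.005, n = 1, rho = 1000)
  cells <- cell_phase(4, density = 1000)  # same density as the fluid
  cells$n <- 1L; cells$x[1] <- 1e-4; cells$z[1] <- 3e-4
  mv <- advance_cells(cells, fx$state, fx$domain, rh, cfg, 1e-4)
  expect_equal(mv$x, cells$x[1], tolerance = 1e-12)
  expect_equal(abs(mv$vz), 0, tolerance = 1e-15)
})

test_that("drag relaxation follows v(t) = U (1 - exp(-t/tau)) within 1%", {
  fx <- make_flow_fixture("uniform", U = 1e-3)
  cfg <- flow_config(inlet_speed = 0, gravity = 0)
  rh <- marrow_rheology(k = 0.005, n = 1, rho = 1050)
  cells <- cell_phase(4)
  cells$n <- 1L; cells$x[1] <- 5e-4; cells$z[1] <- 5e-4
  tau <- 1000 * (25e-6)^2 / (18 * 0.005)
  flds <- osteoseed:::mixture_fields(fx$state, fx$domain, rh, cfg)
  dt <- tau / 20
  for (i in 1:20) {          # advance to t = tau
    mv <- advance_cells(cells, fx$state, fx$domain, rh, cfg, dt, fields = flds)
    cells$x[1] <- mv$x; cells$z[1] <- mv$z
    cells$vx[1] <- mv$vx; cells$vz[1] <- mv$vz
  }
  expect_close(cells$vx[1], 1e-3 * (1 - exp(-1)), rel = 0.01)
})

test_that("still-fluid settling reaches the Stokes terminal speed within 1%", {
  fx <- make_flow_fixture("settling_column", n = 8, L = 2e-4)
  cfg <- flow_config(inlet_speed = 0, gravity = -9.81)
  rh <- marrow_rheology(k = 0.005, n = 1, rho = 1050)
  cells <- cell_phase(4, density = 2000)
  cells$n <- 1L; cells$x[1] <- 1e-4; cells$z[1] <- 6e-4
  tau <- 2000 * (25e-6)^2 / (18 * 0.005)
  flds <- osteoseed:::mixture_fields(fx$state, fx$domain, rh, cfg)
  for (i in 1:100) {
    mv <- advance_cells(cells, fx$state, fx$domain, rh, cfg, tau / 5,
                        fields = flds)
    cells$x[1] <- mv$x; cells$z[1] <- mv$z
    cells$vx[1] <- mv$vx; cells$vz[1] <- mv$vz
  }
  v_term <- (2000 - 1050) * 9.81 * (25e-6)^2 / (18 * 0.005)
  expect_close(-cells$vz[1], v_term, rel = 0.01)
})

test_that("impingement detection matches a fine-marching oracle", {
  dom <- small_section(nr = 20, nz = 30)
  set.seed(13)
  cfg <- flow_config()
  n <- 300
  # random segments inside the domain box, many grazing solids
  W <- dom$nr * dom$dr; H <- dom$nz * dom$dz
  fluid <- which(dom$cell_type == 0L, arr.ind = TRUE)
  pick <- fluid[sample(nrow(fluid), n, replace = TRUE), ]
  x0 <- (pick[, 1] - 0.5) * dom$dr
  z0 <- (pick[, 2] - 0.5) * dom$dz
  x1 <- pmin(pmax(x0 + runif(n, -2, 2) * dom$dr, 1e-9), W - 1e-9)
  z1 <- pmin(pmax(z0 + runif(n, -2, 2) * dom$dz, -0.5 * dom$dz), H * 1.01)
  ev <- osteoseed:::cpp_detect_impingement(x0, z0, x1, z1,
                                          (x1 - x0) * 1e3, (z1 - z0) * 1e3,
                                          dom$geom, 0)  # no touch capture
  hits <- logical(n)
  hits[ev$idx] <- TRUE
  for (m in seq_len(n)) {
    want <- impinge_oracle(x0[m], z0[m], x1[m], z1[m], dom)
    expect_identical(hits[m], want$hit)
  }
})

test_that("paths parallel to a wall at clearance raise no event", {
  dom <- build_cavity_domain(16, 1e-3)
  d <- 25e-6
  z <- 1e-3 - 3 * d                      # 3 diameters below the top wall
  ev <- osteoseed:::cpp_detect_impingement(2e-4, z, 8e-4, z, 1e-3, 0,
                                          dom$geom, d / 2)
  expect_length(ev$idx, 0)
})

test_that("head-on wall approach yields one event with v_n = |v|", {
  dom <- build_cavity_domain(16, 1e-3)
  v <- 2e-3
  ev <- osteoseed:::cpp_detect_impingement(5e-4, 5e-4, 5e-4, 1.2e-3,
                                          0, v, dom$geom, 12.5e-6)
  expect_length(ev$idx, 1)
  expect_equal(ev$vn, v)
  expect_equal(ev$nz, -1)               # normal back into the fluid
})
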