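test_that("pixel classification honours the threshold boundaries", {
  img <- matrix(c(255L, 251L, 250L, 180L, 179L, 60L, 59L, 0L), 2, 4)
  lab <- classify_pixels(img)
  expect_identical(as.vector(unclass(lab)),
                   c(2L, 2L, 0L, 0L, 1L, 1L, 0L, 0L))
  expect_error(classify_pixels(matrix(300L, 2, 2)), "8-bit")
  expect_error(classify_pixels(matrix(0.5, 2, 2)), "8-bit")
})

test_that("classes partition the image", {
  set.seed(7)
  img <- matrix(sample(0:255, 900, replace = TRUE), 30, 30)
  lab <- classify_pixels(img)
  expect_identical(sum(lab == 0L) + sum(lab == 1L) + sum(lab == 2L), 900L)
})

test_that("grid partition uses integer strides with trailing remainder", {
  img <- matrix(0L, 100, 103)
  g <- partition_grids(img, 4, 4)
  expect_equal(nrow(g), 16)
  w <- g$c1[g$row == 1] - g$c0[g$row == 1] + 1
  expect_equal(sort(w), c(25, 25, 25, 28))
  g1 <- partition_grids(img, 1, 1)
  expect_equal(c(g1$r0, g1$r1, g1$c0, g1$c1), c(1, 100, 1, 103))
  expect_error(partition_grids(matrix(0, 3, 3), 5, 1), "finer")
})

test_that("bone fraction implements P_b = S_bone / (S_all - S_s)", {
  lab <- matrix(0L, 10, 10)
  lab[1:2, ] <- 2L           # 20 scaffold pixels
  lab[3:6, ] <- 1L           # 40 bone pixels
  class(lab) <- c("label_image", class(lab))
  st <- bone_fraction(lab, partition_grids(lab, 1, 1))
  expect_equal(st$P_b, 40 / (100 - 20))
  allsc <- matrix(2L, 4, 4)
  st2 <- bone_fraction(allsc, partition_grids(allsc, 1, 1))
  expect_true(is.na(st2$P_b))   # undefined when the grid is all scaffold
  allo <- matrix(0L, 4, 4)
  st3 <- bone_fraction(allo, partition_grids(allo, 1, 1))
  expect_equal(st3$P_b, 0)
})

test_that("profiles are flat for uniform fields and monotone for gradients", {
  lab <- matrix(1L, 40, 40)   # all bone
  st <- bone_fraction(lab, partition_grids(lab, 4, 4))
  pr <- grid_profiles(st, "columns")
  expect_equal(pr$mean_P_b, rep(1, 4))
  # planted linear gradient across columns
  frac <- seq(0.1, 0.9, length.out = 40)
  set.seed(1)
  lab2 <- matrix(0L, 40, 40)
  for (j in 1:40) lab2[, j] <- ifelse(runif(40) < frac[j], 1L, 0L)
  st2 <- bone_fraction(lab2, partition_grids(lab2, 4, 8))
  pr2 <- grid_profiles(st2, "columns", n_groups = 4)
  expect_true(all(diff(pr2$mean_P_b) > 0))
  single <- grid_profiles(st2, "rows", n_groups = 1)
  expect_equal(single$mean_P_b, mean(st2$P_b))
})

test_that("contact percentage follows the neighbourhood semantics", {
  # scaffold pixel whose only bone neighbour is diagonal
  lab <- matrix(0L, 3, 3); lab[2, 2] <- 2L; lab[1, 1] <- 1L
  expect_equal(contact_percentage(lab, 4)$percentage, 0)
  expect_equal(contact_percentage(lab, 8)$percentage, 100)
  # scaffold pixel fully ringed by bone
  lab2 <- matrix(1L, 3, 3); lab2[2, 2] <- 2L
  expect_equal(contact_percentage(lab2, 4)$percentage, 100)
  expect_equal(contact_percentage(lab2, 8)$percentage, 100)
  expect_error(contact_percentage(matrix(0L, 3, 3), 4), "no scaffold")
})

test_that("contact counts equal the brute-force oracle and 8 >= 4", {
  set.seed(99)
  for (trial in 1:100) {
    lab <- matrix(sample(0:2, 144, replace = TRUE,
                         prob = c(0.4, 0.3, 0.3)), 12, 12)
    if (!any(lab == 2L)) next
    for (conn in c(4, 8)) {
      got <- contact_percentage(lab, conn)
      want <- contact_oracle(lab, conn)
      expect_identical(got$interface_pixels, want$interface)
      expect_identical(got$contact_pixels, want$contact)
    }
    expect_gte(contact_percentage(lab, 8)$percentage,
               contact_percentage(lab, 4)$percentage)
  }
})

test_that("quantification batch reports one result per image", {
  set.seed(3)
  imgs <- replicate(3, {
    m <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    m[1:3, ] <- 255L
    m
  }, simplify = FALSE)
  out <- run_quantification(imgs, n_rows = 2, n_cols = 2)
  expect_length(out, 3)
  for (r in out) {
    expect_equal(nrow(r$grid_stats), 4)
    expect_gte(r$contact8$percentage, r$contact4$percentage)
  }
})

test_that("rotating the image permutes but preserves grid P_b values", {
  synth <- render_radiograph(build_titanium_lattice(tiny_scaffold()),
                             ingrowth_model(seed = 5), width_px = 120)
  n <- (min(dim(synth$image)) %/% 4) * 4   # grids must divide evenly
  sq <- synth$image[1:n, 1:n]
  rot <- t(sq[n:1, ])                    # 90 degree rotation
  pb <- function(m) {
    st <- bone_fraction(classify_pixels(m), partition_grids(m, 4, 4))
    sort(round(st$P_b, 12))
  }
  expect_equal(pb(sq), pb(rot))
})
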