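#' Synthetic bone-ingrowth model for radiograph generation
#'
#' Describes the planted bone distribution in a rendered radiograph: a base
#' void-filling fraction plus linear gradients along the normalised radius
#' (positive = more bone toward the scaffold edge) and the normalised depth
#' (positive = more bone toward the bottom), with trabecular-like speckle
#' texture from thresholded smoothed noise.  Defaults emulate the observed
#' ingrowth pattern: about 30% in the middle, 40% sub-side and 50% at the
#' edge, with a slight bottom-to-top decrease.
#'
#' @param base_fraction bone fraction of the void at the centre-top.
#' @param radial_gradient added fraction per unit normalised radius.
#' @param vertical_gradient added fraction per unit normalised depth.
#' @param speckle_scale speckle correlation length (px).
#' @param noise_sigma Gaussian intensity noise s.d. (grey levels) applied to
#'   non-scaffold pixels (the saturated titanium clips at 255).
#' @param seed RNG seed making the render reproducible.
#' @return object of class `ingrowth_model`.
#' @export
ingrowth_model <- function(base_fraction = 0.3, radial_gradient = 0.2,
                           vertical_gradient = 0.1, speckle_scale = 3,
                           noise_sigma = 0, seed = 1L) {
  stopifnot(base_fraction >= 0, speckle_scale >= 1, noise_sigma >= 0)
  structure(list(base_fraction = base_fraction,
                 radial_gradient = radial_gradient,
                 vertical_gradient = vertical_gradient,
                 speckle_scale = speckle_scale, noise_sigma = noise_sigma,
                 seed = as.integer(seed)), class = "ingrowth_model")
}

#' @keywords internal
box_blur <- function(m, w) {
  if (w <= 1) return(m)
  k <- rep(1 / w, w)
  blur1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], w), x, rep(x[n], w))
    stats::filter(xp, k, sides = 2)[(w + 1):(w + n)]
  }
  m <- apply(m, 2, blur1)
  t(apply(t(m), 2, blur1))
}

#' Render a synthetic X-ray radiograph of the scaffold with bone ingrowth
#'
#' Projects the titanium lattice through the viewing axis onto an 8-bit
#' image: projected scaffold at the saturated level 255 (> 250), planted
#' bone speckle in \[70, 170\] (inside the bone band \[60, 180) with margin
#' for noise), background below 60.  Bone pixels are selected among the
#' in-silhouette non-scaffold pixels by ranking a speckle field against the
#' local target fraction, so a spatially uniform target is met exactly
#' (to one pixel) before noise.  The pre-noise ground-truth label image is
#' returned alongside.
#'
#' @param lattice a `lattice_model` from [build_titanium_lattice()].
#' @param ingrowth an [ingrowth_model()].
#' @param width_px image width in pixels (height follows the aspect ratio).
#' @return object of class `synthetic_radiograph`: `image` (0..255 integer
#'   matrix), `labels` (ground truth: 0 other, 1 bone, 2 scaffold),
#'   `pixel_size_mm`, and `planted` (void/bone pixel counts and fraction).
#' @export
render_radiograph <- function(lattice, ingrowth = ingrowth_model(),
                              width_px = 200) {
  stopifnot(inherits(lattice, "lattice_model"), width_px >= 20)
  s <- lattice$spec
  R <- s$top_diameter / 2
  h <- max(s$height, 1e-6)
  px <- 2 * R / width_px
  height_px <- max(ceiling(h / px), 1)
  if (px > s$beam_diameter / 2)
    stop("image too small to resolve the beams")
  set.seed(ingrowth$seed)
  xs <- seq(-R + px / 2, R - px / 2, length.out = width_px)
  zs <- seq(h - px / 2, px / 2, length.out = height_px)  # row 1 = top
  X <- matrix(rep(xs, each = height_px), height_px, width_px)
  Z <- matrix(rep(zs, width_px), height_px, width_px)
  Rz <- matrix(frustum_radius(s$bottom_diameter, s$top_diameter, s$height,
                              as.vector(Z)), height_px, width_px)
  sil <- abs(X) <= Rz
  scaffold <- matrix(FALSE, height_px, width_px)
  if (s$n_sublayers > 0) {
    l <- pmin(pmax(floor(Z / s$layer_pitch), 0), s$n_sublayers - 1)
    zl <- (l + 0.5) * s$layer_pitch
    dzb <- abs(Z - zl)
    in_slab <- dzb <= s$beam_diameter / 2
    along_x <- if (s$alternate_orientation) (l %% 2 == 0) else
      matrix(TRUE, height_px, width_px)
    halfw <- sqrt(pmax((s$beam_diameter / 2)^2 - dzb^2, 0))
    u <- X / s$pore_pitch
    d <- abs(u - (floor(u) + 0.5)) * s$pore_pitch
    scaffold <- sil & in_slab & (along_x | d <= halfw)
  }
  void <- !scaffold   # bone can appear anywhere off the implant (host bone too)
  target <- pmin(pmax(ingrowth$base_fraction +
                        ingrowth$radial_gradient * pmin(abs(X) / Rz, 1.5) +
                        ingrowth$vertical_gradient * (1 - Z / h), 0), 1)
  speck <- box_blur(matrix(runif(height_px * width_px), height_px, width_px),
                    round(ingrowth$speckle_scale))
  bone <- matrix(FALSE, height_px, width_px)
  nv <- sum(void)
  if (nv > 0) {
    rk <- rank(speck[void], ties.method = "first")
    bone[void] <- (rk - 0.5) / nv <= target[void]
  }
  labels <- matrix(0L, height_px, width_px)
  labels[bone] <- 1L
  labels[scaffold] <- 2L
  img <- matrix(0, height_px, width_px)
  img[labels == 0L] <- sample(10:40, sum(labels == 0L), replace = TRUE)
  img[labels == 1L] <- sample(70:170, sum(labels == 1L), replace = TRUE)
  img[labels == 2L] <- 255
  if (ingrowth$noise_sigma > 0) {
    ns <- labels != 2L
    img[ns] <- img[ns] + stats::rnorm(sum(ns), 0, ingrowth$noise_sigma)
  }
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)),
                height_px, width_px)
  structure(list(image = img, labels = labels, pixel_size_mm = px,
                 planted = list(n_void = nv, n_bone = sum(bone),
                                fraction = if (nv > 0) sum(bone) / nv else 0),
                 ingrowth = ingrowth),
            class = "synthetic_radiograph")
}

#' Write a synthetic radiograph and its ground truth to disk
#'
#' Writes the 8-bit image as PNG, the ground-truth labels as CSV, and a
#' manifest echoing the generator configuration.
#'
#' @param synth a `synthetic_radiograph`.
#' @param stem output path stem (writes `<stem>.png`, `<stem>_truth.csv`,
#'   `<stem>_manifest.json`).
#' @return invisibly, the written paths.
#' @export
write_radiograph <- function(synth, stem) {
  p1 <- paste0(stem, ".png")
  png::writePNG(synth$image / 255, p1)
  p2 <- paste0(stem, "_truth.csv")
  utils::write.csv(as.data.frame(which(synth$labels == 1L, arr.ind = TRUE)),
                   p2, row.names = FALSE)
  p3 <- paste0(stem, "_manifest.json")
  writeLines(manifest_json(c(synth$ingrowth,
                             list(pixel_size_mm = synth$pixel_size_mm))), p3)
  invisible(c(p1, p2, p3))
}

#' Analytic flow/particle fixtures
#'
#' Small closed planar domains with prescribed velocity fields used to
#' exercise the shear-rate, interpolation and drag kernels against closed
#' forms: `"uniform"` (plug flow, zero shear), `"linear_shear"` (du/dz = G,
#' shear rate G everywhere), `"settling_column"` (quiescent tall column for
#' terminal-velocity checks).
#'
#' @param kind fixture kind.
#' @param n cells per side (column uses n x 4n).
#' @param L domain size (m).
#' @param U plug speed (m/s) for `"uniform"`.
#' @param G shear rate (1/s) for `"linear_shear"`.
#' @return list with `domain` (a `flow_domain`) and `state` (a
#'   `flow_state`, marrow-filled).
#' @export
make_flow_fixture <- function(kind = c("uniform", "linear_shear",
                                       "settling_column"),
                              n = 16, L = 1e-3, U = 1e-3, G = 10) {
  kind <- match.arg(kind)
  if (kind == "settling_column") {
    dx <- L / n
    nzc <- 4L * n
    ct <- matrix(0L, n, nzc)
    fx <- matrix(0L, n + 1, nzc); fx[1, ] <- 1L; fx[n + 1, ] <- 1L
    fz <- matrix(0L, n, nzc + 1); fz[, 1] <- 1L; fz[, nzc + 1] <- 1L
    geom <- list(nx = as.integer(n), nz = as.integer(nzc), dx = dx, dz = dx,
                 ctype = as.integer(ct), fx = as.integer(fx),
                 fz = as.integer(fz), Ax = rep(dx, (n + 1) * nzc),
                 Az = rep(dx, n * (nzc + 1)), vol = rep(dx * dx, n * nzc),
                 sx = rep(0, (n + 1) * nzc), sz = rep(0, n * (nzc + 1)))
    domain <- structure(list(nr = n, nz = nzc, dr = dx, dz = dx,
                             r_centers = (seq_len(n) - 0.5) * dx,
                             z_centers = (seq_len(nzc) - 0.5) * dx,
                             cell_type = ct, geom = geom, inlet_faces = NULL,
                             inlet_area = 0, n_outlet_faces = 0,
                             wall_area = 0, void_volume = n * nzc * dx^2,
                             scaffold = NULL, defect = NULL, ring = NULL,
                             axisymmetric = FALSE), class = "flow_domain")
  } else {
    domain <- build_cavity_domain(n, L)
  }
  state <- initialize_flow(domain, flow_config(inlet_speed = 0))
  state$alpha <- rep(1, domain$nr * domain$nz)
  if (kind == "uniform") {
    state$u <- rep(U, (domain$nr + 1) * domain$nz)
  } else if (kind == "linear_shear") {
    zc <- (rep(seq_len(domain$nz), each = domain$nr + 1) - 0.5) * domain$dz
    state$u <- G * zc
  }
  state$u_max <- max(abs(state$u))
  list(domain = domain, state = state)
}
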