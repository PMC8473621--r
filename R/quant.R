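#' Intensity thresholds for radiograph classification
#'
#' On 8-bit grayscale radiographs the titanium scaffold saturates the
#' detector (intensity > 250, exclusive) while mineralising bone falls in
#' the band \[60, 180) — inclusive lower, exclusive upper.  Everything else
#' (void, soft tissue, background) is `other`.
#'
#' @param scaffold_min exclusive lower bound of the scaffold class.
#' @param bone_min inclusive lower bound of the bone class.
#' @param bone_max exclusive upper bound of the bone class.
#' @return object of class `quant_thresholds`.
#' @export
quant_thresholds <- function(scaffold_min = 250, bone_min = 60,
                             bone_max = 180) {
  stopifnot(0 <= bone_min, bone_min < bone_max, bone_max <= scaffold_min,
            scaffold_min <= 255)
  structure(list(scaffold_min = scaffold_min, bone_min = bone_min,
                 bone_max = bone_max), class = "quant_thresholds")
}

#' Read an 8-bit grayscale radiograph (PNG or TIFF)
#'
#' @param path image file path.
#' @return integer matrix of intensities 0..255 (rows = image rows).
#' @export
read_radiograph <- function(path) {
  if (!file.exists(path)) stop("no such image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of grayscale-as-RGB
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' Classify radiograph pixels into scaffold / bone / other
#'
#' @param image integer matrix of 8-bit intensities (0..255).
#' @param th a [quant_thresholds()].
#' @return integer matrix of class `label_image`: 0 other, 1 bone, 2 scaffold.
#' @export
classify_pixels <- function(image, th = quant_thresholds()) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (any(image < 0 | image > 255, na.rm = TRUE) ||
      any(image != round(image), na.rm = TRUE))
    stop("image must hold 8-bit integer intensities in 0..255")
  lab <- matrix(0L, nrow(image), ncol(image))
  lab[image >= th$bone_min & image < th$bone_max] <- 1L
  lab[image > th$scaffold_min] <- 2L
  class(lab) <- c("label_image", class(lab))
  lab
}

#' Partition an image into an n_rows x n_cols grid
#'
#' Equal integer strides; remainder pixels are absorbed by the last row and
#' column (e.g. 103 columns into 4 gives widths 25, 25, 25, 28).
#'
#' @param image matrix (only its dimensions are used).
#' @param n_rows,n_cols grid dimensions, >= 1.
#' @return data.frame of half-open pixel ranges per grid cell: `row`, `col`,
#'   `r0`, `r1`, `c0`, `c1` (1-based inclusive bounds).
#' @export
partition_grids <- function(image, n_rows, n_cols) {
  nr <- nrow(image); nc <- ncol(image)
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (n_rows > nr || n_cols > nc) stop("grid finer than the image")
  rs <- nr %/% n_rows; cs <- nc %/% n_cols
  g <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  g$r0 <- (g$row - 1) * rs + 1
  g$r1 <- ifelse(g$row == n_rows, nr, g$row * rs)
  g$c0 <- (g$col - 1) * cs + 1
  g$c1 <- ifelse(g$col == n_cols, nc, g$col * cs)
  g
}

#' Per-grid bone fraction P_b
#'
#' For each grid cell, \eqn{P_b = S_{bone} / (S_{all} - S_s)}: the bone
#' pixel count over the non-scaffold area.  A cell that is entirely
#' scaffold has an undefined `P_b`, reported as `NA` and excluded from
#' aggregates.
#'
#' @param labels a `label_image` from [classify_pixels()].
#' @param grids grid table from [partition_grids()].
#' @return the grid table extended with `S_all`, `S_s`, `S_bone`, `P_b`.
#' @export
bone_fraction <- function(labels, grids) {
  n <- nrow(grids)
  S_all <- S_s <- S_bone <- integer(n)
  for (i in seq_len(n)) {
    blk <- labels[grids$r0[i]:grids$r1[i], grids$c0[i]:grids$c1[i]]
    S_all[i] <- length(blk)
    S_s[i] <- sum(blk == 2L)
    S_bone[i] <- sum(blk == 1L)
  }
  out <- grids
  out$S_all <- S_all; out$S_s <- S_s; out$S_bone <- S_bone
  out$P_b <- ifelse(S_all - S_s > 0, S_bone / (S_all - S_s), NA_real_)
  out
}

#' Row / column profiles of the grid bone fractions
#'
#' Mean `P_b` per group of grid columns (horizontal profile) or rows
#' (vertical profile); undefined cells excluded.  `n_groups` pools adjacent
#' rows/columns, e.g. 5 groups mirror the five-column edge-to-middle
#' analysis.
#'
#' @param stats output of [bone_fraction()].
#' @param axis `"columns"` or `"rows"`.
#' @param n_groups number of groups to pool into (default: no pooling).
#' @return data.frame with `group`, `mean_P_b`, `n_cells`.
#' @export
grid_profiles <- function(stats, axis = c("columns", "rows"),
                          n_groups = NULL) {
  axis <- match.arg(axis)
  key <- if (axis == "columns") stats$col else stats$row
  nk <- max(key)
  if (is.null(n_groups)) n_groups <- nk
  stopifnot(n_groups >= 1, n_groups <= nk)
  grp <- ceiling(key * n_groups / nk)
  ok <- !is.na(stats$P_b)
  if (!any(ok)) stop("no defined P_b values to profile")
  agg <- stats::aggregate(stats$P_b[ok], list(group = grp[ok]),
                          FUN = mean)
  cnt <- stats::aggregate(rep(1, sum(ok)), list(group = grp[ok]), FUN = sum)
  data.frame(group = agg$group, mean_P_b = agg$x, n_cells = cnt$x)
}

#' @keywords internal
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  keep_r <- rs >= 1 & rs <= nr; keep_c <- cs >= 1 & cs <= nc
  out[which(keep_r), which(keep_c)] <- m[rs[keep_r], cs[keep_c]]
  out
}

#' Bone-scaffold contact percentage
#'
#' The interface is the scaffold perimeter: scaffold pixels with at least
#' one non-scaffold edge (4-connected) neighbour inside the image.  The
#' contact percentage is the share of interface pixels that touch at least
#' one bone pixel under the requested connectivity — 4-connected (edges
#' only) or 8-connected (edges and diagonals).  With the perimeter fixed,
#' the 8-connected percentage can never fall below the 4-connected one.
#' Out-of-image neighbours are ignored.
#'
#' @param labels a `label_image`.
#' @param connectivity 4 or 8.
#' @return object of class `contact_report`: `connectivity`,
#'   `interface_pixels`, `contact_pixels`, `percentage`, and the
#'   denominator convention.
#' @export
contact_percentage <- function(labels, connectivity = c(4, 8)) {
  connectivity <- match.arg(as.character(connectivity[1]), c("4", "8"))
  connectivity <- as.integer(connectivity)
  sc <- labels == 2L
  if (!any(sc)) stop("image contains no scaffold pixels")
  bone <- labels == 1L
  inb <- matrix(1L, nrow(labels), ncol(labels))
  n4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nd <- list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  non_sc_nb <- matrix(FALSE, nrow(labels), ncol(labels))
  bone_nb <- matrix(FALSE, nrow(labels), ncol(labels))
  for (o in n4) {
    non_sc_nb <- non_sc_nb |
      (shift_mat(!sc & inb > 0, o[1], o[2], FALSE) &
         shift_mat(inb, o[1], o[2], 0L) > 0)
    bone_nb <- bone_nb | shift_mat(bone, o[1], o[2], FALSE)
  }
  if (connectivity == 8) {
    for (o in nd) bone_nb <- bone_nb | shift_mat(bone, o[1], o[2], FALSE)
  }
  interface <- sc & non_sc_nb
  contact <- interface & bone_nb
  structure(list(connectivity = connectivity,
                 interface_pixels = sum(interface),
                 contact_pixels = sum(contact),
                 percentage = 100 * sum(contact) / sum(interface),
                 denominator = "scaffold perimeter (4-connected)"),
            class = "contact_report")
}

#' Quantify a batch of radiographs
#'
#' Full analysis path for one or more images: classify, grid, compute
#' per-grid bone fractions, profiles, and 4-/8-connected contact reports.
#' Optionally writes per-image CSV reports and a class-overlay PNG
#' (scaffold white, bone red, other dark) for visual QC.
#'
#' @param image_paths character vector of PNG/TIFF paths.
#' @param th a [quant_thresholds()].
#' @param n_rows,n_cols analysis grid (default 10 x 10).
#' @param output_dir optional report directory.
#' @return list per image with `grid_stats`, `profiles_cols`,
#'   `profiles_rows`, `contact4`, `contact8`, `summary` (one-row
#'   data.frame).
#' @export
run_quantification <- function(image_paths, th = quant_thresholds(),
                               n_rows = 10, n_cols = 10, output_dir = NULL) {
  out <- lapply(image_paths, function(p) {
    img <- if (is.character(p)) read_radiograph(p) else p
    lab <- classify_pixels(img, th)
    grids <- partition_grids(lab, n_rows, n_cols)
    stats <- bone_fraction(lab, grids)
    c4 <- contact_percentage(lab, 4)
    c8 <- contact_percentage(lab, 8)
    res <- list(
      grid_stats = stats,
      profiles_cols = grid_profiles(stats, "columns"),
      profiles_rows = grid_profiles(stats, "rows"),
      contact4 = c4, contact8 = c8,
      summary = data.frame(
        image = if (is.character(p)) basename(p) else "<matrix>",
        global_P_b = sum(stats$S_bone) / sum(stats$S_all - stats$S_s),
        contact_pct_4 = c4$percentage, contact_pct_8 = c8$percentage))
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      stem <- if (is.character(p))
        tools::file_path_sans_ext(basename(p)) else "image"
      utils::write.csv(stats, file.path(output_dir,
                                        paste0(stem, "_grids.csv")),
                       row.names = FALSE)
      utils::write.csv(res$profiles_cols,
                       file.path(output_dir, paste0(stem, "_cols.csv")),
                       row.names = FALSE)
      utils::write.csv(res$profiles_rows,
                       file.path(output_dir, paste0(stem, "_rows.csv")),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(connectivity = c(4, 8),
                   interface = c(c4$interface_pixels, c8$interface_pixels),
                   contact = c(c4$contact_pixels, c8$contact_pixels),
                   percentage = c(c4$percentage, c8$percentage),
                   denominator = c4$denominator),
        file.path(output_dir, paste0(stem, "_contact.csv")),
        row.names = FALSE)
      ov <- array(0, dim = c(nrow(lab), ncol(lab), 3))
      ov[, , 1] <- (lab == 2L) + 0.9 * (lab == 1L)
      ov[, , 2] <- (lab == 2L) + 0.15 * (lab == 0L)
      ov[, , 3] <- (lab == 2L) + 0.15 * (lab == 0L)
      png::writePNG(ov, file.path(output_dir, paste0(stem, "_overlay.png")))
    }
    res
  })
  names(out) <- vapply(seq_along(image_paths), function(i) {
    p <- image_paths[[i]]
    if (is.character(p)) basename(p) else paste0("image", i)
  }, "")
  out
}
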