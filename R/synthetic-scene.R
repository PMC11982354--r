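# Synthetic microscopy scenes with known ground truth: two-channel
# fluorescence fields (nuclei + lipid-droplet channel) and stained-area
# images for migration/clonogenic-style assays.
#
# Coordinate convention (shared with the imaging module): row-major,
# 0-based, pixel centers at integer coordinates; `x` is the column index,
# `y` the row index.

# paint an anti-aliased disk onto `img` (max composition); the intensity
# ramps linearly over 1 px at the rim to emulate partial-volume edges
paint_disk <- function(img, y, x, r, intensity) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(0, floor(y - r - 1)); r1 <- min(nr - 1, ceiling(y + r + 1))
  c0 <- max(0, floor(x - r - 1)); c1 <- min(nc - 1, ceiling(x + r + 1))
  ri <- (r0:r1) + 1L; ci <- (c0:c1) + 1L
  dy <- (r0:r1) - y; dx <- (c0:c1) - x
  d <- sqrt(outer(dy^2, dx^2, "+"))
  cov <- clip(r + 0.5 - d, 0, 1)
  img[ri, ci] <- pmax(img[ri, ci], intensity * cov)
  img
}

disk_mask_indices <- function(nr, nc, y, x, r) {
  r0 <- max(0, floor(y - r)); r1 <- min(nr - 1, ceiling(y + r))
  c0 <- max(0, floor(x - r)); c1 <- min(nc - 1, ceiling(x + r))
  dy <- (r0:r1) - y; dx <- (c0:c1) - x
  inside <- outer(dy^2, dx^2, "+") <= r^2
  cbind(row = rep(r0:r1, times = length(dx))[inside] + 1L,
        col = rep(c0:c1, each = length(dy))[inside] + 1L)
}

# rejection-sample `n` centers with per-object radii such that rims stay
# `sep` apart and objects fit in the frame
place_disks <- function(n, height, width, radii, sep, max_tries = 500L,
                        restarts = 20L) {
  for (attempt in seq_len(restarts)) {
    ys <- numeric(0); xs <- numeric(0)
    ok <- TRUE
    for (i in seq_len(n)) {
      r <- radii[i]
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        y <- runif(1, r + 1, height - r - 2)
        x <- runif(1, r + 1, width - r - 2)
        if (i == 1 ||
            all(sqrt((ys - y)^2 + (xs - x)^2) >=
                  r + radii[seq_len(i - 1)] + sep)) {
          ys <- c(ys, y); xs <- c(xs, x); placed <- TRUE
          break
        }
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(data.frame(y = ys, x = xs, r = radii[seq_len(n)]))
  }
  stop(sprintf(paste("cannot place %d objects with min_separation =",
                     "%g in a %dx%d frame"), n, sep, height, width),
       call. = FALSE)
}

#' Specification of a synthetic two-channel fluorescence scene
#'
#' Emulates a confocal field with Hoechst-stained nuclei (channel 1) and
#' BODIPY-stained lipid droplets over a dim cell body (channel 2). Cells
#' are disjoint disks with a concentric nucleus; droplets lie in the
#' cytoplasmic annulus and do not overlap. All structures are rendered as
#' anti-aliased disks (1 px intensity ramp at the rim) plus additive
#' Gaussian noise.
#'
#' @param height,width frame size in pixels.
#' @param n_cells number of cells (0 gives a noise-only scene).
#' @param nucleus_radius,cell_radius,droplet_radius pixel ranges
#'   (length-2, min <= max); nuclei must fit inside cells with room for the
#'   droplet annulus.
#' @param droplets_per_cell integer range of droplets per cell.
#' @param intensity list of levels in \[0,1\]: `background`, `nucleus`,
#'   `cell` (cytoplasm in the droplet channel), `droplet`.
#' @param gaussian_noise_sd additive noise standard deviation.
#' @param min_separation minimum rim-to-rim distance between cells (px).
#' @param seed RNG seed.
#' @return validated list of class `scene_spec`.
#' @export
scene_spec <- function(height = 192, width = 192, n_cells = 6,
                       nucleus_radius = c(6, 9), cell_radius = c(20, 28),
                       droplet_radius = c(2, 3),
                       droplets_per_cell = c(2, 6),
                       intensity = list(background = 0.05, nucleus = 0.85,
                                        cell = 0.25, droplet = 0.9),
                       gaussian_noise_sd = 0.02, min_separation = 6,
                       seed = 1) {
  rng_ok <- function(r) length(r) == 2 && r[1] > 0 && r[1] <= r[2]
  assert_that(rng_ok(nucleus_radius) && rng_ok(cell_radius) &&
                rng_ok(droplet_radius),
              "radius ranges must be positive and increasing")
  assert_that(nucleus_radius[2] < cell_radius[1],
              "nucleus_radius must be smaller than cell_radius")
  assert_that(nucleus_radius[2] + 2 * droplet_radius[2] + 2 <
                cell_radius[1],
              "no room for droplets between nucleus and cell rim")
  assert_that(n_cells >= 0 && height > 4 * cell_radius[2] &&
                width > 4 * cell_radius[2],
              "frame too small for the requested cell size")
  assert_that(gaussian_noise_sd >= 0 && min_separation >= 0,
              "noise sd and min_separation must be >= 0")
  structure(list(height = height, width = width, n_cells = n_cells,
                 nucleus_radius = nucleus_radius,
                 cell_radius = cell_radius,
                 droplet_radius = droplet_radius,
                 droplets_per_cell = droplets_per_cell,
                 intensity = intensity,
                 gaussian_noise_sd = gaussian_noise_sd,
                 min_separation = min_separation, seed = seed),
            class = "scene_spec")
}

#' Generate a synthetic fluorescence scene with ground truth
#'
#' @param spec a [scene_spec()].
#' @return list of class `fluor_scene`:
#'   `image` (list of matrices `nuclei`, `droplets` in \[0,1\]) and `truth`
#'   (list with `nuclei` data.frame (cell, y, x, r), `cell_labels`
#'   ground-truth label matrix, `cells` data.frame (cell, y, x, r), and
#'   `droplets` data.frame (cell, y, x, r)).
#' @export
gen_fluor_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed + 606L, {
    h <- spec$height; w <- spec$width
    ch_nuc <- matrix(spec$intensity$background, h, w)
    ch_drop <- matrix(spec$intensity$background, h, w)
    labels <- matrix(0L, h, w)
    cells <- data.frame(cell = integer(0), y = numeric(0), x = numeric(0),
                        r = numeric(0))
    nuclei <- cells
    droplets <- cells
    if (spec$n_cells > 0) {
      cr <- runif(spec$n_cells, spec$cell_radius[1], spec$cell_radius[2])
      pos <- place_disks(spec$n_cells, h, w, cr, spec$min_separation)
      cells <- data.frame(cell = seq_len(spec$n_cells), y = pos$y,
                          x = pos$x, r = pos$r)
      nr_ <- runif(spec$n_cells, spec$nucleus_radius[1],
                   spec$nucleus_radius[2])
      nuclei <- data.frame(cell = cells$cell, y = cells$y, x = cells$x,
                           r = nr_)
      dpc <- sample(seq(spec$droplets_per_cell[1],
                        spec$droplets_per_cell[2]),
                    spec$n_cells, replace = TRUE)
      drop_sep <- 2 * spec$droplet_radius[2] + 4  # resolvable by top-hat
      for (i in seq_len(spec$n_cells)) {
        idx <- disk_mask_indices(h, w, cells$y[i], cells$x[i], cells$r[i])
        labels[idx] <- i
        ch_drop <- paint_disk(ch_drop, cells$y[i], cells$x[i], cells$r[i],
                              spec$intensity$cell)
        ch_nuc <- paint_disk(ch_nuc, nuclei$y[i], nuclei$x[i], nuclei$r[i],
                             spec$intensity$nucleus)
        dy <- numeric(0); dx <- numeric(0); dr <- numeric(0)
        for (j in seq_len(dpc[i])) {
          r <- runif(1, spec$droplet_radius[1], spec$droplet_radius[2])
          inner <- nuclei$r[i] + r + 1
          outer <- cells$r[i] - r - 1
          placed <- FALSE
          for (k in seq_len(500L)) {
            rad <- sqrt(runif(1, (inner / outer)^2, 1)) * outer
            th <- runif(1, 0, 2 * pi)
            y <- cells$y[i] + rad * sin(th)
            x <- cells$x[i] + rad * cos(th)
            if (length(dy) == 0 ||
                all(sqrt((dy - y)^2 + (dx - x)^2) >= drop_sep)) {
              dy <- c(dy, y); dx <- c(dx, x); dr <- c(dr, r)
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            stop(sprintf(paste("cannot place %d droplets per cell with",
                               "separation %g px; reduce",
                               "droplets_per_cell"),
                         dpc[i], drop_sep), call. = FALSE)
          }
        }
        for (j in seq_along(dy)) {
          ch_drop <- paint_disk(ch_drop, dy[j], dx[j], dr[j],
                                spec$intensity$droplet)
        }
        if (length(dy)) {
          droplets <- rbind(droplets,
                            data.frame(cell = i, y = dy, x = dx, r = dr))
        }
      }
    }
    if (spec$gaussian_noise_sd > 0) {
      ch_nuc <- clip(ch_nuc + rnorm(h * w, 0, spec$gaussian_noise_sd),
                     0, 1)
      ch_drop <- clip(ch_drop + rnorm(h * w, 0, spec$gaussian_noise_sd),
                      0, 1)
    }
    structure(list(image = list(nuclei = ch_nuc, droplets = ch_drop),
                   truth = list(nuclei = nuclei, cells = cells,
                                cell_labels = labels, droplets = droplets),
                   spec = spec),
              class = "fluor_scene")
  })
}

#' Specification of a synthetic stained-area image
#'
#' Dark "stained" blobs (crystal-violet-like) on a light background, used
#' to validate area-fraction quantification.
#'
#' @param height,width frame size in pixels.
#' @param blob_radius pixel range of stain blob radii.
#' @param intensity list with `background` (light) and `stain` (dark)
#'   levels in \[0,1\].
#' @param gaussian_noise_sd additive noise standard deviation.
#' @param seed RNG seed.
#' @return validated list of class `stain_spec`.
#' @export
stain_spec <- function(height = 220, width = 220, blob_radius = c(4, 9),
                       intensity = list(background = 0.9, stain = 0.15),
                       gaussian_noise_sd = 0.02, seed = 1) {
  assert_that(length(blob_radius) == 2 && blob_radius[1] > 0 &&
                blob_radius[1] <= blob_radius[2],
              "blob_radius must be a positive increasing range")
  assert_that(intensity$stain < intensity$background,
              "stain must be darker than background")
  structure(list(height = height, width = width, blob_radius = blob_radius,
                 intensity = intensity,
                 gaussian_noise_sd = gaussian_noise_sd, seed = seed),
            class = "stain_spec")
}

#' Generate a stained-area image with exact covered-fraction ground truth
#'
#' Random dark disks are added until the covered pixel fraction reaches
#' `target_fraction`; the truth records the exact realized fraction
#' (covered pixels / total pixels), which can overshoot the target by at
#' most one blob's area.
#'
#' @param target_fraction desired covered fraction in \[0, 1\].
#' @param spec a [stain_spec()].
#' @return list of class `stained_image`: `image` (matrix in \[0,1\]) and
#'   `truth` (list with the binary `mask` and `covered_fraction`).
#' @export
gen_stained_image <- function(target_fraction, spec = stain_spec()) {
  stopifnot(inherits(spec, "stain_spec"))
  assert_that(is_scalar_in(target_fraction, 0, 1),
              "target_fraction must lie in [0,1]")
  with_seed(spec$seed + 707L, {
    h <- spec$height; w <- spec$width
    mask <- matrix(FALSE, h, w)
    if (target_fraction >= 1) {
      mask[] <- TRUE
    } else if (target_fraction > 0) {
      while (mean(mask) < target_fraction) {
        r <- runif(1, spec$blob_radius[1], spec$blob_radius[2])
        y <- runif(1, 0, h - 1); x <- runif(1, 0, w - 1)
        mask[disk_mask_indices(h, w, y, x, r)] <- TRUE
      }
    }
    img <- matrix(spec$intensity$background, h, w)
    img[mask] <- spec$intensity$stain
    if (spec$gaussian_noise_sd > 0) {
      img <- clip(img + rnorm(h * w, 0, spec$gaussian_noise_sd), 0, 1)
    }
    structure(list(image = img,
                   truth = list(mask = mask, covered_fraction = mean(mask)),
                   spec = spec),
              class = "stained_image")
  })
}
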