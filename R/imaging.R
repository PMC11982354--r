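# Microscopy quantification: per-cell lipid-droplet counting (watershed
# nuclei -> geodesic Voronoi cytoplasm -> top-hat dot segmentation) and
# stained-area-fraction assays.
#
# Morphological primitives (Gaussian blur, grayscale opening, distance
# map, connected-component labeling) are delegated to EBImage; the
# propagation, thresholding and quantification logic is implemented here.
#
# Coordinates are row-major and 0-based with pixel centers at integer
# coordinates; `x` is the column index and `y` the row index.

as_matrix <- function(img) {
  if (inherits(img, "Image")) img <- EBImage::imageData(img)
  if (length(dim(img)) > 2) stop("expected a single-channel image")
  as.matrix(img)
}

# map positive labels to contiguous 1..n (0 stays background)
relabel_mask <- function(m) {
  u <- sort(unique(m[m > 0]))
  if (length(u) == 0) return(matrix(0L, nrow(m), ncol(m)))
  out <- matrix(0L, nrow(m), ncol(m))
  out[m > 0] <- match(m[m > 0], u)
  out
}

# per-label centroids in 0-based (y, x) coordinates
label_centroids <- function(m) {
  idx <- which(m > 0)
  if (length(idx) == 0) {
    return(data.frame(label = integer(0), y = numeric(0), x = numeric(0)))
  }
  lab <- m[idx]
  rows <- (idx - 1) %% nrow(m)
  cols <- (idx - 1) %/% nrow(m)
  data.frame(label = sort(unique(lab)),
             y = as.vector(tapply(rows, lab, mean)),
             x = as.vector(tapply(cols, lab, mean)))
}

#' Rescale image intensities to \[0,1\]
#'
#' Linear rescale between the 1st and 99th intensity percentiles, clipped,
#' making downstream thresholds robust to a few saturated pixels. Affine
#' transformations of the input yield identical output.
#'
#' @param image numeric matrix (any intensity scale); must not be constant.
#' @return matrix in \[0,1\].
#' @export
normalize_intensity <- function(image) {
  image <- as_matrix(image)
  rng <- range(image)
  assert_that(diff(rng) > 0, "cannot normalize a constant image")
  p <- stats::quantile(image, c(0.01, 0.99), names = FALSE)
  if (p[2] <= p[1]) p <- rng
  clip((image - p[1]) / (p[2] - p[1]), 0, 1)
}

#' Sigmoidal intensity transform
#'
#' `s(x) = 1 / (1 + exp(-gain * (x - midpoint)))`; strictly increasing, so
#' pixel intensity order is preserved.
#'
#' @param image numeric matrix in \[0,1\].
#' @param midpoint inflection point (defaults to the Otsu threshold of the
#'   image, giving parameter-free contrast enhancement before
#'   binarization).
#' @param gain slope at the midpoint; must be > 0.
#' @return matrix in (0,1).
#' @export
sigmoid_transform <- function(image, midpoint = otsu_threshold(image),
                              gain = 10) {
  image <- as_matrix(image)
  assert_that(gain > 0, "gain must be > 0")
  1 / (1 + exp(-gain * (image - midpoint)))
}

#' Otsu threshold over a 256-bin histogram
#'
#' Returns the threshold maximizing the between-class variance of the
#' foreground/background split, searched over the 256 equal-width bin
#' edges of \[0,1\]. Pixels `>= t` are foreground.
#'
#' @param image numeric matrix with values in \[0,1\].
#' @param levels number of histogram bins (default 256).
#' @return scalar threshold in (0,1).
#' @export
otsu_threshold <- function(image, levels = 256L) {
  x <- as.vector(as_matrix(image))
  assert_that(all(x >= 0 & x <= 1), "image must be scaled to [0,1]")
  h <- tabulate(pmin(floor(x * levels), levels - 1) + 1L, nbins = levels)
  w <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(w)
  mu0 <- cumsum(w * mids)
  mu_t <- mu0[levels]
  # between-class variance for thresholds at bin edges k/levels
  k <- seq_len(levels - 1)
  denom <- w0[k] * (1 - w0[k])
  bcv <- ifelse(denom > 0, (mu_t * w0[k] - mu0[k])^2 / denom, -Inf)
  k[which.max(bcv)] / levels
}

#' Binarize an image
#'
#' @param image numeric matrix in \[0,1\].
#' @param method `"otsu"` or a fixed numeric threshold.
#' @return logical mask; pixels `>= t` are foreground.
#' @export
threshold_mask <- function(image, method = "otsu") {
  image <- as_matrix(image)
  t <- if (identical(method, "otsu")) otsu_threshold(image) else {
    assert_that(is.numeric(method) && length(method) == 1,
                "method must be 'otsu' or a numeric threshold")
    method
  }
  image >= t
}

#' Detect and label nuclei by seeded watershed
#'
#' Gaussian smoothing, Otsu binarization, then splitting of touching
#' nuclei: seeds are the regional maxima of the distance transform (at
#' least `min_distance` apart) and mask pixels are assigned to the
#' geodesically nearest seed. Components smaller than `min_area` are
#' removed. A blank image yields an empty mask, not an error.
#'
#' @param nucleus_channel numeric matrix in \[0,1\] (nucleus stain).
#' @param smoothing_sigma Gaussian sigma in px (default 2).
#' @param min_distance minimum seed separation in px (default 10).
#' @param min_area minimum nucleus area in px (default 50).
#' @return integer label matrix (0 background, labels 1..n).
#' @export
detect_nuclei <- function(nucleus_channel, smoothing_sigma = 2,
                          min_distance = 10, min_area = 50) {
  img <- as_matrix(nucleus_channel)
  empty <- matrix(0L, nrow(img), ncol(img))
  if (diff(range(img)) == 0) return(empty)
  sm <- as_matrix(EBImage::gblur(EBImage::Image(img),
                                 sigma = smoothing_sigma))
  sm <- clip(sm, 0, 1)
  mask <- sm >= otsu_threshold(sm)
  if (!any(mask)) return(empty)
  dm <- as_matrix(EBImage::distmap(EBImage::Image(mask)))
  brush <- EBImage::makeBrush(2L * floor(min_distance) + 1L, "disc")
  dil <- as_matrix(EBImage::dilate(EBImage::Image(dm), brush))
  peaks <- mask & dm > 0 & dm >= dil - 1e-7
  peak_lab <- as_matrix(EBImage::bwlabel(EBImage::Image(peaks)))
  cent <- label_centroids(peak_lab)
  if (nrow(cent) == 0) return(empty)
  seeds <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_len(nrow(cent))) {
    r <- round(cent$y[i]) + 1L; c <- round(cent$x[i]) + 1L
    if (!mask[r, c]) {
      # plateau centroid fell outside the mask: use the deepest pixel
      pix <- which(peak_lab == cent$label[i])
      pix <- pix[which.max(dm[pix])]
      r <- (pix - 1) %% nrow(img) + 1L
      c <- (pix - 1) %/% nrow(img) + 1L
    }
    seeds[r, c] <- i
  }
  lab <- cpp_propagate(matrix(0, nrow(img), ncol(img)), seeds, mask,
                       lambda = 1)$labels
  areas <- tabulate(lab[lab > 0])
  lab[lab %in% which(areas < min_area)] <- 0L
  relabel_mask(lab)
}

#' Propagate seed labels through a mask (geodesic Voronoi)
#'
#' Assigns every in-mask pixel to the seed minimizing a geodesic cost that
#' mixes spatial distance with intensity change: each step of length `s`
#' (1 axial, sqrt(2) diagonal) costs
#' `s * sqrt((lambda + dI^2) / (lambda + mean dI^2))`, where `dI` is the
#' intensity difference across the step and the mean is taken over in-mask
#' neighbor pairs. Large `lambda` (or a uniform image) reduces the cost to
#' pure spatial distance, i.e. the geodesic nearest-seed (Voronoi)
#' partition; small `lambda` makes boundaries follow intensity ridges.
#' Pixels outside `cyto_mask` stay 0; every seed keeps its own pixels.
#'
#' @param seeds integer label matrix of seeds (e.g. [detect_nuclei()]
#'   output). Seeds outside the mask are clipped with a warning.
#' @param intensity numeric matrix guiding the propagation (droplet/cell
#'   channel).
#' @param cyto_mask logical matrix delimiting the region to segment.
#' @param lambda positive regularization weight (default 0.05).
#' @return integer label matrix of propagated cell regions.
#' @export
propagate_cytoplasm <- function(seeds, intensity, cyto_mask,
                                lambda = 0.05) {
  seeds <- as_matrix(seeds); intensity <- as_matrix(intensity)
  cyto_mask <- as_matrix(cyto_mask) > 0
  assert_that(all(dim(seeds) == dim(intensity)) &&
                all(dim(seeds) == dim(cyto_mask)),
              "seeds, intensity and cyto_mask must share dimensions")
  assert_that(lambda > 0, "lambda must be > 0")
  outside <- seeds > 0 & !cyto_mask
  if (any(outside)) {
    warning(sprintf("%d seed pixel(s) outside cyto_mask were clipped",
                    sum(outside)))
    seeds[outside] <- 0L
  }
  assert_that(any(seeds > 0), "no seeds inside the mask")
  storage.mode(seeds) <- "integer"
  cpp_propagate(intensity, seeds, cyto_mask, lambda)$labels
}

#' White top-hat filter
#'
#' Image minus its grayscale opening with a disk structuring element;
#' isolates bright features smaller than the element. Output is
#' non-negative and bounded by the input.
#'
#' @param image numeric matrix.
#' @param radius structuring-element radius in px (>= 1).
#' @return matrix of the same shape.
#' @export
tophat <- function(image, radius) {
  image <- as_matrix(image)
  assert_that(radius >= 1, "radius must be >= 1")
  kern <- EBImage::makeBrush(2L * floor(radius) + 1L, "disc")
  opened <- as_matrix(EBImage::opening(EBImage::Image(image), kern))
  pmax(image - opened, 0)
}

#' Segment lipid-droplet dots within cells
#'
#' Top-hat filtering (structuring element larger than a droplet), then a
#' sigmoidal transform centered on the Otsu threshold of the top-hat
#' image, binarization at 0.5, and connected-component labeling. Dots
#' smaller than `min_dot_area` or whose centroid lies outside every cell
#' are discarded.
#'
#' @param droplet_channel numeric matrix in \[0,1\].
#' @param cell_labels integer label matrix of cell regions
#'   ([propagate_cytoplasm()] output).
#' @param se_radius top-hat structuring-element radius (default 4 px).
#' @param gain sigmoid gain (default 10).
#' @param min_dot_area minimum dot area in px (default 2).
#' @return integer label matrix of droplet dots.
#' @export
segment_droplets <- function(droplet_channel, cell_labels, se_radius = 4,
                             gain = 10, min_dot_area = 2) {
  img <- as_matrix(droplet_channel)
  cell_labels <- as_matrix(cell_labels)
  empty <- matrix(0L, nrow(img), ncol(img))
  th <- clip(tophat(img, se_radius), 0, 1)
  if (diff(range(th)) == 0) return(empty)
  mid <- otsu_threshold(th)
  mask <- sigmoid_transform(th, mid, gain) >= 0.5
  lab <- as_matrix(EBImage::bwlabel(EBImage::Image(mask)))
  if (max(lab) == 0) return(empty)
  areas <- tabulate(lab[lab > 0])
  lab[lab %in% which(areas < min_dot_area)] <- 0L
  cent <- label_centroids(lab)
  if (nrow(cent) > 0) {
    inside <- cell_labels[cbind(round(cent$y) + 1L,
                                round(cent$x) + 1L)] > 0
    drop_ids <- cent$label[!inside]
    lab[lab %in% drop_ids] <- 0L
  }
  relabel_mask(lab)
}

#' Per-cell droplet quantification
#'
#' Each dot is assigned to the cell containing its centroid. Per cell:
#' dot count, summed dot pixel area, cytoplasm (cell region) pixel area,
#' and the two normalized ratios. Cells with zero area are excluded with
#' a warning.
#'
#' @param cell_labels,dot_labels integer label matrices of equal shape.
#' @param view_field optional identifier stored alongside the metrics.
#' @return data.frame of class `cell_quant`: `cell`, `n_droplets`,
#'   `droplet_area`, `cell_area`, `count_per_area`, `area_ratio`,
#'   `view_field`.
#' @export
quantify_cells <- function(cell_labels, dot_labels, view_field = 1L) {
  cell_labels <- as_matrix(cell_labels); dot_labels <- as_matrix(dot_labels)
  assert_that(all(dim(cell_labels) == dim(dot_labels)),
              "label masks must share shape")
  n_cells <- max(cell_labels)
  if (n_cells == 0) {
    return(structure(data.frame(cell = integer(0), n_droplets = integer(0),
                                droplet_area = numeric(0),
                                cell_area = numeric(0),
                                count_per_area = numeric(0),
                                area_ratio = numeric(0),
                                view_field = character(0)),
                     class = c("cell_quant", "data.frame")))
  }
  cell_area <- tabulate(cell_labels[cell_labels > 0], nbins = n_cells)
  dot_area <- if (max(dot_labels) > 0) {
    tabulate(dot_labels[dot_labels > 0], nbins = max(dot_labels))
  } else integer(0)
  counts <- integer(n_cells)
  areas <- numeric(n_cells)
  cent <- label_centroids(dot_labels)
  for (i in seq_len(nrow(cent))) {
    cell <- cell_labels[round(cent$y[i]) + 1L, round(cent$x[i]) + 1L]
    if (cell > 0) {
      counts[cell] <- counts[cell] + 1L
      areas[cell] <- areas[cell] + dot_area[cent$label[i]]
    }
  }
  keep <- cell_area > 0
  if (any(!keep)) warning(sprintf("%d cell(s) with zero area excluded",
                                  sum(!keep)))
  out <- data.frame(cell = which(keep), n_droplets = counts[keep],
                    droplet_area = areas[keep], cell_area = cell_area[keep],
                    count_per_area = counts[keep] / cell_area[keep],
                    area_ratio = areas[keep] / cell_area[keep],
                    view_field = rep(as.character(view_field), sum(keep)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_quant", "data.frame")
  out
}

#' Summarize per-cell metrics by view field and condition
#'
#' Cell metrics are averaged within each view field, then across view
#' fields per condition (mean and SD); fold changes are reported against
#' the control condition's mean.
#'
#' @param quants data.frame with columns `condition`, `view_field`, and
#'   `value` (one metric per call, e.g. `count_per_area`).
#' @param control name of the control condition (default: first condition
#'   in the data).
#' @return data.frame: `condition`, `n_fields`, `mean`, `sd`,
#'   `fold_change`.
#' @export
summarize_condition <- function(quants, control = NULL) {
  assert_that(all(c("condition", "view_field", "value") %in% names(quants)),
              "quants needs columns condition, view_field, value")
  assert_that(nrow(quants) > 0, "no measurements supplied")
  fm <- stats::aggregate(value ~ condition + view_field, data = quants,
                         FUN = mean)
  agg <- stats::aggregate(value ~ condition, data = fm,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  out <- data.frame(condition = agg$condition,
                    n_fields = agg$value[, "n"],
                    mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"],
                    stringsAsFactors = FALSE)
  if (is.null(control)) control <- quants$condition[1]
  assert_that(control %in% out$condition,
              "control condition '%s' not present", control)
  ctrl_mean <- out$mean[out$condition == control]
  assert_that(ctrl_mean != 0, "control mean is zero; fold change undefined")
  out$fold_change <- out$mean / ctrl_mean
  out
}

#' Stained-area fraction of an image
#'
#' Quantifies migration/clonogenic-style assays: the ratio between the
#' stained surface and the image surface. The image is converted to
#' grayscale (luminance) if RGB, percentile-normalized, optionally
#' inverted (dark stain on light background), sigmoid-enhanced around the
#' Otsu threshold and binarized; the fraction of foreground pixels is
#' returned. Constant images short-circuit to 0 or 1 by comparing the
#' (inverted) level to 0.5.
#'
#' @param image numeric matrix, or array with 3 channels (RGB).
#' @param invert `TRUE` when the stain is darker than the background.
#' @param gain sigmoid gain (default 10).
#' @return scalar fraction in \[0,1\].
#' @export
area_fraction <- function(image, invert = TRUE, gain = 10) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (length(dim(image)) == 3) {
    assert_that(dim(image)[3] == 3, "expected an RGB image")
    image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] +
      0.0722 * image[, , 3]
  }
  image <- as_matrix(image)
  if (diff(range(image)) == 0) {
    lev <- if (invert) 1 - image[1] else image[1]
    return(as.numeric(lev >= 0.5))
  }
  x <- normalize_intensity(image)
  if (invert) x <- 1 - x
  mask <- sigmoid_transform(x, otsu_threshold(x), gain) >= 0.5
  mean(mask)
}

#' Combine view-field fractions into per-condition means
#'
#' Field measurements are averaged within each replicate, then replicate
#' means are averaged per condition (each replicate weighs equally
#' regardless of its number of view fields).
#'
#' @param values numeric measurements (e.g. [area_fraction()] outputs).
#' @param replicate replicate identifier per measurement.
#' @param condition condition label per measurement (a single label is
#'   recycled).
#' @return data.frame: `condition`, `n_replicates`, `mean`.
#' @export
combine_replicates <- function(values, replicate,
                               condition = "condition") {
  assert_that(length(values) >= 1, "no measurements supplied")
  if (length(condition) == 1) condition <- rep(condition, length(values))
  assert_that(length(replicate) == length(values) &&
                length(condition) == length(values),
              "values, replicate and condition must be matched")
  df <- data.frame(value = values, replicate = replicate,
                   condition = condition)
  rm_ <- stats::aggregate(value ~ condition + replicate, data = df,
                          FUN = mean)
  agg <- stats::aggregate(value ~ condition, data = rm_,
                          FUN = function(v) c(n = length(v),
                                              mean = mean(v)))
  data.frame(condition = agg$condition,
             n_replicates = agg$value[, "n"],
             mean = agg$value[, "mean"], stringsAsFactors = FALSE)
}

#' Quantify lipid droplets per cell in a two-channel scene
#'
#' The full per-field pipeline: nuclei detection on the nucleus channel
#' ([detect_nuclei()]), a cytoplasm mask from the Otsu-binarized smoothed
#' droplet channel, geodesic Voronoi propagation of the nucleus seeds
#' ([propagate_cytoplasm()]), top-hat droplet segmentation
#' ([segment_droplets()]), and per-cell quantification
#' ([quantify_cells()]).
#'
#' @param nuclei_channel,droplet_channel numeric matrices in \[0,1\].
#' @param view_field identifier stored in the per-cell table.
#' @param smoothing_sigma,min_distance,min_area nuclei-detection
#'   parameters.
#' @param lambda propagation regularization.
#' @param se_radius,gain,min_dot_area droplet-segmentation parameters.
#' @return list: `cell_labels`, `dot_labels`, `quant` (a `cell_quant`
#'   data.frame).
#' @export
quantify_ld_scene <- function(nuclei_channel, droplet_channel,
                              view_field = 1L, smoothing_sigma = 2,
                              min_distance = 10, min_area = 50,
                              lambda = 0.05, se_radius = 4, gain = 10,
                              min_dot_area = 2) {
  nuclei <- detect_nuclei(nuclei_channel, smoothing_sigma, min_distance,
                          min_area)
  drop_ch <- as_matrix(droplet_channel)
  if (max(nuclei) == 0) {
    empty <- matrix(0L, nrow(drop_ch), ncol(drop_ch))
    return(list(cell_labels = empty, dot_labels = empty,
                quant = quantify_cells(empty, empty, view_field)))
  }
  sm <- clip(as_matrix(EBImage::gblur(EBImage::Image(drop_ch),
                                      sigma = smoothing_sigma)), 0, 1)
  cyto_mask <- (sm >= otsu_threshold(sm)) | nuclei > 0
  cell_labels <- propagate_cytoplasm(nuclei, drop_ch, cyto_mask, lambda)
  dot_labels <- segment_droplets(drop_ch, cell_labels, se_radius, gain,
                                 min_dot_area)
  list(cell_labels = cell_labels, dot_labels = dot_labels,
       quant = quantify_cells(cell_labels, dot_labels, view_field))
}

#' Read a TIFF/PNG image as a list of channel matrices
#'
#' @param path image file readable by EBImage (8/16-bit TIFF or PNG).
#' @return list of numeric matrices in \[0,1\], one per channel/frame.
#' @export
read_image_channels <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2) return(list(EBImage::imageData(img)))
  lapply(seq_len(d[3]), function(k) EBImage::imageData(img)[, , k])
}

#' Write a label mask as a 16-bit TIFF
#'
#' Labels are stored as `label / 65535` intensities so that up to 65535
#' objects round-trip exactly at 16-bit depth.
#'
#' @param labels integer label matrix.
#' @param path output path (`.tif`).
#' @export
write_label_mask <- function(labels, path) {
  labels <- as_matrix(labels)
  assert_that(max(labels) <= 65535, "too many labels for 16-bit storage")
  EBImage::writeImage(EBImage::Image(labels / 65535), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}
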