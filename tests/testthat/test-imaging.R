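# microscopy pipeline: intensity transforms, thresholding, segmentation,
# propagation, and quantification

test_that("normalize_intensity rescales between the 1st/99th percentiles", {
  ramp <- matrix(seq(0, 10, length.out = 400), 20, 20)
  nm <- normalize_intensity(ramp)
  p <- quantile(ramp, c(0.01, 0.99), names = FALSE)
  expect_equal(range(nm), c(0, 1))
  expect_equal(nm[ramp <= p[1]], rep(0, sum(ramp <= p[1])))
  expect_equal(nm[ramp >= p[2]], rep(1, sum(ramp >= p[2])))
  # affine invariance
  expect_equal(normalize_intensity(3 * ramp + 7), nm, tolerance = 1e-12)
  expect_error(normalize_intensity(matrix(1, 5, 5)), "constant")
})

test_that("sigmoid_transform is centered and order-preserving", {
  img <- matrix(runif(100), 10, 10)
  s <- sigmoid_transform(img, midpoint = 0.3, gain = 10)
  expect_equal(sigmoid_transform(matrix(0.3, 2, 2), 0.3, 5),
               matrix(0.5, 2, 2))
  expect_equal(order(as.vector(s)), order(as.vector(img)))
  expect_error(sigmoid_transform(img, 0.5, gain = -1), "gain")
})

test_that("otsu_threshold separates a bimodal image and matches brute force", {
  img <- matrix(rep(c(0.1, 0.9), each = 50), 10, 10)
  t <- otsu_threshold(img)
  expect_gt(t, 0.1); expect_lte(t, 0.9)
  expect_equal(as.vector(table(img >= t)), c(50L, 50L))
  # exhaustive 256-threshold search oracle (bin-center values so the
  # histogram is lossless)
  set.seed(61)
  for (i in 1:5) {
    vals <- (sample(0:255, 300, replace = TRUE) + 0.5) / 256
    x <- matrix(vals, 15, 20)
    expect_equal(otsu_threshold(x), brute_otsu(x), tolerance = 1e-12)
  }
})

test_that("threshold_mask applies fixed and Otsu thresholds", {
  img <- matrix(runif(64), 8, 8)
  expect_equal(threshold_mask(img, 0.5), img >= 0.5)
  expect_equal(threshold_mask(img, "otsu"),
               img >= otsu_threshold(img))
})

test_that("tophat removes large structures and keeps small peaks", {
  flat <- matrix(0.4, 30, 30)
  expect_equal(tophat(flat, 5), matrix(0, 30, 30))
  # small bright disk (r = 2) survives a r = 5 top-hat at full amplitude
  img <- methscreen:::paint_disk(matrix(0.1, 40, 40), 20, 20, 2, 0.9)
  th <- tophat(img, 5)
  expect_equal(max(th), 0.9 - 0.1, tolerance = 1e-6)
  # large disk (r = 15) is mostly flattened away
  img2 <- methscreen:::paint_disk(matrix(0.1, 60, 60), 30, 30, 15, 0.9)
  th2 <- tophat(img2, 5)
  expect_lt(max(th2[25:35, 25:35]), 1e-6)
  expect_true(all(th2 >= 0) && all(th2 <= img2 + 1e-12))
})

test_that("uniform-intensity propagation equals the Dijkstra oracle", {
  set.seed(67)
  for (i in 1:3) {
    mask <- matrix(TRUE, 32, 32)
    # carve a hole to force geodesic (not straight-line) paths
    mask[10:22, 15:17] <- FALSE
    seeds <- matrix(0L, 32, 32)
    pos <- which(mask)
    sp <- sample(pos, 4)
    seeds[sp] <- 1:4
    intensity <- matrix(0, 32, 32)
    lab <- propagate_cytoplasm(seeds, intensity, mask, lambda = 1)
    expect_valid_propagation(lab, intensity, seeds, mask, lambda = 1)
    expect_true(all(lab[!mask] == 0))
    # seeds retain their own pixels
    expect_equal(lab[sp], 1:4)
  }
})

test_that("a bright ridge steers low-lambda propagation boundaries", {
  n <- 32
  intensity <- matrix(0.1, n, n)
  intensity[, 16] <- 1  # vertical ridge between the two seeds
  mask <- matrix(TRUE, n, n)
  seeds <- matrix(0L, n, n)
  seeds[16, 4] <- 1L; seeds[16, 28] <- 2L
  lab <- propagate_cytoplasm(seeds, intensity, mask, lambda = 1e-4)
  expect_valid_propagation(lab, intensity, seeds, mask, lambda = 1e-4)
  # the boundary hugs the ridge: columns left of it belong to seed 1
  expect_true(all(lab[, 1:15] == 1))
  expect_true(all(lab[, 17:32] == 2))
})

test_that("propagation clips out-of-mask seeds and requires some seed", {
  mask <- matrix(FALSE, 8, 8); mask[1:4, ] <- TRUE
  seeds <- matrix(0L, 8, 8); seeds[2, 2] <- 1L; seeds[7, 7] <- 2L
  expect_warning(lab <- propagate_cytoplasm(seeds, matrix(0, 8, 8), mask,
                                            1), "clipped")
  expect_true(all(lab[5:8, ] == 0))
  expect_error(suppressWarnings(
    propagate_cytoplasm(matrix(0L, 8, 8) + diag(0L, 8), matrix(0, 8, 8),
                        mask, 1)), "no seeds")
})

test_that("detect_nuclei counts well-separated and touching nuclei", {
  expect_equal(max(detect_nuclei(matrix(0.05, 64, 64))), 0)
  img <- matrix(0.05, 128, 128)
  truth <- data.frame(y = c(20, 20, 64, 100, 100),
                      x = c(20, 100, 60, 30, 90), r = 9)
  for (i in 1:5) {
    img <- methscreen:::paint_disk(img, truth$y[i], truth$x[i], truth$r[i],
                                   0.9)
  }
  lab <- detect_nuclei(img)
  expect_equal(max(lab), 5)
  cent <- methscreen:::label_centroids(lab)
  for (i in 1:5) {
    d <- sqrt((cent$y - truth$y[i])^2 + (cent$x - truth$x[i])^2)
    expect_lt(min(d), 2)
  }
  # two overlapping nuclei with distinct distance peaks split into 2
  img2 <- methscreen:::paint_disk(matrix(0.05, 64, 64), 32, 22, 8, 0.9)
  img2 <- methscreen:::paint_disk(img2, 32, 36, 8, 0.9)
  expect_equal(max(detect_nuclei(img2, min_distance = 8)), 2)
})

test_that("segment_droplets recovers planted dots and filters specks", {
  cells <- matrix(1L, 64, 64)
  blank <- matrix(0.05, 64, 64)
  expect_equal(max(segment_droplets(blank, cells)), 0)
  img <- matrix(0.2, 64, 64)
  pts <- expand.grid(y = c(12, 32, 52), x = c(12, 32, 52))
  for (i in seq_len(nrow(pts))) {
    img <- methscreen:::paint_disk(img, pts$y[i], pts$x[i], 2.5, 0.9)
  }
  lab <- segment_droplets(img, cells)
  expect_equal(max(lab), 9)
  # single-pixel speck removed by min_dot_area = 2
  img2 <- matrix(0.2, 64, 64)
  img2[30, 30] <- 0.9
  expect_equal(max(segment_droplets(img2, cells, min_dot_area = 2)), 0)
  # dots outside any cell are discarded
  half <- matrix(0L, 64, 64); half[, 1:32] <- 1L
  lab3 <- segment_droplets(img, half)
  expect_equal(max(lab3), 3)
})

test_that("quantify_cells normalizes counts and areas per cell", {
  cells <- matrix(0L, 40, 50)
  cells[1:20, 1:50] <- 1L  # area 1000
  dots <- matrix(0L, 40, 50)
  dots[2:3, 2:6] <- 1L     # 10 px
  dots[6:7, 12:16] <- 2L   # 10 px
  dots[10:11, 22:26] <- 3L # 10 px
  q <- quantify_cells(cells, dots)
  expect_equal(q$n_droplets, 3L)
  expect_equal(q$count_per_area, 0.003)
  expect_equal(q$area_ratio, 0.03)
  # a labeled cell with no dots reports zeros
  cells2 <- cells; cells2[25:30, 1:10] <- 2L
  q2 <- quantify_cells(cells2, dots)
  expect_equal(q2$n_droplets[q2$cell == 2], 0L)
  expect_equal(q2$area_ratio[q2$cell == 2], 0)
})

test_that("the full scene pipeline recovers per-cell truth", {
  sc <- gen_fluor_scene(scene_spec(n_cells = 5, gaussian_noise_sd = 0,
                                   seed = 14))
  res <- quantify_ld_scene(sc$image$nuclei, sc$image$droplets)
  expect_equal(max(res$cell_labels), nrow(sc$truth$cells))
  expect_equal(sum(res$quant$n_droplets), nrow(sc$truth$droplets))
  # match detected cells to truth cells via nucleus centers
  truth_counts <- table(factor(sc$truth$droplets$cell,
                               levels = sc$truth$cells$cell))
  for (i in seq_len(nrow(sc$truth$cells))) {
    lab <- res$cell_labels[round(sc$truth$cells$y[i]) + 1,
                           round(sc$truth$cells$x[i]) + 1]
    expect_gt(lab, 0)
    expect_equal(res$quant$n_droplets[res$quant$cell == lab],
                 unname(truth_counts[i]))
  }
})

test_that("summarize_condition averages by field then condition", {
  q <- data.frame(condition = rep(c("ctrl", "treated"), each = 4),
                  view_field = rep(c("f1", "f1", "f2", "f2"), 2),
                  value = c(2, 2, 2, 2, 1.5, 0.5, 1, 1))
  s <- summarize_condition(q, control = "ctrl")
  expect_equal(s$fold_change[s$condition == "ctrl"], 1)
  expect_equal(s$fold_change[s$condition == "treated"], 0.5)
  # brute-force two-level average on an unbalanced design
  q2 <- data.frame(condition = "c", view_field = c("a", "a", "a", "b"),
                   value = c(1, 2, 3, 10))
  s2 <- summarize_condition(q2, control = "c")
  expect_equal(s2$mean, mean(c(mean(c(1, 2, 3)), 10)))
  expect_error(summarize_condition(
    data.frame(condition = "c", view_field = "f", value = 0), "c"),
    "zero")
})

test_that("area_fraction recovers planted stain fractions", {
  expect_equal(area_fraction(matrix(0.9, 20, 20), invert = TRUE), 0)
  expect_equal(area_fraction(matrix(0.1, 20, 20), invert = TRUE), 1)
  st <- gen_stained_image(0.5, stain_spec(seed = 16))
  expect_lt(abs(area_fraction(st$image) - st$truth$covered_fraction),
            0.02)
  # RGB input collapses to luminance
  rgb <- array(rep(st$image, 3), c(dim(st$image), 3))
  expect_equal(area_fraction(rgb), area_fraction(st$image))
})

test_that("combine_replicates averages within then across replicates", {
  expect_equal(combine_replicates(0.7, "r1")$mean, 0.7)
  expect_equal(combine_replicates(c(0.2, 0.4), c("r1", "r1"))$mean, 0.3)
  # unbalanced: replicate means first, equal replicate weights after
  v <- c(0.1, 0.3, 0.8, 0.6, 0.4)
  r <- c("r1", "r1", "r2", "r3", "r3")
  expect_equal(combine_replicates(v, r)$mean,
               mean(c(mean(c(0.1, 0.3)), 0.8, mean(c(0.6, 0.4)))))
  out <- combine_replicates(c(0.2, 0.6), c("r1", "r1"),
                            condition = c("a", "b"))
  expect_equal(out$mean, c(0.2, 0.6))
})

test_that("label masks round-trip through 16-bit TIFF", {
  f <- withr::local_tempfile(fileext = ".tif")
  lab <- matrix(0L, 16, 16)
  lab[2:5, 2:5] <- 1L; lab[10:14, 9:12] <- 2L
  write_label_mask(lab, f)
  back <- round(read_image_channels(f)[[1]] * 65535)
  expect_equal(unname(back), unname(lab))
})
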