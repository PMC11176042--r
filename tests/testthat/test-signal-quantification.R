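test_that("signal ratio hits the trivial extremes", {
  dims <- c(4, 6, 6)
  region <- array(FALSE, dims); region[2:3, 2:5, 2:5] <- TRUE
  full <- array(0, dims); full[region] <- 100
  r1 <- quantify_signal_in_region(full, region, threshold_method = 50,
                                  voxel_size_um = c(1, 1, 1))
  expect_equal(r1$ratio, 1)
  expect_equal(r1$signal_volume_um3, r1$region_volume_um3)
  r0 <- quantify_signal_in_region(array(0, dims), region, threshold_method = 50,
                                  voxel_size_um = c(1, 1, 1))
  expect_equal(r0$ratio, 0)
  expect_error(quantify_signal_in_region(full, array(FALSE, dims),
                                         voxel_size_um = c(1, 1, 1)), "empty region")
})

test_that("raising the threshold never increases the ratio", {
  set.seed(3)
  dims <- c(5, 8, 8)
  sig <- array(runif(prod(dims), 0, 100), dims)
  region <- array(TRUE, dims)
  ratios <- vapply(seq(0, 100, by = 5), function(t)
    quantify_signal_in_region(sig, region, threshold_method = t,
                              voxel_size_um = c(1, 1, 1))$ratio, numeric(1))
  expect_true(all(diff(ratios) <= 0))
})

test_that("splitting a region conserves the volume-weighted mean ratio", {
  set.seed(4)
  dims <- c(6, 10, 10)
  sig <- array(runif(prod(dims), 0, 10), dims)
  region <- array(runif(prod(dims)) < 0.6, dims)
  part1 <- region; part1[, , 1:5] <- FALSE
  part2 <- region & !part1
  whole <- quantify_signal_in_region(sig, region, threshold_method = 5,
                                     voxel_size_um = c(2, 1, 1))
  p1 <- quantify_signal_in_region(sig, part1, threshold_method = 5,
                                  voxel_size_um = c(2, 1, 1))
  p2 <- quantify_signal_in_region(sig, part2, threshold_method = 5,
                                  voxel_size_um = c(2, 1, 1))
  wmean <- (p1$ratio * p1$region_volume_um3 + p2$ratio * p2$region_volume_um3) /
    (p1$region_volume_um3 + p2$region_volume_um3)
  expect_equal(whole$ratio, wmean, tolerance = 1e-12)
  expect_equal(whole$signal_volume_um3, p1$signal_volume_um3 + p2$signal_volume_um3)
})

test_that("generator transcript fractions are recovered from the ground truth", {
  for (f in c(0.1, 0.3, 0.5)) {
    spec <- scene_spec(volume_shape_voxels = c(20, 170, 240), n_glands = 3,
                       branch_counts = c(0, 1, 2), lif_volume_fraction = f,
                       seed = 21)
    sc <- make_gland_scene(spec)
    gmask <- glandmorph:::scene_masks(sc)$gland_labels > 0
    # exact count: puncta are trimmed to round(f * gland voxels) voxels
    expect_equal(length(sc$lif_voxels), round(f * sum(gmask)),
                 label = sprintf("fraction %.1f", f))
    got <- length(sc$lif_voxels) / sum(gmask)
    # noiseless render: thresholded lif volume inside glands matches exactly
    vol <- render_volume(sc, imaging_noiseless(), "lif")
    q <- quantify_signal_in_region(vol, gmask, threshold_method = 50, channel = "lif")
    expect_equal(q$ratio, got, tolerance = 1e-12)
  }
})

test_that("otsu binarization agrees with a brute-force threshold sweep", {
  set.seed(5)
  vals <- c(rnorm(4000, 30, 5), rnorm(1000, 120, 10))
  vol <- array(vals[1:4992], c(4, 312, 4))
  mask <- binarize(vol, "otsu")
  t_pkg <- attr(mask, "threshold")
  t_ref <- otsu_bruteforce(as.vector(vol))
  mid <- (30 + 120) / 2
  expect_lt(abs(t_pkg - t_ref) / t_ref, 0.05)
  expect_lt(abs(t_pkg - mid) / mid, 0.15)
  expect_error(binarize(array(3, c(2, 2, 2)), "otsu"), "degenerate|constant")
  # fixed threshold on a binary volume is the identity
  bin <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
  expect_equal(binarize(bin, "fixed", threshold = 0.5), array(bin == 1, dim(bin)),
               ignore_attr = TRUE)
})

test_that("positive cell fractions pass through exactly on truth labels", {
  spec <- scene_spec(volume_shape_voxels = c(20, 170, 240), n_glands = 3,
                     branch_counts = c(0, 0, 1), n_gland_cells = 400,
                     esr1_positive_fraction = 0.10, seed = 31)
  sc <- make_gland_scene(spec)
  expect_equal(sum(sc$cells$positive), 40)
  ch <- scene_cell_marker_channel(sc, imaging_noiseless())
  labelled <- sum(tabulate(ch$cell_labels[ch$cell_labels > 0]) > 0)
  cf <- positive_cell_fraction(ch$cell_labels, ch$marker,
                               positivity_threshold = 90)
  # noiseless: positives at amplitude 150, negatives at 37.5
  expect_equal(cf$n_total, labelled)
  truth_frac <- mean(sc$cells$positive[sc$cells$id %in%
                                         unique(ch$cell_labels[ch$cell_labels > 0])])
  expect_equal(cf$fraction, truth_frac, tolerance = 1e-12)
  expect_error(positive_cell_fraction(array(0L, c(2, 2, 2)), array(0, c(2, 2, 2))),
               "no labeled cells")
})

test_that("noisy cell calling recovers the positive fraction within a binomial CI", {
  spec <- scene_spec(volume_shape_voxels = c(24, 200, 320), n_glands = 4,
                     branch_counts = c(0, 0, 1, 1), n_gland_cells = 600,
                     esr1_positive_fraction = 0.10, seed = 33)
  sc <- make_gland_scene(spec)
  ch <- scene_cell_marker_channel(sc, imaging_params(psf_sigma_um = c(1.5, 1, 1)))
  cf <- positive_cell_fraction(ch$cell_labels, ch$marker, positivity_threshold = "otsu")
  ci <- qbinom(c(0.005, 0.995), cf$n_total, 0.10) / cf$n_total
  expect_gte(cf$fraction, ci[1])
  expect_lte(cf$fraction, ci[2])
})
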