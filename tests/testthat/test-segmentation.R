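test_that("background subtraction flattens constants and keeps point sources", {
  vs <- c(1, 1, 1)
  flat <- array(37, c(10, 12, 12))
  out <- subtract_background(flat, 8, voxel_size_um = vs)
  expect_true(all(out == 0))
  spot <- array(0, c(10, 12, 12)); spot[5, 6, 6] <- 100
  out2 <- subtract_background(spot, 8, voxel_size_um = vs)
  expect_equal(out2[5, 6, 6], 100)
  expect_true(all(out2 >= 0))
  expect_error(subtract_background(flat, 0.2, voxel_size_um = vs), "smaller than one voxel")
})

test_that("top-hat removes a smooth gradient so thresholding recovers the tube", {
  dims <- c(14, 40, 60); vs <- c(2, 1, 1)
  tube <- tube_mask(dims, vs, c(14, 20, 5), c(14, 20, 55), 4)
  grad <- outer(rep(1, dims[1]), outer(seq(40, 90, length.out = dims[2]),
                                       rep(1, dims[3])))
  vol <- array(grad, dims) + 150 * tube
  clean <- subtract_background(vol, 16, voxel_size_um = vs)
  mask <- binarize(clean, "otsu")
  jac <- sum(mask & tube) / sum(mask | tube)
  expect_gte(jac, 0.95)
})

test_that("hole filling closes cavities, keeps tubes, and is idempotent", {
  dims <- c(12, 12, 12)
  ball <- array(FALSE, dims)
  for (z in 1:12) for (y in 1:12) for (x in 1:12)
    if ((z - 6.5)^2 + (y - 6.5)^2 + (x - 6.5)^2 <= 16) ball[z, y, x] <- TRUE
  hollow <- ball
  for (z in 1:12) for (y in 1:12) for (x in 1:12)
    if ((z - 6.5)^2 + (y - 6.5)^2 + (x - 6.5)^2 <= 4) hollow[z, y, x] <- FALSE
  expect_equal(fill_holes_3d(hollow), ball)
  tube <- tube_mask(dims, c(1, 1, 1), c(6, 6, 1), c(6, 6, 11), 2.5)
  expect_equal(fill_holes_3d(tube), tube)
  set.seed(8)
  rnd <- array(runif(prod(dims)) < 0.4, dims)
  once <- fill_holes_3d(rnd)
  expect_equal(fill_holes_3d(once), once)
})

test_that("separate_glands cuts trees from the lumen and flags border contact", {
  spec <- scene_spec(n_glands = 3, branch_counts = c(0, 1, 2), seed = 41)
  sc <- make_gland_scene(spec)
  masks <- glandmorph:::scene_masks(sc)
  fg <- masks$gland_labels > 0 | masks$lumen
  glands <- separate_glands(fg, masks$lumen, sc$voxel_size_um)
  expect_equal(length(glands), 3)
  expect_true(all(vapply(glands, function(g) g$compartment, character(1)) == "gland"))
  # volume invariant: labelled gland volume can't exceed the foreground
  expect_lte(sum(vapply(glands, `[[`, numeric(1), "n_voxels")) + sum(masks$lumen), sum(fg))
  # attachment points sit at the lumen surface within a couple of voxels
  for (g in glands) {
    d_axis <- sqrt((g$attachment_point_um[1] - sc$lumen$centerline[1, 1])^2 +
                     (g$attachment_point_um[2] - sc$lumen$centerline[1, 2])^2)
    expect_lt(abs(d_axis - sc$lumen$radius_um), 3 * max(sc$voxel_size_um))
  }
  expect_error(separate_glands(fg, array(FALSE, dim(fg)), sc$voxel_size_um), "empty")
  # a tube crossing the volume boundary is retained and flagged
  dims <- c(10, 20, 30)
  tube <- tube_mask(dims, c(1, 1, 1), c(5, 18, 1), c(5, 3, 29), 2.5)
  lum <- tube_mask(dims, c(1, 1, 1), c(5, 19, 1), c(5, 19, 29), 1.5)
  gg <- separate_glands(tube | lum, lum, c(1, 1, 1), min_volume_voxels = 10)
  expect_equal(length(gg), 1)
  expect_true(gg[[1]]$touches_border)
})

test_that("noiseless segmentation reproduces the rasterized ground truth exactly", {
  spec <- scene_spec(n_glands = 3, branch_counts = c(0, 2, 4), seed = 43)
  sc <- make_gland_scene(spec)
  vol <- render_volume(sc, imaging_noiseless(), "gland_marker")
  masks <- glandmorph:::scene_masks(sc)
  seg <- segment_glands(vol, masks$lumen, sphere_diameter_um = NULL,
                        threshold_method = "fixed", threshold = 75)
  truth <- scene_label_mask(sc)
  mt <- match_to_truth(seg$glands, truth$labels)
  expect_equal(sort(mt$truth_id), 1:3)
  expect_true(all(mt$iou == 1))
})

test_that("segmentation of a fixed volume is deterministic", {
  spec <- scene_spec(n_glands = 2, branch_counts = c(1, 2), seed = 47,
                     volume_shape_voxels = c(20, 160, 240))
  sc <- make_gland_scene(spec)
  vol <- render_volume(sc, imaging_params(), "gland_marker", seed = 5)
  masks <- glandmorph:::scene_masks(sc)
  s1 <- segment_glands(vol, masks$lumen)
  s2 <- segment_glands(vol, masks$lumen)
  expect_identical(lapply(s1$glands, `[[`, "voxels"), lapply(s2$glands, `[[`, "voxels"))
  expect_identical(s1$threshold, s2$threshold)
})
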