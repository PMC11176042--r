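test_that("scene specs validate their invariants", {
  expect_error(scene_spec(branch_count_distribution = c("0" = 0.5, "1-3" = 0.4, ">3" = 0.2)),
               "sum to 1")
  expect_error(scene_spec(branch_count_distribution = c(a = 1)), "named")
  expect_error(scene_spec(voxel_size_um = c(0, 1, 1)), "positive")
  expect_error(scene_spec(n_glands = 3, branch_counts = c(1, 2)), "length")
  expect_error(scene_spec(embryo_axis_angle_deg = 120), "0, 90")
  expect_error(scene_spec(lif_volume_fraction = 1.2), "0, 1")
})

test_that("infeasible geometry raises an explicit geometry error", {
  # gland longer than the available depth below the lumen
  expect_error(
    make_gland_scene(scene_spec(volume_shape_voxels = c(12, 40, 200),
                                gland_length_range_um = c(300, 400), seed = 1)),
    class = "glandmorph_geometry_error")
  # far too many glands for the x-extent
  expect_error(
    make_gland_scene(scene_spec(volume_shape_voxels = c(24, 180, 60),
                                n_glands = 6, seed = 1)),
    class = "glandmorph_geometry_error")
})

test_that("explicit branch counts are honoured exactly and tallied by category", {
  spec <- scene_spec(n_glands = 1, branch_counts = 0, volume_shape_voxels = c(24, 180, 120),
                     seed = 2)
  sc <- make_gland_scene(spec)
  expect_equal(sc$glands[[1]]$true_branch_points, 0)
  expect_equal(nrow(sc$glands[[1]]$edges), nrow(sc$glands[[1]]$nodes) - 1)
  spec3 <- scene_spec(n_glands = 3, branch_counts = c(0, 2, 5), seed = 2)
  sc3 <- make_gland_scene(spec3)
  cats <- table(vapply(sc3$glands, `[[`, character(1), "category"))
  expect_equal(as.integer(cats[c("0", "1-3", ">3")]), c(1, 1, 1))
})

test_that("identical seeds give identical scenes and renders; noise seeds differ", {
  spec <- scene_spec(n_glands = 2, branch_counts = c(1, 3), seed = 11,
                     volume_shape_voxels = c(20, 170, 200))
  s1 <- make_gland_scene(spec)
  s2 <- make_gland_scene(spec)
  expect_identical(s1, s2)
  clean1 <- render_volume(s1, imaging_noiseless(), "gland_marker")
  clean2 <- render_volume(s2, imaging_noiseless(), "gland_marker")
  expect_identical(clean1$data, clean2$data)
  n1 <- render_volume(s1, imaging_params(), "gland_marker", seed = 1)
  n1b <- render_volume(s1, imaging_params(), "gland_marker", seed = 1)
  n2 <- render_volume(s1, imaging_params(), "gland_marker", seed = 2)
  expect_identical(n1$data, n1b$data)
  expect_false(identical(n1$data, n2$data))
})

test_that("ground truth is self-consistent: branch points, lengths, tree structure", {
  spec <- scene_spec(n_glands = 5, branch_counts = c(0, 1, 2, 4, 6), seed = 13,
                     volume_shape_voxels = c(24, 200, 480))
  sc <- make_gland_scene(spec)
  for (g in sc$glands) {
    deg <- tabulate(c(g$edges), nbins = nrow(g$nodes))
    expect_equal(sum(deg >= 3), g$true_branch_points)
    d <- sqrt(rowSums((g$nodes - matrix(g$attachment_um, nrow(g$nodes), 3,
                                        byrow = TRUE))^2))
    expect_equal(max(d), g$true_length_um)
    expect_gte(g$true_length_um, 0)
    # a tree: edges = nodes - 1 and connected
    expect_equal(nrow(g$edges), nrow(g$nodes) - 1)
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    expect_equal(igraph::components(ig)$no, 1)
  }
})

test_that("sampled branch categories land inside the binomial 99% CI", {
  probs <- c("0" = 0.9, "1-3" = 0.08, ">3" = 0.02)
  n <- 400
  spec <- scene_spec(volume_shape_voxels = c(24, 200, 24000), n_glands = n,
                     branch_count_distribution = probs, seed = 17)
  sc <- make_gland_scene(spec)
  cats <- vapply(sc$glands, `[[`, character(1), "category")
  for (cc in names(probs)) {
    k <- sum(cats == cc)
    ci <- qbinom(c(0.005, 0.995), n, probs[[cc]])
    expect_gte(k, ci[1])
    expect_lte(k, ci[2])
  }
})

test_that("noiseless gland-marker rendering is the binary rasterization times amplitude", {
  spec <- scene_spec(n_glands = 2, branch_counts = c(0, 2), seed = 19,
                     volume_shape_voxels = c(20, 170, 200))
  sc <- make_gland_scene(spec)
  img <- imaging_noiseless(signal_amplitude = 140)
  vol <- render_volume(sc, img, "gland_marker")
  truth <- glandmorph:::scene_masks(sc)$gland_labels > 0
  expect_identical(vol$data, array(140 * truth, dim(truth)))
  expect_error(render_volume(sc, img, c("gland_marker", "mystery")),
               class = "glandmorph_config_error")
})

test_that("rendered intensities always fit the bit depth", {
  spec <- scene_spec(n_glands = 1, branch_counts = 1, seed = 23,
                     gland_length_range_um = c(60, 100),
                     volume_shape_voxels = c(16, 170, 200))
  sc <- make_gland_scene(spec)
  v8 <- render_volume(sc, imaging_params(bit_depth = 8, signal_amplitude = 250,
                                         gaussian_sd = 20), "gland_marker")
  expect_lte(max(v8$data), 255)
  expect_gte(min(v8$data), 0)
  expect_true(all(v8$data == round(v8$data)))
})

test_that("truth tables serialize every gland with its edges", {
  spec <- scene_spec(n_glands = 3, branch_counts = c(0, 1, 3), seed = 29)
  sc <- make_gland_scene(spec)
  tt <- scene_truth_tables(sc)
  expect_equal(nrow(tt$glands), 3)
  expect_equal(tt$glands$true_branch_points, c(0, 1, 3))
  expect_setequal(unique(tt$edges$gland_id), 1:3)
  n_edges <- vapply(sc$glands, function(g) nrow(g$edges), numeric(1))
  expect_equal(as.integer(table(tt$edges$gland_id)), as.integer(n_edges))
})
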