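# shared small shapes, built through the package rasterizer
raster_shape <- function(segs, dims = c(20L, 60L, 60L), vs = c(1, 1, 1)) {
  lab <- glandmorph:::cpp_rasterize_tubes(dims, vs, segs,
                                          rep(1L, nrow(segs)), integer(0))
  array(lab > 0, dims)
}

test_that("a straight cylinder thins to a single path with two endpoints", {
  m <- raster_shape(rbind(c(10, 30, 5, 10, 30, 55, 4)))
  sk <- skeletonize_3d(m)
  g <- skeleton_to_graph(sk, c(1, 1, 1))
  deg <- graph_degree(g)
  expect_equal(sum(deg == 1), 2)
  expect_equal(count_branch_points(prune_spurs(g, 8)), 0)
  # skeleton is inside the mask and connected
  expect_true(all(m[sk]))
  expect_equal(max(label_components_3d(sk, 26L)), 1)
})

test_that("a Y-shaped tube yields exactly one branch point after pruning", {
  m <- raster_shape(rbind(c(10, 5, 30, 10, 30, 30, 4),
                          c(10, 30, 30, 10, 50, 15, 4),
                          c(10, 30, 30, 10, 50, 45, 4)))
  g <- prune_spurs(skeleton_to_graph(skeletonize_3d(m), c(1, 1, 1)), 8)
  expect_equal(count_branch_points(g), 1)
  expect_equal(sum(graph_degree(g) == 1), 3)
})

test_that("a solid ball leaves no branch points after pruning", {
  dims <- c(17L, 17L, 17L)
  m <- array(FALSE, dims)
  for (z in 1:17) for (y in 1:17) for (x in 1:17)
    if ((z - 9)^2 + (y - 9)^2 + (x - 9)^2 <= 36) m[z, y, x] <- TRUE
  sk <- skeletonize_3d(m)
  expect_lte(sum(sk), 8)          # collapses to a voxel-scale core
  g <- prune_spurs(skeleton_to_graph(sk, c(1, 1, 1)), 8)
  expect_equal(count_branch_points(g), 0)
})

test_that("skeletonize_3d rejects empty and multi-component masks", {
  expect_error(skeletonize_3d(array(FALSE, c(4, 4, 4))), "empty")
  two <- array(FALSE, c(6, 6, 12)); two[3, 3, 2:3] <- TRUE; two[3, 3, 9:10] <- TRUE
  expect_error(skeletonize_3d(two), "separate_glands")
})

test_that("optimized thinning equals the brute-force reference on small masks", {
  shapes <- list(
    cyl = raster_shape(rbind(c(6, 12, 2, 6, 12, 22, 3)), c(12L, 24L, 24L)),
    y = raster_shape(rbind(c(6, 2, 12, 6, 12, 12, 3),
                           c(6, 12, 12, 6, 20, 5, 3),
                           c(6, 12, 12, 6, 20, 19, 3)), c(12L, 24L, 24L)),
    tee = raster_shape(rbind(c(6, 12, 2, 6, 12, 22, 2.5),
                             c(6, 12, 12, 6, 22, 12, 2.5)), c(12L, 24L, 24L)))
  set.seed(55)
  blob <- array(runif(10 * 14 * 14) < 0.45, c(10, 14, 14))
  shapes$blob <- fill_holes_3d(blob)
  for (nm in names(shapes)) {
    m <- shapes[[nm]]
    comp <- label_components_3d(m, 26L)
    m[comp != which.max(tabulate(comp[comp > 0]))] <- FALSE   # keep largest component
    fast <- skeletonize_3d(m)
    ref <- thin_reference(m)
    expect_identical(fast, ref, label = nm)
  }
})

test_that("graph edge lengths use anisotropy-weighted physical distance", {
  m <- array(FALSE, c(3, 12, 3)); m[2, 2:11, 2] <- TRUE
  g <- skeleton_to_graph(m, c(7, 1.52, 1.52))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$length_um, 9 * 1.52, tolerance = 1e-12)
  expect_equal(sum(graph_degree(g) == 1), 2)
})

test_that("spur pruning is thresholded, idempotent, and identity at zero", {
  m <- raster_shape(rbind(c(10, 5, 30, 10, 50, 30, 3),
                          c(10, 28, 30, 10, 32, 36, 3)))  # short 7 um side twig
  g <- skeleton_to_graph(skeletonize_3d(m), c(1, 1, 1))
  expect_identical(prune_spurs(g, 0), g)
  p <- prune_spurs(g, 15)
  expect_equal(count_branch_points(p), 0)
  expect_identical(prune_spurs(p, 15)$edges, p$edges)
  # a long arm survives the same threshold
  m2 <- raster_shape(rbind(c(10, 5, 30, 10, 50, 30, 3),
                           c(10, 28, 30, 10, 40, 52, 3)))
  p2 <- prune_spurs(skeleton_to_graph(skeletonize_3d(m2), c(1, 1, 1)), 15)
  expect_equal(count_branch_points(p2), 1)
})

test_that("gland length is the chord to the furthest tip", {
  # 3-4-5 triangle: tips at 30/40 um from the attachment in y/x
  g <- structure(list(
    nodes = data.frame(node = 1:3, z_um = c(0, 0, 0), y_um = c(0, 30, 5),
                       x_um = c(10, 40, 2), type = c("junction", "endpoint", "endpoint")),
    edges = data.frame(from = c(1, 1), to = c(2, 3), length_um = c(50, 10)),
    paths = list(), voxel_size_um = c(1, 1, 1)), class = "skeleton_graph")
  expect_equal(gland_length(c(0, 0, 0), g), 50)   # sqrt(30^2+40^2), the farther tip
  lone <- structure(list(nodes = data.frame(node = 1, z_um = 0, y_um = 0, x_um = 0,
                                            type = "isolated"),
                         edges = data.frame(from = integer(0), to = integer(0),
                                            length_um = numeric(0)),
                         paths = list(), voxel_size_um = c(1, 1, 1)),
                    class = "skeleton_graph")
  expect_warning(l0 <- gland_length(c(0, 0, 0), lone), "no endpoints")
  expect_equal(l0, 0)
})

test_that("recovered tree is isomorphic to the generator tree after pruning", {
  spec <- scene_spec(n_glands = 3, branch_counts = c(2, 3, 5), seed = 61,
                     volume_shape_voxels = c(24, 200, 480))
  sc <- make_gland_scene(spec)
  vol <- render_volume(sc, imaging_noiseless(), "gland_marker")
  masks <- glandmorph:::scene_masks(sc)
  seg <- segment_glands(vol, masks$lumen, sphere_diameter_um = NULL,
                        threshold_method = "fixed", threshold = 75)
  morph <- gland_morphometry(seg$glands)
  mt <- match_to_truth(seg$glands, scene_label_mask(sc)$labels)
  for (i in seq_along(seg$glands)) {
    truth <- sc$glands[[mt$truth_id[i]]]
    # recompute the pruned graph to compare topology, not just the count
    g <- seg$glands[[i]]
    co <- arrayInd(g$voxels, g$dims)
    lo <- pmax(apply(co, 2, min) - 1L, 1L); hi <- pmin(apply(co, 2, max) + 1L, g$dims)
    sub <- array(FALSE, hi - lo + 1L)
    sub[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L, co[, 3] - lo[3] + 1L)] <- TRUE
    f <- max(1L, round(g$voxel_size_um[1] / g$voxel_size_um[2]))
    sub <- sub[rep(seq_len(dim(sub)[1]), each = f), , , drop = FALSE]
    gr <- prune_spurs(skeleton_to_graph(
      skeletonize_3d(sub), c(g$voxel_size_um[1] / f, g$voxel_size_um[2:3])), 24, 10)
    rec_top <- contract_deg2(as.matrix(gr$edges[, 1:2]))
    truth_top <- contract_deg2(truth$edges)
    ig_rec <- igraph::graph_from_edgelist(
      matrix(as.integer(factor(rec_top)), ncol = 2), directed = FALSE)
    ig_tru <- igraph::graph_from_edgelist(
      matrix(as.integer(factor(truth_top)), ncol = 2), directed = FALSE)
    expect_true(igraph::isomorphic(ig_rec, ig_tru),
                label = sprintf("gland %d topology", i))
  }
})

test_that("branch categories are consistent with counts and sum to 100 percent", {
  rec <- data.frame(n_branch_points = c(0, 0, 1, 3, 4, 9, 2, 0))
  expect_equal(as.character(branch_category(rec$n_branch_points)),
               c("0", "0", "1-3", "1-3", ">3", ">3", "1-3", "0"))
  tab <- branch_category_table(rec, rep(c("a", "b"), each = 4))
  sums <- tapply(tab$percent, tab$group, sum)
  expect_equal(as.numeric(sums), c(100, 100))
  a <- tab[tab$group == "a" & tab$category == "0", ]
  expect_equal(a$n, 2); expect_equal(a$percent, 50)
  expect_equal(unique(tab$n_group[tab$group == "b"]), 4L)
  # all glands >3 branches
  tb <- branch_category_table(data.frame(n_branch_points = c(4, 5, 6)), rep("g", 3))
  expect_equal(tb$percent[tb$category == ">3"], 100)
  expect_error(branch_category_table(rec[0, , drop = FALSE], character(0)), "no records")
})
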