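test_that("volumes round-trip through TIFF with spacing and channel names", {
  dims <- c(6, 10, 12)
  set.seed(1)
  data <- array(sample(0:65535, prod(dims) * 2, replace = TRUE), c(dims, 2))
  vol <- volume_image(data, c(7, 1.52, 1.52), c("gland_marker", "nuclei"))
  path <- file.path(tempdir(), "rt.tif")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data)
  expect_equal(back$voxel_size_um, c(7, 1.52, 1.52))
  expect_equal(back$channel_names, c("gland_marker", "nuclei"))
  # single channel keeps a 3D array
  v1 <- volume_image(array(0:59, c(3, 4, 5)), c(1.5, 0.76, 0.76))
  p1 <- file.path(tempdir(), "rt1.tif")
  write_volume(v1, p1)
  expect_equal(length(dim(read_volume(p1)$data)), 3)
  expect_equal(read_volume(p1)$data, v1$data)
})

test_that("2D TIFFs and missing spacing are rejected", {
  p <- file.path(tempdir(), "flat.tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), p)
  expect_error(read_volume(p), "2D")
  # multi-page but no sidecar and no override -> spacing error
  p2 <- file.path(tempdir(), "nometa.tif")
  tiff::writeTIFF(list(matrix(0.2, 4, 4), matrix(0.4, 4, 4)), p2)
  expect_error(read_volume(p2), "spacing")
  v <- read_volume(p2, voxel_size_um = c(7, 1.52, 1.52))
  expect_equal(dim(v$data), c(2, 4, 4))
  expect_equal(v$voxel_size_um, c(7, 1.52, 1.52))
  expect_error(read_volume(file.path(tempdir(), "absent.tif")), "not found")
})

test_that("volume_image validates its invariants", {
  expect_error(volume_image(array(-1, c(2, 2, 2)), c(1, 1, 1)), "nonnegative")
  expect_error(volume_image(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_error(volume_image(array(0, c(2, 2, 2)), c(0, 1, 1)), "positive")
  expect_error(volume_image(array(0, c(2, 2, 2, 2)), c(1, 1, 1), "one_name"), "channels")
  expect_error(volume_image(matrix(0, 2, 2), c(1, 1, 1)), "3D or 4D")
})

test_that("label masks round-trip with their compartment table", {
  labels <- array(0L, c(4, 5, 6)); labels[2, 2:3, 2] <- 1L; labels[3, 4, 5] <- 2L
  lm <- label_mask(labels, c(7, 1.52, 1.52),
                   data.frame(label = 1:2, compartment = c("gland", "lumen")))
  p <- file.path(tempdir(), "mask.tif")
  write_mask(lm, p)
  back <- read_mask(p)
  expect_equal(back$labels, lm$labels)
  expect_equal(back$label_table$compartment, c("gland", "lumen"))
  expect_error(label_mask(labels, c(7, 1.52, 1.52),
                          data.frame(label = 1, compartment = "soup")), "compartment")
})

test_that("reports are deterministic, ordered, and refuse empty input", {
  rec <- data.frame(b_col = c(2, 1), a_col = c("x", "y"), c_col = c(0.5, 0.25))
  p1 <- file.path(tempdir(), "r1.csv"); p2 <- file.path(tempdir(), "r2.csv")
  write_report(rec, p1, config = list(k = 1), seed = 42)
  write_report(rec, p2, config = list(k = 1), seed = 42)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  tab <- read.csv(p1)
  expect_equal(names(tab), c("a_col", "b_col", "c_col"))  # stable column order
  expect_equal(nrow(tab), 2)
  prov <- jsonlite::read_json(paste0(p1, ".prov.json"), simplifyVector = TRUE)
  expect_equal(prov$seed, 42)
  expect_false(is.null(prov$config_hash))
  expect_error(write_report(data.frame(), file.path(tempdir(), "e.csv")), "non-empty")
  expect_error(write_report(NULL, file.path(tempdir(), "e.csv")), "non-empty")
})

test_that("scene specs round-trip through YAML config files", {
  spec <- scene_spec(n_glands = 4, lif_volume_fraction = 0.3,
                     branch_count_distribution = c("0" = 0.5, "1-3" = 0.4, ">3" = 0.1),
                     seed = 99)
  p <- file.path(tempdir(), "spec.yml")
  write_scene_config(spec, p)
  back <- read_scene_config(p)
  expect_equal(back, spec)
  spec2 <- scene_spec(n_glands = 3, branch_counts = c(0, 2, 5), seed = 1)
  write_scene_config(spec2, p)
  expect_equal(read_scene_config(p), spec2)
})
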