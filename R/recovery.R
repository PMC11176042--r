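#' Standard scene specification for branch-recovery studies
#'
#' The fixed study conditions used to validate branch counting: whole-mount
#' scenes (7 um optical sections, as for whole uterine horns) and section
#' scenes (1.5 um sections, smaller glands, narrower lumen), three gland
#' trees per scene with explicit branch counts.
#'
#' @param preset `"whole_mount"` or `"section"`.
#' @param branch_counts integer(3) per-gland branch-point counts.
#' @param seed scene seed.
#' @return a [scene_spec()].
#' @export
recovery_scene_spec <- function(preset, branch_counts, seed) {
  if (preset == "whole_mount") {
    scene_spec(volume_shape_voxels = c(24, 200, 480),
               voxel_size_um = voxel_preset("whole_mount"),
               n_glands = length(branch_counts), branch_counts = branch_counts,
               seed = seed)
  } else {
    scene_spec(volume_shape_voxels = c(30, 400, 300),
               voxel_size_um = voxel_preset("section"),
               n_glands = length(branch_counts), branch_counts = branch_counts,
               lumen_radius_um = 18, gland_length_range_um = c(60, 110),
               seed = seed)
  }
}

# count panels cycled over scenes; each preset's cycle spans branch counts
# 0-8 (section stacks are shallow, so each section scene carries one gland
# with the full lateral field to itself)
RECOVERY_COUNT_SETS <- list(
  whole_mount = list(c(0L, 4L, 8L), c(1L, 5L, 7L), c(2L, 6L, 3L), c(0L, 3L, 6L)),
  section = as.list(0:8))

#' Branch-count and length recovery over synthetic scenes
#'
#' Generates scenes with known per-gland branch counts, renders them under
#' the given imaging model, runs the full segmentation + skeletonization
#' pipeline, matches recovered glands to the ground truth by IoU, and
#' returns one row per ground-truth gland. Scenes whose random tree
#' placement is geometrically infeasible are retried under derived seeds
#' (deterministically), so the gland panel is always complete.
#'
#' @param preset `"whole_mount"` or `"section"`.
#' @param seeds integer vector, one scene per seed.
#' @param imaging an [imaging_params()].
#' @return data.frame: `preset`, `seed`, `truth_id`, `true_branch_points`,
#'   `recovered_branch_points` (NA if the gland was not recovered),
#'   `true_length_um`, `length_um`, `iou`.
#' @export
run_branch_recovery <- function(preset, seeds, imaging = imaging_params()) {
  out <- list()
  sets <- RECOVERY_COUNT_SETS[[preset]]
  for (seed in seeds) {
    counts <- sets[[((seed - 1) %% length(sets)) + 1]]
    sc <- NULL
    for (s in seed + c(0L, 10000L, 20000L, 30000L)) {
      sc <- tryCatch(make_gland_scene(recovery_scene_spec(preset, counts, s)),
                     glandmorph_geometry_error = function(e) NULL)
      if (!is.null(sc)) break
    }
    if (is.null(sc))
      geometry_error(sprintf("no feasible scene for seed %d (%s)", seed, preset))
    vol <- render_volume(sc, imaging, "gland_marker")
    masks <- scene_masks(sc)
    seg <- segment_glands(vol, masks$lumen)
    morph <- if (length(seg$glands)) gland_morphometry(seg$glands) else NULL
    mt <- match_to_truth(seg$glands, scene_label_mask(sc)$labels)
    rec <- data.frame(preset = preset, seed = seed,
                      truth_id = seq_along(sc$glands),
                      true_branch_points = vapply(sc$glands, `[[`, numeric(1),
                                                  "true_branch_points"),
                      true_length_um = vapply(sc$glands, `[[`, numeric(1),
                                              "true_length_um"),
                      recovered_branch_points = NA_integer_,
                      length_um = NA_real_, iou = NA_real_)
    for (i in seq_len(nrow(mt))) {
      if (is.na(mt$truth_id[i])) next
      j <- mt$truth_id[i]
      rec$recovered_branch_points[j] <- morph$n_branch_points[i]
      rec$length_um[j] <- morph$length_um[i]
      rec$iou[j] <- mt$iou[i]
    }
    out[[length(out) + 1L]] <- rec
  }
  do.call(rbind, out)
}
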