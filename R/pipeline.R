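#' Match segmented glands to ground-truth labels by IoU
#'
#' Greedy one-to-one matching between recovered gland objects and
#' ground-truth labels, highest intersection-over-union first; pairs below
#' `min_iou` are left unmatched.
#'
#' @param glands list of `gland_object`s.
#' @param truth_labels integer 3D array of ground-truth gland labels.
#' @param min_iou minimum IoU accepted as a match (default 0.5).
#' @return data.frame: `gland_label`, `truth_id`, `iou` (NA rows for
#'   unmatched recovered glands).
#' @export
match_to_truth <- function(glands, truth_labels, min_iou = 0.5) {
  if (!length(glands)) return(data.frame(gland_label = integer(0),
                                         truth_id = integer(0), iou = numeric(0)))
  tids <- setdiff(sort(unique(as.integer(truth_labels))), 0L)
  truth_idx <- lapply(tids, function(t) which(truth_labels == t))
  cand <- list()
  for (i in seq_along(glands)) for (j in seq_along(tids)) {
    inter <- length(intersect(glands[[i]]$voxels, truth_idx[[j]]))
    if (inter == 0) next
    uni <- length(glands[[i]]$voxels) + length(truth_idx[[j]]) - inter
    cand[[length(cand) + 1L]] <- c(i, j, inter / uni)
  }
  out <- data.frame(gland_label = vapply(glands, `[[`, numeric(1), "label"),
                    truth_id = NA_integer_, iou = NA_real_)
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3]), , drop = FALSE]
    used_g <- logical(length(glands)); used_t <- logical(length(tids))
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, 1]; j <- cm[r, 2]
      if (used_g[i] || used_t[j] || cm[r, 3] < min_iou) next
      used_g[i] <- TRUE; used_t[j] <- TRUE
      out$truth_id[i] <- tids[j]
      out$iou[i] <- cm[r, 3]
    }
  }
  out
}

default_pipeline_config <- function() {
  list(scene = list(),                   # scene_spec() overrides
       embryo_angles = NULL,             # when set, an embryo scene is built
       imaging = list(),                 # imaging_params() overrides
       channels = c("gland_marker"),
       sphere_diameter_um = 30,
       threshold_method = "otsu",
       min_volume_voxels = 50L,
       lumen_dilation_vox = 1L,
       min_spur_length_um = 36,
       lif_threshold = "auto",
       sample_id = "sample1")
}

#' Run the full synthetic-scene analysis pipeline
#'
#' Simulate, render, write, segment, skeletonize, quantify and report, end to
#' end, writing deterministic CSV outputs (plus provenance sidecars) under
#' `out_dir`. The same config and seed produce byte-identical CSVs.
#'
#' @param config list (or YAML file path) overriding
#'   `default_pipeline_config()` entries; `config$scene` holds
#'   [scene_spec()] arguments, `config$imaging` holds [imaging_params()]
#'   arguments.
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed for scene geometry and noise.
#' @return invisible list of output paths (`volume`, `truth_glands`,
#'   `truth_edges`, `morphometry`, `categories`, `axis`, `signal` as
#'   applicable).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  spec <- do.call(scene_spec, utils::modifyList(cfg$scene, list(seed = as.integer(seed))))
  scene <- if (!is.null(cfg$embryo_angles))
    make_embryo_scene(cfg$embryo_angles, spec) else make_gland_scene(spec)
  vol <- render_volume(scene, do.call(imaging_params, cfg$imaging),
                       channels = cfg$channels, seed = seed + 1L)
  paths$volume <- file.path(out_dir, "volume.tif")
  write_volume(vol, paths$volume)
  truth <- scene_truth_tables(scene)
  if (!is.null(truth$glands)) {
    paths$truth_glands <- write_report(truth$glands, file.path(out_dir, "truth_glands.csv"),
                                       config = cfg, seed = seed)
    paths$truth_edges <- write_report(truth$edges, file.path(out_dir, "truth_edges.csv"),
                                      config = cfg, seed = seed)
  }
  masks <- scene_masks(scene)
  if (length(scene$glands) > 0 && "gland_marker" %in% cfg$channels) {
    seg <- segment_glands(vol, masks$lumen, channel = "gland_marker",
                          sphere_diameter_um = cfg$sphere_diameter_um,
                          threshold_method = cfg$threshold_method,
                          min_volume_voxels = cfg$min_volume_voxels,
                          lumen_dilation_vox = cfg$lumen_dilation_vox)
    if (length(seg$glands)) {
      morph <- gland_morphometry(seg$glands, cfg$min_spur_length_um,
                                 sample_id = cfg$sample_id)
      paths$morphometry <- write_report(morph, file.path(out_dir, "morphometry.csv"),
                                        config = cfg, seed = seed)
      cats <- branch_category_table(morph, rep(cfg$sample_id, nrow(morph)))
      paths$categories <- write_report(cats, file.path(out_dir, "branch_categories.csv"),
                                       config = cfg, seed = seed)
    }
  }
  if (length(scene$embryos) > 0) {
    if (!"nuclei" %in% cfg$channels)
      stop("embryo scenes need the 'nuclei' channel in config$channels")
    ax <- measure_embryos(vol, mam_axis = scene$mam_axis, channel = "nuclei")
    if (nrow(ax))
      paths$axis <- write_report(ax, file.path(out_dir, "axis_measurements.csv"),
                                 config = cfg, seed = seed)
  }
  if (!is.null(scene$lif_voxels) && "lif" %in% cfg$channels) {
    gmask <- masks$gland_labels > 0
    sq <- quantify_signal_in_region(vol, gmask, threshold_method = cfg$lif_threshold,
                                    channel = "lif", region_label = "gland")
    sq$sample_id <- cfg$sample_id
    paths$signal <- write_report(sq, file.path(out_dir, "signal_quant.csv"),
                                 config = cfg, seed = seed)
  }
  invisible(paths)
}
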