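# Otsu threshold for a plain numeric vector (histogram-based, 256 levels)
otsu_threshold <- function(values) {
  rng <- range(values)
  if (!all(is.finite(rng)) || diff(rng) == 0)
    stop(errorCondition("degenerate input: constant values have no Otsu threshold",
                        class = c("glandmorph_degenerate_input", "error", "condition")))
  EBImage::otsu(EBImage::Image(as.numeric(values), dim = c(length(values), 1L)),
                range = rng, levels = 256L)
}

#' Quantify thresholded signal volume within a region
#'
#' The volumetric transcript readout: signal voxels are the thresholded
#' signal channel intersected with the region mask; the reported ratio is
#' signal volume over region volume (unitless "normalized units").
#'
#' @param signal 3D numeric array (signal channel) or a [volume_image()].
#' @param region_mask logical 3D array, same shape; must be nonempty.
#' @param threshold_method `"otsu"` (within-region histogram), `"auto"`
#'   (Otsu with a unimodality guard: when the two Otsu classes are separated
#'   by less than three background standard deviations the region is called
#'   signal-free), or a numeric cutoff.
#' @param voxel_size_um numeric(3) spacing (taken from the volume when given).
#' @param channel signal channel when `signal` is a multi-channel volume.
#' @param region_label label stored in the output record.
#' @return data.frame (`signal_quant` record): `region_label`,
#'   `region_volume_um3`, `signal_volume_um3`, `ratio`, `threshold`.
#' @export
quantify_signal_in_region <- function(signal, region_mask, threshold_method = "otsu",
                                      voxel_size_um = NULL, channel = 1L,
                                      region_label = "region") {
  if (inherits(signal, "volume_image")) {
    voxel_size_um <- signal$voxel_size_um
    signal <- get_channel(signal, channel)
  }
  voxel_size_um <- check_voxel_size(voxel_size_um)
  if (!identical(dim(signal), dim(region_mask)))
    stop("signal and region_mask must have identical shapes")
  if (!any(region_mask)) stop("empty region mask")
  vals <- signal[region_mask]
  t <- NA_real_
  if (is.numeric(threshold_method)) {
    t <- threshold_method
    pos <- vals >= t
  } else if (identical(threshold_method, "otsu") || identical(threshold_method, "auto")) {
    rng <- range(vals)
    if (diff(rng) == 0) {
      # constant region: either saturated signal or none at all
      pos <- rep(vals[1] > 0, length(vals))
      t <- if (vals[1] > 0) rng[1] else Inf
    } else {
      t <- otsu_threshold(vals)
      pos <- vals > t
      if (identical(threshold_method, "auto")) {
        lo <- vals[!pos]; hi <- vals[pos]
        sd_lo <- stats::sd(lo)
        if (!length(hi) || (is.finite(sd_lo) && sd_lo > 0 &&
                            (mean(hi) - mean(lo)) < 3 * sd_lo)) {
          pos <- rep(FALSE, length(vals))   # unimodal background: no signal
          t <- Inf
        }
      }
    }
  } else stop("threshold_method must be 'otsu', 'auto' or a numeric cutoff")
  vv <- voxel_volume_um3(voxel_size_um)
  data.frame(region_label = region_label,
             region_volume_um3 = length(vals) * vv,
             signal_volume_um3 = sum(pos) * vv,
             ratio = sum(pos) / length(vals),
             threshold = t,
             stringsAsFactors = FALSE)
}

#' Fraction of marker-positive cells within a region
#'
#' A cell is called positive when its mean marker intensity over the nuclear
#' instance reaches the positivity threshold; the fraction is taken over
#' cells whose centroid lies inside the region mask.
#'
#' @param nuclei_mask a [label_mask()] or integer 3D array of nuclear
#'   instance labels (0 = background).
#' @param marker_channel 3D numeric array of marker intensities.
#' @param region_mask logical 3D array restricting the cell population
#'   (`NULL` = whole volume).
#' @param positivity_threshold numeric cutoff, or `"otsu"` to derive it from
#'   the distribution of within-region cell means.
#' @return data.frame (`cell_fraction` record): `n_positive`, `n_total`,
#'   `fraction`, `threshold`, `compartment`.
#' @export
positive_cell_fraction <- function(nuclei_mask, marker_channel, region_mask = NULL,
                                   positivity_threshold = "otsu") {
  labels <- if (inherits(nuclei_mask, "label_mask")) nuclei_mask$labels else nuclei_mask
  if (!identical(dim(labels), dim(marker_channel)))
    stop("nuclei mask and marker channel must have identical shapes")
  idx <- which(labels > 0)
  if (!length(idx)) stop("no labeled cells in nuclei mask")
  labs <- labels[idx]
  means <- tapply(marker_channel[idx], labs, mean)
  if (!is.null(region_mask)) {
    co <- arrayInd(idx, dim(labels))
    cz <- round(tapply(co[, 1], labs, mean))
    cy <- round(tapply(co[, 2], labs, mean))
    cx <- round(tapply(co[, 3], labs, mean))
    inside <- region_mask[cbind(cz, cy, cx)]
    means <- means[inside]
  }
  if (!length(means))
    stop(errorCondition("zero cells in region",
                        class = c("glandmorph_degenerate_input", "error", "condition")))
  t <- if (identical(positivity_threshold, "otsu")) otsu_threshold(as.numeric(means))
       else as.numeric(positivity_threshold)
  n_pos <- sum(means >= t)
  data.frame(n_positive = n_pos, n_total = length(means),
             fraction = n_pos / length(means), threshold = t,
             compartment = "gland", stringsAsFactors = FALSE)
}

#' Render a marker channel for the scene's epithelial cells
#'
#' Positive cells are rendered at the full signal amplitude, negative cells
#' at a dim baseline (25%), then the standard imaging forward model is
#' applied. Ground-truth positivity is in `scene$cells$positive`.
#'
#' @param scene a `gland_scene` with cells (see `n_gland_cells` in
#'   [scene_spec()]).
#' @param imaging an [imaging_params()].
#' @param seed noise seed (default `scene$spec$seed + 2000`).
#' @return list: `marker` (3D array), `cell_labels` (integer 3D array of
#'   nuclear instances).
#' @export
scene_cell_marker_channel <- function(scene, imaging = imaging_params(), seed = NULL) {
  if (is.null(scene$cells)) stop("scene has no cells; set n_gland_cells in scene_spec()")
  if (is.null(seed)) seed <- scene$spec$seed + 2000L
  m <- scene_masks(scene)
  dims <- scene$volume_shape
  A <- imaging$signal_amplitude
  cl <- m$cell_labels
  sig <- array(0, dims)
  pos_ids <- scene$cells$id[scene$cells$positive]
  sig[cl > 0] <- 0.25 * A
  sig[cl %in% pos_ids] <- A
  maxval <- 2^imaging$bit_depth - 1
  with_seed(seed, {
    if (any(imaging$psf_sigma_um > 0))
      sig <- array(cpp_gaussian_blur(sig, dims, imaging$psf_sigma_um / scene$voxel_size_um), dims)
    sig <- sig + imaging$background_level
    if (imaging$apply_poisson)
      sig <- array(rpois(length(sig), imaging$poisson_gain * sig) / imaging$poisson_gain, dims)
    if (imaging$gaussian_sd > 0)
      sig <- sig + array(rnorm(length(sig), 0, imaging$gaussian_sd), dims)
  })
  list(marker = array(pmin(pmax(round(sig), 0), maxval), dims), cell_labels = cl)
}
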