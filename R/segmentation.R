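#' Rolling-ball style background subtraction (3D grayscale top-hat)
#'
#' Subtracts the morphological opening with a spherical structuring element
#' of the stated physical diameter (an ellipsoid in voxel units on
#' anisotropic grids). Structures smaller than the sphere are preserved; any
#' background varying on a larger scale is removed. Output is nonnegative.
#'
#' When the sphere spans many voxels the background (the opening) is
#' estimated on a strided grid — the stride keeps at least four voxels per
#' sphere radius — and the erosion/dilation is computed as an iterated
#' Minkowski decomposition (several passes with a small ellipsoid whose
#' radii sum to the requested radius). Both are the standard tractable
#' approximations for large rolling-ball radii; the computation is exact
#' for spheres up to a few voxels across.
#'
#' @param x a [volume_image()] or 3D numeric array.
#' @param sphere_diameter_um structuring-element diameter in um (default 30).
#' @param channel channel to process when `x` is a multi-channel volume.
#' @param voxel_size_um numeric(3) spacing, required when `x` is a bare array.
#' @return same container kind as the input (single-channel `volume_image`
#'   or 3D array).
#' @export
subtract_background <- function(x, sphere_diameter_um = 30, channel = 1L,
                                voxel_size_um = NULL) {
  if (inherits(x, "volume_image")) {
    arr <- get_channel(x, channel)
    vs <- x$voxel_size_um
  } else {
    arr <- x
    vs <- check_voxel_size(voxel_size_um)
  }
  if (sphere_diameter_um <= 0) stop("sphere_diameter_um must be positive")
  r <- sphere_diameter_um / 2
  if (r < min(vs) / 2)
    stop("structuring-element diameter (", sphere_diameter_um,
         " um) is smaller than one voxel; increase the diameter")
  dims <- dim(arr)
  # stride keeps >= 4 voxels per radius and >= 8 voxels per axis
  stride <- pmax(1L, pmin(as.integer(floor(r / (4 * vs))), dims %/% 8L))
  work <- arr[seq(1, dims[1], stride[1]),
              seq(1, dims[2], stride[2]),
              seq(1, dims[3], stride[3]), drop = FALSE]
  vs_w <- vs * stride
  wdims <- dim(work)
  # each pass must span at least one voxel along every axis it can move in
  k <- max(1L, floor(r / max(vs_w)))
  off <- ball_offsets(2 * r / k, vs_w)
  er <- work
  for (i in seq_len(k)) er <- cpp_grey_morph(er, wdims, off, dilate = FALSE)
  op <- er
  for (i in seq_len(k)) op <- cpp_grey_morph(op, wdims, off, dilate = TRUE)
  op <- array(op, wdims)
  if (any(stride > 1L)) {
    op <- op[rep(seq_len(wdims[1]), each = stride[1])[seq_len(dims[1])],
             rep(seq_len(wdims[2]), each = stride[2])[seq_len(dims[2])],
             rep(seq_len(wdims[3]), each = stride[3])[seq_len(dims[3])], drop = FALSE]
  }
  out <- array(pmax(arr - op, 0), dims)
  if (inherits(x, "volume_image"))
    volume_image(out, vs, if (is.character(channel)) channel else x$channel_names[channel])
  else out
}

#' Binarize a volume by Otsu's method or a fixed threshold
#'
#' @param x a [volume_image()] (single channel used) or 3D numeric array.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold numeric cutoff, required for `method = "fixed"`.
#' @param channel channel when `x` is multi-channel.
#' @return logical 3D array (`TRUE` = foreground, intensity > threshold for
#'   otsu, >= threshold for fixed) with the applied cutoff stored in
#'   `attr(, "threshold")`.
#' @export
binarize <- function(x, method = c("otsu", "fixed"), threshold = NULL, channel = 1L) {
  method <- match.arg(method)
  arr <- if (inherits(x, "volume_image")) get_channel(x, channel) else x
  if (method == "fixed") {
    if (is.null(threshold)) stop("method = 'fixed' needs a threshold")
    t <- threshold
    mask <- arr >= t
  } else {
    rng <- range(arr)
    if (!all(is.finite(rng)) || diff(rng) == 0)
      stop(errorCondition("degenerate input: constant or empty image has no Otsu threshold",
                          class = c("glandmorph_degenerate_input", "error", "condition")))
    t <- EBImage::otsu(EBImage::Image(as.vector(arr), dim = c(length(arr), 1L)),
                       range = rng, levels = 256L)
    mask <- arr > t
  }
  mask <- array(mask, dim(arr))
  attr(mask, "threshold") <- t
  mask
}

#' Fill interior cavities of a 3D binary mask
#'
#' Every background component not 6-connected to the volume border becomes
#' foreground. Idempotent.
#'
#' @param mask logical 3D array.
#' @return logical 3D array.
#' @export
fill_holes_3d <- function(mask) {
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
    mask <- array(as.logical(mask), dim(mask))
  }
  array(cpp_fill_holes(mask, dim(mask)), dim(mask))
}

#' Label connected components of a 3D binary mask
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer 3D array of component labels (0 = background).
#' @export
label_components_3d <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  array(cpp_label_components(as.logical(mask), dim(mask), connectivity), dim(mask))
}

#' Separate gland objects from a foreground mask by lumen subtraction
#'
#' Automates the manual cut between glands and the uterine lumen: the lumen
#' mask (dilated by `lumen_dilation_vox` voxels) is subtracted from the
#' foreground, and the remaining 26-connected components of at least
#' `min_volume_voxels` voxels become gland objects. Each object's attachment
#' point is its voxel nearest the lumen surface (ties broken by lowest
#' (z, y, x) index).
#'
#' @param mask logical 3D foreground mask (glands, possibly touching lumen).
#' @param lumen_mask logical 3D lumen mask, same shape.
#' @param voxel_size_um numeric(3) spacing in um.
#' @param min_volume_voxels minimum component size kept (default 50).
#' @param lumen_dilation_vox lumen dilation in voxels before subtraction.
#' @return list of `gland_object`s: `label`, `voxels` (linear indices),
#'   `n_voxels`, `volume_um3`, `attachment_point_um`, `touches_border`,
#'   `compartment = "gland"`. Empty list when nothing remains.
#' @export
separate_glands <- function(mask, lumen_mask, voxel_size_um,
                            min_volume_voxels = 50L, lumen_dilation_vox = 1L) {
  voxel_size_um <- check_voxel_size(voxel_size_um)
  if (!identical(dim(mask), dim(lumen_mask)))
    stop("mask and lumen_mask must have identical shapes")
  if (!any(lumen_mask)) stop("lumen mask is empty")
  dims <- dim(mask)
  cut <- as.logical(lumen_mask)
  if (lumen_dilation_vox > 0) {
    r <- lumen_dilation_vox
    off <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
    storage.mode(off) <- "integer"
    cut <- cpp_binary_dilate(cut, dims, off)
  }
  gmask <- as.logical(mask) & !array(cut, dims)
  labels <- label_components_3d(array(gmask, dims), 26L)
  if (max(labels) == 0) return(list())
  # attachment candidates: gland voxels one step from the lumen cut zone
  off6 <- matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
                 ncol = 3, byrow = TRUE)
  storage.mode(off6) <- "integer"
  ring <- array(cpp_binary_dilate(cut, dims, off6), dims) & gmask
  not_lum <- !as.logical(lumen_mask)
  touch_bg <- cpp_binary_dilate(not_lum, dims, off6)
  lum_surface <- which(as.logical(lumen_mask) & array(touch_bg, dims))
  ls_coord <- arrayInd(lum_surface, dims)
  ls_um <- sweep(ls_coord - 1, 2, voxel_size_um, "*")
  if (nrow(ls_um) > 1000) ls_um <- ls_um[seq(1, nrow(ls_um), length.out = 1000), , drop = FALSE]
  out <- list()
  keep_label <- 0L
  for (lab in seq_len(max(labels))) {
    idx <- which(labels == lab)
    if (length(idx) < min_volume_voxels) next
    keep_label <- keep_label + 1L
    coord <- arrayInd(idx, dims)
    um <- sweep(coord - 1, 2, voxel_size_um, "*")
    cand <- which(ring[idx])
    if (!length(cand)) cand <- seq_along(idx)   # component never touches the cut zone
    d2 <- rep(Inf, length(cand))
    for (s in seq_len(nrow(ls_um)))
      d2 <- pmin(d2, (um[cand, 1] - ls_um[s, 1])^2 + (um[cand, 2] - ls_um[s, 2])^2 +
                   (um[cand, 3] - ls_um[s, 3])^2)
    # lowest (z,y,x) among ties
    near <- cand[d2 <= min(d2) + 1e-9]
    ord <- near[order(coord[near, 1], coord[near, 2], coord[near, 3])][1]
    tb <- any(coord[, 1] %in% c(1L, dims[1]) | coord[, 2] %in% c(1L, dims[2]) |
                coord[, 3] %in% c(1L, dims[3]))
    out[[keep_label]] <- structure(list(
      label = keep_label,
      voxels = idx,
      n_voxels = length(idx),
      volume_um3 = length(idx) * voxel_volume_um3(voxel_size_um),
      attachment_point_um = um[ord, ],
      touches_border = tb,
      compartment = "gland",
      dims = dims,
      voxel_size_um = voxel_size_um), class = "gland_object")
  }
  out
}

#' @export
print.gland_object <- function(x, ...) {
  cat(sprintf("gland_object %d: %d voxels (%.0f um^3), attachment (%.1f, %.1f, %.1f) um%s\n",
              x$label, x$n_voxels, x$volume_um3,
              x$attachment_point_um[1], x$attachment_point_um[2], x$attachment_point_um[3],
              if (x$touches_border) ", touches border" else ""))
  invisible(x)
}

#' Convert gland objects back to a label mask
#' @param glands list of `gland_object`s from [separate_glands()].
#' @param dims volume shape (taken from the glands when omitted).
#' @return a [label_mask()] with all labels tagged `gland`.
#' @export
glands_to_label_mask <- function(glands, dims = NULL) {
  if (length(glands) == 0) stop("no gland objects supplied")
  if (is.null(dims)) dims <- glands[[1]]$dims
  labels <- array(0L, dims)
  for (g in glands) labels[g$voxels] <- g$label
  lt <- data.frame(label = vapply(glands, `[[`, numeric(1), "label"),
                   compartment = "gland")
  label_mask(labels, glands[[1]]$voxel_size_um, lt)
}

#' End-to-end gland segmentation from a gland-marker channel
#'
#' Background subtraction, thresholding, 3D hole filling and lumen
#' separation, in the order of the imaging protocol this package models.
#'
#' @param vol a [volume_image()].
#' @param lumen_mask logical 3D lumen mask (curated, fitted, or ground truth).
#' @param channel gland-marker channel name or index.
#' @param sphere_diameter_um background-subtraction sphere diameter (um);
#'   `NULL` skips background subtraction.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold value when `threshold_method = "fixed"`.
#' @param min_volume_voxels,lumen_dilation_vox passed to [separate_glands()].
#' @return list with `glands` (gland objects), `mask` (filled binary mask)
#'   and `threshold` (applied cutoff).
#' @export
segment_glands <- function(vol, lumen_mask, channel = 1L,
                           sphere_diameter_um = 30, threshold_method = "otsu",
                           threshold = NULL, min_volume_voxels = 50L,
                           lumen_dilation_vox = 1L) {
  arr <- get_channel(vol, channel)
  if (!is.null(sphere_diameter_um))
    arr <- subtract_background(arr, sphere_diameter_um, voxel_size_um = vol$voxel_size_um)
  mask <- binarize(arr, threshold_method, threshold = threshold)
  th <- attr(mask, "threshold")
  mask <- fill_holes_3d(mask)
  glands <- separate_glands(mask, lumen_mask, vol$voxel_size_um,
                            min_volume_voxels, lumen_dilation_vox)
  list(glands = glands, mask = mask, threshold = th)
}
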