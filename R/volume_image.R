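#' Multi-channel 3D intensity volume
#'
#' The universal raster container of the pipeline: a 3D (single channel) or 4D
#' (multi-channel) nonnegative intensity grid with anisotropic voxel spacing.
#' Data are stored as an array with dim `(nz, ny, nx)` or `(nz, ny, nx, nc)`;
#' voxel indices are interpreted 0-based in physical space, so the voxel at R
#' index `(iz, iy, ix)` sits at `((iz-1)*sz, (iy-1)*sy, (ix-1)*sx)` micrometres
#' (voxel centers).
#'
#' @param data numeric array, dim `(nz, ny, nx)` or `(nz, ny, nx, nc)`;
#'   finite, nonnegative intensities.
#' @param voxel_size_um numeric(3), strictly positive spacing `(z, y, x)` in
#'   micrometres.
#' @param channel_names character vector naming each channel; length must match
#'   the channel axis (a single name for 3D data).
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size_um, channel_names = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("data must be a 3D or 4D array (z, y, x[, channel])")
  if (any(!is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be nonnegative")
  voxel_size_um <- check_voxel_size(voxel_size_um)
  nc <- if (length(dim(data)) == 4L) dim(data)[4] else 1L
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names length (", length(channel_names),
         ") does not match number of channels (", nc, ")")
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 channel_names = as.character(channel_names)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat("volume_image:", d[1], "z x", d[2], "y x", d[3], "x voxels,",
      n_channels(x), "channel(s)\n")
  cat("  voxel size (z,y,x):", paste(signif(x$voxel_size_um, 4), collapse = " x "), "um\n")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(vol) if (length(dim(vol$data)) == 4L) dim(vol$data)[4] else 1L

#' Extract one channel of a volume as a 3D array
#'
#' @param vol a [volume_image()].
#' @param channel channel name or index.
#' @return 3D numeric array `(nz, ny, nx)`.
#' @export
get_channel <- function(vol, channel = 1L) {
  stopifnot(inherits(vol, "volume_image"))
  if (is.character(channel)) {
    idx <- match(channel, vol$channel_names)
    if (is.na(idx)) stop("unknown channel: ", channel)
  } else idx <- as.integer(channel)
  if (idx < 1 || idx > n_channels(vol)) stop("channel index out of range")
  if (length(dim(vol$data)) == 3L) vol$data else vol$data[, , , idx, drop = TRUE]
}

#' Labeled voxel mask aligned with a volume
#'
#' Programmatic stand-in for interactively curated surface objects: an integer
#' label grid (0 = background) plus a table mapping labels to anatomical
#' compartments.
#'
#' @param labels integer 3D array; nonnegative labels, 0 = background.
#' @param voxel_size_um numeric(3), spacing `(z, y, x)` in micrometres.
#' @param label_table data.frame with columns `label` and `compartment`
#'   (values in `lumen`, `gland`, `embryo`, `other`); defaults to all labels
#'   tagged `other`.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, voxel_size_um, label_table = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(labels < 0)) stop("labels must be nonnegative")
  storage.mode(labels) <- "integer"
  voxel_size_um <- check_voxel_size(voxel_size_um)
  present <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(label_table)) {
    label_table <- data.frame(label = present,
                              compartment = rep("other", length(present)),
                              stringsAsFactors = FALSE)
  }
  ok <- label_table$compartment %in% c("lumen", "gland", "embryo", "other")
  if (!all(ok)) stop("unknown compartment tag: ",
                     paste(unique(label_table$compartment[!ok]), collapse = ", "))
  structure(list(labels = labels, voxel_size_um = voxel_size_um,
                 label_table = label_table),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat("label_mask:", d[1], "z x", d[2], "y x", d[3], "x voxels,",
      nrow(x$label_table), "label(s)\n")
  invisible(x)
}

voxel_volume_um3 <- function(voxel_size_um) prod(voxel_size_um)

# physical coordinates (um, z/y/x) of the TRUE voxels of a 3D mask
mask_coords_um <- function(mask, voxel_size_um) {
  idx <- which(mask)
  arr <- arrayInd(idx, dim(mask))
  cbind(z = (arr[, 1] - 1) * voxel_size_um[1],
        y = (arr[, 2] - 1) * voxel_size_um[2],
        x = (arr[, 3] - 1) * voxel_size_um[3])
}
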