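#' Write a volume to multi-page TIFF with a JSON metadata sidecar
#'
#' Frames are written z-major with channels fastest within each z-plane
#' (ZCYX page order). Intensities are stored as 16-bit (or 8-bit) samples;
#' integer-valued volumes round-trip exactly. Voxel spacing, channel names and
#' array shape are written to `<path>.meta.json` (the bundled TIFF writer
#' cannot embed an ImageDescription tag, so metadata travel in the sidecar).
#'
#' @param vol a [volume_image()].
#' @param path output file path (`.tif`).
#' @param bit_depth 8 or 16; intensities must fit the chosen depth.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, bit_depth = 16L) {
  stopifnot(inherits(vol, "volume_image"))
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (max(vol$data) > maxval)
    stop("intensities exceed ", bit_depth, "-bit range; rescale first")
  nc <- n_channels(vol)
  d <- dim(vol$data)
  frames <- vector("list", d[1] * nc)
  for (z in seq_len(d[1])) for (c in seq_len(nc)) {
    plane <- if (nc == 1L && length(d) == 3L) vol$data[z, , ] else vol$data[z, , , c]
    frames[[(z - 1) * nc + c]] <- plane / maxval
  }
  tiff::writeTIFF(frames, path, bits.per.sample = bit_depth, compression = "none")
  meta <- list(voxel_size_um = vol$voxel_size_um,
               channel_names = vol$channel_names,
               shape_zyx = d[1:3], n_channels = nc,
               axis_order = "ZCYX", bit_depth = bit_depth)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a volume written by [write_volume()] (or a plain TIFF stack)
#'
#' Axis order is normalized to `(z, y, x[, channel])`. Voxel spacing is taken
#' from the JSON sidecar when present, else from `voxel_size_um`; if neither is
#' available the read fails rather than guessing.
#'
#' @param path TIFF file path.
#' @param voxel_size_um optional numeric(3) spacing override `(z, y, x)` in um,
#'   used when no sidecar metadata exist.
#' @return a [volume_image()].
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  nframes <- length(frames)
  if (is.null(meta) && nframes < 2L)
    stop("2D TIFF (single page, no metadata sidecar): a 3D stack is required")
  nc <- if (!is.null(meta)) as.integer(meta$n_channels) else 1L
  nz <- nframes / nc
  if (nz != round(nz)) stop("page count ", nframes, " is not a multiple of channel count ", nc)
  nz <- as.integer(nz)
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  data <- array(0, dim = c(nz, ny, nx, nc))
  for (z in seq_len(nz)) for (c in seq_len(nc))
    data[z, , , c] <- frames[[(z - 1) * nc + c]]
  if (nc == 1L) data <- array(data, dim = c(nz, ny, nx))
  vs <- if (!is.null(meta)) as.numeric(meta$voxel_size_um) else voxel_size_um
  if (is.null(vs)) stop("no voxel spacing: file carries no metadata sidecar and no ",
                        "voxel_size_um override was supplied")
  ch <- if (!is.null(meta)) meta$channel_names else NULL
  volume_image(data, vs, ch)
}

#' Write a label mask to TIFF (+ sidecar with the label table)
#' @param mask a [label_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535) stop("more than 65535 labels not supported")
  vol <- volume_image(mask$labels + 0, mask$voxel_size_um, "labels")
  write_volume(vol, path, bit_depth = 16L)
  meta_path <- paste0(path, ".meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  meta$label_table <- mask$label_table
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#' @param path TIFF path.
#' @return a [label_mask()].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  lt <- if (!is.null(meta$label_table)) as.data.frame(meta$label_table) else NULL
  labels <- vol$data
  storage.mode(labels) <- "integer"
  label_mask(labels, vol$voxel_size_um, lt)
}

#' Write a measurement table as CSV with a provenance sidecar
#'
#' Writes `records` with a stable column order plus `<path>.prov.json`
#' containing the config hash, seed and package version. Output is
#' deterministic: the same records produce byte-identical files.
#'
#' @param records non-empty data.frame.
#' @param path CSV output path.
#' @param config optional list describing the run configuration (hashed into
#'   the sidecar).
#' @param seed optional integer seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, config = NULL, seed = NULL) {
  if (is.null(records) || !is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data.frame")
  records <- records[, sort(names(records)), drop = FALSE]
  write.csv(records, path, row.names = FALSE)
  prov <- list(config_hash = if (is.null(config)) NA else hash_object(config),
               seed = if (is.null(seed)) NA else seed,
               package_version = as.character(packageVersion("glandmorph")),
               n_records = nrow(records),
               columns = names(records))
  jsonlite::write_json(prov, paste0(path, ".prov.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
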