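#' Embryo-uterine axis alignment angle
#'
#' Reproduces the three-point measurement of embryo orientation: the embryo
#' axis runs from the abembryonic pole to the inner cell mass (ICM), and its
#' angle to the mesometrial-antimesometrial (M-AM) axis is measured in the
#' imaging plane. The axis vector `v = icm - abembryonic` is projected onto
#' the plane spanned by the M-AM axis and the in-plane (XY) component of `v`
#' orthogonal to it, and the unsigned angle to the M-AM axis is returned,
#' folded into `[0, 90]` degrees (alignment is a direction, not an
#' orientation). Coordinates are `(z, y, x)` with z the optical axis.
#'
#' @param icm_point numeric(3) ICM point (um).
#' @param abembryonic_point numeric(3) abembryonic-pole point (um).
#' @param mam_axis numeric(3) M-AM axis direction (mesometrial positive);
#'   need not be normalized.
#' @return angle in degrees in `[0, 90]`; `NA` with a warning when the axis
#'   vector is purely axial (no in-plane component).
#' @export
compute_axis_angle <- function(icm_point, abembryonic_point, mam_axis) {
  v <- as.numeric(icm_point) - as.numeric(abembryonic_point)
  if (vnorm(v) < 1e-12)
    stop(errorCondition("ICM and abembryonic points coincide",
                        class = c("glandmorph_domain_error", "error", "condition")))
  if (vnorm(as.numeric(mam_axis)) < 1e-12)
    stop(errorCondition("M-AM axis vector is zero",
                        class = c("glandmorph_domain_error", "error", "condition")))
  m <- unit(as.numeric(mam_axis))
  w <- c(0, v[2], v[3])                    # in-plane (imaging XY) component of v
  if (vnorm(w) < 1e-12) {
    warning("axis vector is purely along the optical axis; angle undefined")
    return(NA_real_)
  }
  wp <- w - sum(w * m) * m
  a <- sum(v * m)
  if (vnorm(wp) < 1e-9 * vnorm(v)) {
    # v's in-plane part is parallel to the M-AM axis
    return(if (abs(a) > 0) 0 else 90)
  }
  b <- sum(v * unit(wp))
  atan2(abs(b), abs(a)) * 180 / pi
}

#' Measure embryo axis orientation
#'
#' For a ground-truth scene, returns the angle computed from the stored ICM
#' and abembryonic points. For a rendered volume, embryos are detected as
#' large bright clusters in the nuclei channel; the ICM is the centroid of the
#' brightest voxels of a cluster (the ICM is rendered denser), and the
#' abembryonic pole is the cluster boundary point antipodal to the ICM
#' through the cluster centroid.
#'
#' @param x a `gland_scene` or a [volume_image()] with a nuclei channel.
#' @param mam_axis numeric(3) M-AM axis (default `(0, 1, 0)`, mesometrial
#'   towards +y).
#' @param channel nuclei channel name or index (volumes only).
#' @param min_embryo_volume_um3 minimum cluster volume treated as an embryo.
#' @return data.frame with one row per embryo: `embryo_id`, ICM and
#'   abembryonic coordinates (um), `angle_deg`. Empty (with a message) when
#'   no embryo is found.
#' @export
measure_embryos <- function(x, mam_axis = c(0, 1, 0), channel = "nuclei",
                            min_embryo_volume_um3 = 2e4) {
  empty <- data.frame(embryo_id = integer(0), icm_z_um = numeric(0),
                      icm_y_um = numeric(0), icm_x_um = numeric(0),
                      ab_z_um = numeric(0), ab_y_um = numeric(0), ab_x_um = numeric(0),
                      angle_deg = numeric(0))
  if (inherits(x, "gland_scene")) {
    if (!length(x$embryos)) { message("no embryos in scene"); return(empty) }
    return(do.call(rbind, lapply(x$embryos, function(e) data.frame(
      embryo_id = e$embryo_id,
      icm_z_um = e$icm_point_um[1], icm_y_um = e$icm_point_um[2], icm_x_um = e$icm_point_um[3],
      ab_z_um = e$abembryonic_point_um[1], ab_y_um = e$abembryonic_point_um[2],
      ab_x_um = e$abembryonic_point_um[3],
      angle_deg = compute_axis_angle(e$icm_point_um, e$abembryonic_point_um, mam_axis)))))
  }
  stopifnot(inherits(x, "volume_image"))
  arr <- get_channel(x, channel)
  vs <- x$voxel_size_um
  mask <- tryCatch(binarize(arr, "otsu"), error = function(e) NULL)
  if (is.null(mask) || !any(mask)) { message("no embryo found"); return(empty) }
  labels <- label_components_3d(mask, 26L)
  vox_um3 <- voxel_volume_um3(vs)
  rows <- list()
  for (lab in seq_len(max(labels))) {
    idx <- which(labels == lab)
    if (length(idx) * vox_um3 < min_embryo_volume_um3) next
    co <- arrayInd(idx, dim(arr))
    um <- sweep(co - 1, 2, vs, "*")
    ints <- arr[idx]
    ctr <- colSums(um * ints) / sum(ints)
    icm_sel <- ints >= (max(ints) + median(ints)) / 2
    ci <- colMeans(um[icm_sel, , drop = FALSE])
    u <- ci - ctr
    if (vnorm(u) < 1e-9) next
    u <- unit(u)
    t_max <- max(as.numeric(sweep(um, 2, ctr, "-") %*% (-u)))
    ab <- ctr - t_max * u
    rows[[length(rows) + 1L]] <- data.frame(
      embryo_id = NA_integer_,
      icm_z_um = ci[1], icm_y_um = ci[2], icm_x_um = ci[3],
      ab_z_um = ab[1], ab_y_um = ab[2], ab_x_um = ab[3],
      angle_deg = compute_axis_angle(ci, ab, mam_axis),
      x_order = ctr[3])
  }
  if (!length(rows)) { message("no embryo found"); return(empty) }
  out <- do.call(rbind, rows)
  out <- out[order(out$x_order), , drop = FALSE]
  out$embryo_id <- seq_len(nrow(out))
  out$x_order <- NULL
  rownames(out) <- NULL
  out
}
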