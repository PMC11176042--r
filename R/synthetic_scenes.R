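#' Voxel-spacing presets
#'
#' Two acquisition presets: `whole_mount` mirrors tiled whole-horn stacks
#' (7 um optical sections, 1.52 um pixels at 10x) and `section` mirrors
#' cryosection stacks (1.5 um z-spacing, 0.76 um pixels at 20x).
#'
#' @param preset `"whole_mount"` or `"section"`.
#' @return numeric(3) voxel size `(z, y, x)` in micrometres.
#' @export
voxel_preset <- function(preset = c("whole_mount", "section")) {
  preset <- match.arg(preset)
  switch(preset,
         whole_mount = c(7, 1.52, 1.52),
         section     = c(1.5, 0.76, 0.76))
}

BRANCH_CATEGORIES <- c("0", "1-3", ">3")

#' Branch-count category
#'
#' Gland branching is reported in three categories: unbranched (`"0"`),
#' `"1-3"` branch points, and `">3"` (four or more) branch points.
#'
#' @param n_branch_points integer vector of branch-point counts.
#' @return factor with levels `0`, `1-3`, `>3`.
#' @export
branch_category <- function(n_branch_points) {
  if (any(n_branch_points < 0)) stop("branch counts must be nonnegative")
  lab <- ifelse(n_branch_points == 0, "0",
                ifelse(n_branch_points <= 3, "1-3", ">3"))
  factor(lab, levels = BRANCH_CATEGORIES)
}

#' Specification of a synthetic uterine scene
#'
#' Parameterizes a ground-truth scene: a luminal tube with attached gland
#' trees of known branch number and length, optional blastocysts with known
#' axis orientation, punctate transcript signal of known volume fraction, and
#' marker-positive epithelial cells of known fraction.
#'
#' @param volume_shape_voxels integer(3) `(nz, ny, nx)`.
#' @param voxel_size_um numeric(3) spacing `(z, y, x)` in um; see [voxel_preset()].
#' @param lumen_radius_um luminal tube radius (um).
#' @param n_glands number of gland trees.
#' @param branch_count_distribution named probabilities over categories
#'   `c("0" = , "1-3" = , ">3" = )`; must sum to 1. Ignored when
#'   `branch_counts` is given.
#' @param branch_counts optional explicit per-gland branch-point counts
#'   (length `n_glands`).
#' @param gland_length_range_um range of trunk lengths (um).
#' @param gland_radius_um gland tube radius (um).
#' @param tortuosity per-step direction jitter (dimensionless, >= 0).
#' @param embryo_axis_angle_deg optional embryo axis angle(s), each in [0, 90].
#' @param lif_volume_fraction fraction of gland volume carrying transcript
#'   signal, in [0, 1].
#' @param esr1_positive_fraction fraction of gland cells positive for the
#'   marker, in [0, 1].
#' @param n_gland_cells number of gland epithelial cells to place (0 = none).
#' @param seed integer RNG seed; identical specs give identical scenes.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(volume_shape_voxels = c(24, 180, 360),
                       voxel_size_um = voxel_preset("whole_mount"),
                       lumen_radius_um = 25,
                       n_glands = 6,
                       branch_count_distribution = c("0" = 0.52, "1-3" = 0.39, ">3" = 0.09),
                       branch_counts = NULL,
                       gland_length_range_um = c(80, 160),
                       gland_radius_um = 6,
                       tortuosity = 0.15,
                       embryo_axis_angle_deg = NULL,
                       lif_volume_fraction = 0,
                       esr1_positive_fraction = 0,
                       n_gland_cells = 0,
                       seed = 1L) {
  voxel_size_um <- check_voxel_size(voxel_size_um)
  volume_shape_voxels <- as.integer(volume_shape_voxels)
  if (length(volume_shape_voxels) != 3 || any(volume_shape_voxels < 4))
    stop("volume_shape_voxels must be three integers >= 4")
  if (lumen_radius_um <= 0) stop("lumen_radius_um must be positive")
  if (n_glands < 0) stop("n_glands must be nonnegative")
  if (!is.null(branch_counts)) {
    if (length(branch_counts) != n_glands)
      stop("branch_counts must have length n_glands")
    if (any(branch_counts < 0)) stop("branch counts must be nonnegative")
  } else {
    if (is.null(names(branch_count_distribution)) ||
        !setequal(names(branch_count_distribution), BRANCH_CATEGORIES))
      stop("branch_count_distribution must be named over categories ",
           paste(BRANCH_CATEGORIES, collapse = ", "))
    branch_count_distribution <- branch_count_distribution[BRANCH_CATEGORIES]
    if (any(branch_count_distribution < 0) ||
        abs(sum(branch_count_distribution) - 1) > 1e-8)
      stop("branch_count_distribution probabilities must be nonnegative and sum to 1")
  }
  if (length(gland_length_range_um) != 2 || any(gland_length_range_um <= 0) ||
      diff(gland_length_range_um) < 0)
    stop("gland_length_range_um must be a positive interval")
  if (gland_radius_um <= 0) stop("gland_radius_um must be positive")
  if (tortuosity < 0) stop("tortuosity must be nonnegative")
  if (!is.null(embryo_axis_angle_deg) &&
      (any(embryo_axis_angle_deg < 0) || any(embryo_axis_angle_deg > 90)))
    stop("embryo_axis_angle_deg must lie in [0, 90]")
  if (lif_volume_fraction < 0 || lif_volume_fraction > 1)
    stop("lif_volume_fraction must lie in [0, 1]")
  if (esr1_positive_fraction < 0 || esr1_positive_fraction > 1)
    stop("esr1_positive_fraction must lie in [0, 1]")
  structure(list(volume_shape_voxels = volume_shape_voxels,
                 voxel_size_um = voxel_size_um,
                 lumen_radius_um = lumen_radius_um,
                 n_glands = as.integer(n_glands),
                 branch_count_distribution =
                   if (is.null(branch_counts)) branch_count_distribution else NULL,
                 branch_counts = if (is.null(branch_counts)) NULL else as.integer(branch_counts),
                 gland_length_range_um = as.numeric(gland_length_range_um),
                 gland_radius_um = gland_radius_um,
                 tortuosity = tortuosity,
                 embryo_axis_angle_deg = embryo_axis_angle_deg,
                 lif_volume_fraction = lif_volume_fraction,
                 esr1_positive_fraction = esr1_positive_fraction,
                 n_gland_cells = as.integer(n_gland_cells),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Round-trip a scene spec through a YAML config file
#' @param spec a [scene_spec()].
#' @param path YAML file path.
#' @return `path` invisibly / the re-validated `scene_spec`.
#' @export
write_scene_config <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  x <- unclass(spec)
  x$branch_count_distribution <- as.list(x$branch_count_distribution)
  yaml::write_yaml(x[!vapply(x, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$branch_count_distribution))
    x$branch_count_distribution <- unlist(x$branch_count_distribution)
  do.call(scene_spec, x)
}

geometry_error <- function(msg) {
  stop(errorCondition(msg, class = c("glandmorph_geometry_error", "error", "condition")))
}

rand_unit3 <- function() unit(rnorm(3))

# Rodrigues rotation of v by angle (rad) around unit axis a
rotate_about <- function(v, a, angle) {
  v * cos(angle) + pracma_cross(a, v) * sin(angle) + a * sum(a * v) * (1 - cos(angle))
}
pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                 a[3] * b[1] - a[1] * b[3],
                                 a[1] * b[2] - a[2] * b[1])

# Grow one polyline arm from `start` with initial direction `dir`.
# Returns matrix of new vertex positions, or NULL if placement failed.
grow_arm <- function(start, dir, n_steps, step_um, tort, bounds, other_pts, min_sep, zw,
                     lumen = NULL, skip_lumen_first = 0L) {
  pts <- matrix(0, n_steps, 3)
  p <- start
  d <- dir
  for (s in seq_len(n_steps)) {
    placed <- FALSE
    for (try in 1:20) {
      dd <- unit(d + tort * rnorm(3) * c(zw, 1, 1) + c(0, -0.04, 0))
      # soft reflection at bounds
      q <- p + step_um * dd
      if (q[1] < bounds$z[1] || q[1] > bounds$z[2]) dd[1] <- -dd[1]
      if (q[2] < bounds$y[1] || q[2] > bounds$y[2]) dd[2] <- -dd[2]
      if (q[3] < bounds$x[1] || q[3] > bounds$x[2]) dd[3] <- -dd[3]
      dd <- unit(dd)
      q <- p + step_um * dd
      q[1] <- min(max(q[1], bounds$z[1]), bounds$z[2])
      q[2] <- min(max(q[2], bounds$y[1]), bounds$y[2])
      q[3] <- min(max(q[3], bounds$x[1]), bounds$x[2])
      ok <- TRUE
      # keep clear of the luminal tube so the lumen cut never severs a tree
      if (!is.null(lumen) && s > skip_lumen_first) {
        rad <- sqrt((q[1] - lumen$z)^2 + (q[2] - lumen$y)^2)
        if (rad < lumen$clear) ok <- FALSE
      }
      if (ok && !is.null(other_pts) && nrow(other_pts) > 0) {
        d2 <- (other_pts[, 1] - q[1])^2 + (other_pts[, 2] - q[2])^2 + (other_pts[, 3] - q[3])^2
        ok <- min(d2) >= min_sep^2
      }
      # no U-turns onto the arm's own earlier course
      if (ok && s > 5) {
        prev <- pts[seq_len(s - 5), , drop = FALSE]
        d2 <- (prev[, 1] - q[1])^2 + (prev[, 2] - q[2])^2 + (prev[, 3] - q[3])^2
        ok <- min(d2) >= min_sep^2
      }
      if (ok) { d <- dd; p <- q; pts[s, ] <- q; placed <- TRUE; break }
      d <- unit(d + 0.6 * rnorm(3) * c(zw, 1, 1)) # deflect harder and retry
    }
    if (!placed) return(NULL)
  }
  pts
}

# Grow a whole gland tree with exactly k branch points; NULL on failure.
grow_gland <- function(attach_pt, u0, k, trunk_len_um, step_um, tort, bounds, zw, min_sep,
                       lumen = NULL) {
  # a trunk must be long enough to host at least one junction with full
  # origin/tip clearances (positions 5..len-8), and two slots per k overall
  n_trunk <- max(round(trunk_len_um / step_um), 2 * k + 6, if (k > 0) 21L else 0L)
  trunk <- grow_arm(attach_pt, u0, n_trunk, step_um, tort, bounds, NULL, min_sep, zw,
                    lumen = lumen, skip_lumen_first = 3L)
  if (is.null(trunk)) return(NULL)
  V <- rbind(attach_pt, trunk)
  parent <- c(0L, seq_len(n_trunk))              # parent of vertex i+1 is i
  arm_id <- rep(0L, n_trunk + 1)
  arm_pos <- 0:n_trunk
  arm_len <- c(`0` = n_trunk)                    # named by arm id
  nchild <- c(rep(1L, n_trunk), 0L)
  is_junction <- rep(FALSE, n_trunk + 1)
  for (j in seq_len(k)) {
    done <- FALSE
    for (try in 1:60) {
      # eligible roots: interior vertices (1 parent, 1 child), not near junctions/ends
      deg <- (parent > 0) + nchild
      elig <- which(deg == 2 & !is_junction)
      # keep away from arm ends and existing junctions (>= 2 steps)
      near_junction <- rep(FALSE, length(parent))
      jidx <- which(is_junction)
      for (q in jidx) near_junction[abs(arm_pos - arm_pos[q]) <= 7 & arm_id == arm_id[q]] <- TRUE
      elig <- setdiff(elig, which(near_junction))
      # keep junctions away from arm origins and arm tips so neither the
      # origin-junction merge nor tip-spur pruning can swallow them; side
      # arms start at a junction, so they need more clearance than the trunk
      min_pos <- ifelse(arm_id[elig] == 0L, 9L, 8L)
      elig <- elig[arm_pos[elig] >= min_pos &
                     arm_pos[elig] <= arm_len[as.character(arm_id[elig])] - 12]
      elig <- elig[elig != 1L]
      if (length(elig) == 0) break
      root <- if (length(elig) == 1) elig else sample(elig, 1)
      pdir <- unit(V[root, ] - V[parent[root], ])
      ax <- rnorm(3); ax <- ax - sum(ax * pdir) * pdir
      if (vnorm(ax) < 1e-8) next
      ax <- unit(ax * c(zw, 1, 1) + 1e-6)
      ndir <- rotate_about(pdir, ax, runif(1, 50, 80) * pi / 180)
      if (ndir[2] > 0.25) { ndir[2] <- 0.25; }
      ndir <- unit(ndir * c(zw, 1, 1))
      n_arm <- max(if (j < k) 20 else 16, round(runif(1, 0.45, 0.75) * n_trunk))
      # collision set: all vertices except those within 4 steps of the root on its arm
      excl <- which(arm_id == arm_id[root] & abs(arm_pos - arm_pos[root]) <= 4)
      arm <- grow_arm(V[root, ], ndir, n_arm, step_um, tort, bounds,
                      V[-excl, , drop = FALSE], min_sep, zw, lumen = lumen)
      if (is.null(arm)) next
      base <- nrow(V)
      V <- rbind(V, arm)
      parent <- c(parent, root, base + seq_len(n_arm - 1))
      arm_id <- c(arm_id, rep(j, n_arm))
      arm_pos <- c(arm_pos, seq_len(n_arm))
      arm_len <- c(arm_len, stats::setNames(n_arm, as.character(j)))
      nchild <- c(nchild, rep(1L, n_arm - 1), 0L)
      nchild[root] <- nchild[root] + 1L
      is_junction <- c(is_junction, rep(FALSE, n_arm))
      is_junction[root] <- TRUE
      done <- TRUE
      break
    }
    if (!done) return(NULL)
  }
  edges <- cbind(from = parent[parent > 0], to = which(parent > 0))
  list(nodes = unname(V), edges = unname(edges), parent = parent)
}

#' Generate a ground-truth gland scene
#'
#' Builds a luminal tube along x with `n_glands` random bifurcating gland
#' trees growing away from it (anti-mesometrially), each with a known number
#' of branch points and a known attachment-to-furthest-tip length. Trees are
#' grown with a minimum mutual clearance so that rasterized tubes do not fuse.
#' Identical specs (including seed) produce identical scenes.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `gland_scene` with elements `lumen`
#'   (centerline + radius), `glands` (per gland: nodes, edges,
#'   `attachment_um`, `true_branch_points`, `true_length_um`, `category`),
#'   `cells`, `lif_voxels`, `mam_axis` and bookkeeping fields.
#' @export
make_gland_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, make_gland_scene_impl(spec))
}

make_gland_scene_impl <- function(spec) {
  vs <- spec$voxel_size_um
  ext <- spec$volume_shape_voxels * vs       # physical extent (z, y, x), um
  rg <- spec$gland_radius_um
  margin <- rg + 2 * max(vs)
  y_l <- ext[2] - spec$lumen_radius_um - margin
  z_l <- ext[1] / 2
  if (y_l <= margin)
    geometry_error("volume too shallow in y for the lumen radius")
  room_y <- y_l - spec$lumen_radius_um - margin
  Lmax <- spec$gland_length_range_um[2]
  if (spec$n_glands > 0 && room_y < 0.80 * Lmax)
    geometry_error(sprintf(
      "gland of length %.0f um does not fit below the lumen (available %.0f um)",
      Lmax, room_y))
  n <- spec$n_glands
  glands <- list()
  if (n > 0) {
    slab_w <- ext[3] / n
    if (slab_w < 2 * rg + 12)
      geometry_error("too many glands for the volume x-extent: slabs narrower than one gland")
    ks <- if (!is.null(spec$branch_counts)) spec$branch_counts else {
      cat_draw <- sample(BRANCH_CATEGORIES, n, replace = TRUE,
                         prob = spec$branch_count_distribution)
      vapply(cat_draw, function(cc) switch(cc,
                                           "0" = 0L,
                                           "1-3" = sample(1:3, 1),
                                           ">3" = sample(4:8, 1)), integer(1))
    }
    zw <- min(1, (ext[1] - 2 * margin) / 60)   # limit z wander in thin stacks
    step_um <- 8
    min_sep <- 2 * rg + 12
    lumen_clear <- list(z = z_l, y = y_l, clear = spec$lumen_radius_um + rg + 9)
    for (i in seq_len(n)) {
      x0 <- (i - 1) * slab_w
      bounds <- list(z = c(margin, ext[1] - margin),
                     y = c(margin, y_l - spec$lumen_radius_um * 0.88),
                     x = c(x0 + rg + 2, x0 + slab_w - rg - 2))
      tree <- NULL
      for (attempt in 1:40) {
        theta <- runif(1, -25, 25) * pi / 180
        x_a <- x0 + slab_w * runif(1, 0.4, 0.6)
        attach_pt <- c(z_l + spec$lumen_radius_um * sin(theta) * zw,
                       y_l - spec$lumen_radius_um * cos(theta),
                       x_a)
        radial <- unit(c(sin(theta) * zw, -cos(theta), 0))
        u0 <- unit(0.5 * radial + c(0, -0.9, 0) + c(0, 0, runif(1, -0.25, 0.25)))
        L <- runif(1, spec$gland_length_range_um[1], spec$gland_length_range_um[2])
        tree <- grow_gland(attach_pt, u0, ks[i], L, step_um, spec$tortuosity,
                           bounds, zw, min_sep, lumen = lumen_clear)
        if (!is.null(tree)) break
      }
      if (is.null(tree))
        geometry_error(sprintf("failed to place gland %d (%d branch points) without collisions", i, ks[i]))
      # ground truth from the realized tree
      deg <- tabulate(c(tree$edges), nbins = nrow(tree$nodes))
      tbp <- sum(deg >= 3)
      stopifnot(tbp == ks[i])
      dists <- sqrt(rowSums((tree$nodes - matrix(tree$nodes[1, ], nrow(tree$nodes), 3,
                                                 byrow = TRUE))^2))
      glands[[i]] <- list(id = i,
                          attachment_um = tree$nodes[1, ],
                          nodes = tree$nodes,
                          edges = tree$edges,
                          radius_um = rg,
                          true_branch_points = tbp,
                          true_length_um = max(dists),
                          category = as.character(branch_category(tbp)))
    }
  }
  scene <- structure(list(spec = spec,
                          volume_shape = spec$volume_shape_voxels,
                          voxel_size_um = vs,
                          extent_um = ext,
                          lumen = list(centerline = rbind(c(z_l, y_l, 0), c(z_l, y_l, ext[3])),
                                       radius_um = spec$lumen_radius_um),
                          glands = glands,
                          embryos = list(),
                          mam_axis = c(0, 1, 0),
                          cells = NULL,
                          lif_voxels = NULL),
                     class = "gland_scene")
  if (spec$n_gland_cells > 0 && length(glands) > 0)
    scene$cells <- place_gland_cells(scene, spec$n_gland_cells, spec$esr1_positive_fraction)
  if (spec$lif_volume_fraction > 0 && length(glands) > 0)
    scene$lif_voxels <- place_lif_puncta(scene, spec$lif_volume_fraction)
  scene
}

# Punctate transcript signal: spherical puncta (~3 um radius) grown inside the
# gland mask until exactly round(fraction * gland voxels) voxels are covered.
place_lif_puncta <- function(scene, fraction, punctum_radius_um = 3) {
  dims <- scene$volume_shape
  vs <- scene$voxel_size_um
  gm <- scene_masks(scene)$gland_labels
  gidx <- which(gm > 0)
  target <- round(fraction * length(gidx))
  if (target == 0) return(integer(0))
  if (target >= length(gidx)) return(sort(gidx))
  in_gland <- array(FALSE, dims); in_gland[gidx] <- TRUE
  chosen <- array(FALSE, dims)
  rv <- pmax(0L, as.integer(floor(punctum_radius_um / vs)))
  og <- expand.grid(dz = -rv[1]:rv[1], dy = -rv[2]:rv[2], dx = -rv[3]:rv[3])
  keep <- (og$dz * vs[1])^2 + (og$dy * vs[2])^2 + (og$dx * vs[3])^2 <= punctum_radius_um^2
  og <- as.matrix(og[keep, , drop = FALSE])
  n_chosen <- 0L
  while (n_chosen < target) {
    ctr <- arrayInd(sample(gidx, 1), dims)
    pz <- ctr[1] + og[, 1]; py <- ctr[2] + og[, 2]; px <- ctr[3] + og[, 3]
    ok <- pz >= 1 & pz <= dims[1] & py >= 1 & py <= dims[2] & px >= 1 & px <= dims[3]
    cand <- cbind(pz[ok], py[ok], px[ok])
    cand <- cand[in_gland[cand] & !chosen[cand], , drop = FALSE]
    if (nrow(cand) == 0) next
    take <- min(nrow(cand), target - n_chosen)   # trim the last punctum exactly
    sel <- cand[seq_len(take), , drop = FALSE]
    chosen[sel] <- TRUE
    n_chosen <- n_chosen + take
  }
  which(chosen)
}

#' @export
print.gland_scene <- function(x, ...) {
  cat("gland_scene:", length(x$glands), "gland(s),", length(x$embryos), "embryo(s)\n")
  cat("  volume:", paste(x$volume_shape, collapse = " x "), "voxels; spacing",
      paste(signif(x$voxel_size_um, 3), collapse = "/"), "um\n")
  if (length(x$glands)) {
    k <- vapply(x$glands, `[[`, numeric(1), "true_branch_points")
    cat("  branch points:", paste(k, collapse = " "), "\n")
  }
  invisible(x)
}

# epithelial cell centers near gland tube walls; positives are an exact subset
place_gland_cells <- function(scene, n_cells, positive_fraction) {
  segs <- do.call(rbind, lapply(scene$glands, function(g)
    cbind(g$nodes[g$edges[, 1], , drop = FALSE], g$nodes[g$edges[, 2], , drop = FALSE])))
  pick <- sample(nrow(segs), n_cells, replace = TRUE)
  t <- runif(n_cells)
  ctr <- segs[pick, 1:3] + t * (segs[pick, 4:6] - segs[pick, 1:3])
  off <- t(vapply(seq_len(n_cells), function(i) rand_unit3(), numeric(3)))
  r_off <- scene$glands[[1]]$radius_um * 0.55
  pos <- ctr + off * r_off
  n_pos <- round(positive_fraction * n_cells)
  positive <- rep(FALSE, n_cells)
  if (n_pos > 0) positive[sample(n_cells, n_pos)] <- TRUE
  data.frame(id = seq_len(n_cells), z = pos[, 1], y = pos[, 2], x = pos[, 3],
             radius_um = 2.5, positive = positive)
}

#' Generate a ground-truth embryo scene
#'
#' Places one blastocyst ellipsoid per requested angle inside the luminal
#' tube, with a denser inner-cell-mass (ICM) sub-ellipsoid positioned so that
#' the ICM-to-abembryonic axis makes exactly `angle_deg` with the stored
#' mesometrial-antimesometrial (M-AM) axis under the in-plane projection
#' convention of [compute_axis_angle()].
#'
#' @param angle_deg numeric vector of angles in [0, 90]; one embryo per angle.
#' @param spec a [scene_spec()]; `lumen_radius_um` should accommodate the
#'   blastocyst (~60 um works with the defaults).
#' @return a `gland_scene` whose `embryos` list holds, per embryo:
#'   `center_um`, `semi_axes_um`, `axes` (unit rows), `icm_point_um`,
#'   `abembryonic_point_um`, `true_angle_deg`.
#' @export
make_embryo_scene <- function(angle_deg, spec = scene_spec(lumen_radius_um = 60, n_glands = 0)) {
  if (any(angle_deg < 0) || any(angle_deg > 90))
    stop(errorCondition("embryo axis angle must lie in [0, 90] degrees",
                        class = c("glandmorph_domain_error", "error", "condition")))
  scene <- make_gland_scene(spec)
  ext <- scene$extent_um
  ne <- length(angle_deg)
  m_hat <- unit(scene$mam_axis)
  w_hat <- c(0, 0, 1)                       # in-plane direction orthogonal to M-AM
  a_long <- min(0.8 * spec$lumen_radius_um, 42)
  if (a_long < 15) geometry_error("lumen too narrow to host a blastocyst")
  cl <- scene$lumen$centerline
  embryos <- vector("list", ne)
  for (i in seq_len(ne)) {
    ang <- angle_deg[i] * pi / 180
    u <- cos(ang) * m_hat + sin(ang) * w_hat
    ctr <- c(cl[1, 1], cl[1, 2], (i - 0.5) * ext[3] / ne)
    v2 <- unit(pracma_cross(u, c(1, 0, 0)))
    v3 <- pracma_cross(u, v2)
    embryos[[i]] <- list(embryo_id = i,
                         center_um = ctr,
                         semi_axes_um = c(a_long, 0.72 * a_long, 0.72 * a_long),
                         axes = rbind(u, v2, v3),
                         icm_center_um = ctr + 0.55 * a_long * u,
                         icm_semi_um = 0.38 * c(a_long, 0.72 * a_long, 0.72 * a_long),
                         icm_point_um = ctr + 0.55 * a_long * u,
                         abembryonic_point_um = ctr - a_long * u,
                         true_angle_deg = angle_deg[i])
  }
  scene$embryos <- embryos
  scene
}

# ---- rasterization of ground truth -------------------------------------------------

# raw masks: gland label grid, lumen mask, embryo/icm masks, cell label grid
scene_masks <- function(scene) {
  dims <- scene$volume_shape
  vs <- scene$voxel_size_um
  gl <- integer(prod(dims))
  if (length(scene$glands) > 0) {
    segs <- do.call(rbind, lapply(scene$glands, function(g)
      cbind(g$nodes[g$edges[, 1], , drop = FALSE],
            g$nodes[g$edges[, 2], , drop = FALSE], g$radius_um)))
    labs <- unlist(lapply(scene$glands, function(g) rep(g$id, nrow(g$edges))))
    gl <- cpp_rasterize_tubes(dims, vs, segs, as.integer(labs), integer(0))
  }
  cl <- scene$lumen$centerline
  lum <- cpp_rasterize_tubes(dims, vs,
                             matrix(c(cl[1, ], cl[2, ], scene$lumen$radius_um), 1),
                             1L, integer(0)) > 0
  emb <- rep(FALSE, prod(dims)); icm <- rep(FALSE, prod(dims))
  for (e in scene$embryos) {
    emb <- emb | cpp_rasterize_ellipsoid(dims, vs, e$center_um, e$axes, e$semi_axes_um)
    icm <- icm | cpp_rasterize_ellipsoid(dims, vs, e$icm_center_um, e$axes, e$icm_semi_um)
  }
  cells <- integer(prod(dims))
  if (!is.null(scene$cells)) {
    cc <- scene$cells
    segs <- cbind(cc$z, cc$y, cc$x, cc$z, cc$y, cc$x, cc$radius_um)
    cells <- cpp_rasterize_tubes(dims, vs, segs, as.integer(cc$id), integer(0))
  }
  list(gland_labels = array(gl, dims), lumen = array(lum, dims),
       embryo = array(emb, dims), icm = array(icm, dims),
       cell_labels = array(cells, dims))
}

#' Ground-truth label mask of a scene
#'
#' Gland labels with the (dilated) lumen removed, plus the lumen itself under
#' its own label — the reference against which segmentation output is scored.
#'
#' @param scene a `gland_scene`.
#' @param lumen_dilation_vox dilation of the lumen (in voxels) subtracted from
#'   the gland labels; matches the default of [separate_glands()].
#' @return a [label_mask()]; lumen label is `max(gland ids) + 1`.
#' @export
scene_label_mask <- function(scene, lumen_dilation_vox = 1) {
  m <- scene_masks(scene)
  dims <- scene$volume_shape
  lum <- m$lumen
  if (lumen_dilation_vox > 0) {
    off <- as.matrix(expand.grid(dz = -lumen_dilation_vox:lumen_dilation_vox,
                                 dy = -lumen_dilation_vox:lumen_dilation_vox,
                                 dx = -lumen_dilation_vox:lumen_dilation_vox))
    storage.mode(off) <- "integer"
    lum <- array(cpp_binary_dilate(as.logical(m$lumen), dims, off), dims)
  }
  labels <- m$gland_labels
  labels[lum & labels > 0] <- 0L
  lumen_label <- max(c(0L, vapply(scene$glands, `[[`, numeric(1), "id"))) + 1L
  labels[m$lumen] <- lumen_label
  lt <- data.frame(label = c(vapply(scene$glands, function(g) g$id, numeric(1)), lumen_label),
                   compartment = c(rep("gland", length(scene$glands)), "lumen"))
  label_mask(labels, scene$voxel_size_um, lt)
}

#' Imaging forward-model parameters
#'
#' PSF blur, then Poisson shot noise, then additive Gaussian read noise: the
#' standard fluorescence forward model, applied in that order.
#'
#' @param psf_sigma_um Gaussian PSF sigma `(z, y, x)` in um; zeros disable blur.
#' @param background_level additive background offset (intensity units).
#' @param poisson_gain photons per intensity unit for shot noise.
#' @param gaussian_sd additive Gaussian read-noise SD.
#' @param bit_depth 8 or 16.
#' @param signal_amplitude intensity of rasterized structures.
#' @param apply_poisson logical; disable for fully noiseless rendering.
#' @return an object of class `imaging_params`.
#' @export
imaging_params <- function(psf_sigma_um = c(3, 1.2, 1.2),
                           background_level = 8,
                           poisson_gain = 1,
                           gaussian_sd = 3,
                           bit_depth = 16L,
                           signal_amplitude = 150,
                           apply_poisson = TRUE) {
  if (any(psf_sigma_um < 0)) stop("psf_sigma_um must be nonnegative")
  if (background_level < 0) stop("background_level must be nonnegative")
  if (poisson_gain <= 0) stop("poisson_gain must be positive")
  if (gaussian_sd < 0) stop("gaussian_sd must be nonnegative")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  structure(list(psf_sigma_um = as.numeric(psf_sigma_um),
                 background_level = background_level,
                 poisson_gain = poisson_gain,
                 gaussian_sd = gaussian_sd,
                 bit_depth = as.integer(bit_depth),
                 signal_amplitude = signal_amplitude,
                 apply_poisson = isTRUE(apply_poisson)),
            class = "imaging_params")
}

#' Noiseless imaging parameters (no blur, no background, no noise)
#' @param ... overrides passed to [imaging_params()].
#' @return an `imaging_params` object.
#' @export
imaging_noiseless <- function(...) {
  imaging_params(psf_sigma_um = c(0, 0, 0), background_level = 0,
                 gaussian_sd = 0, apply_poisson = FALSE, ...)
}

CHANNEL_ROLES <- c("nuclei", "gland_marker", "epithelium", "lif", "vasculature")

#' Render a scene into a noisy multi-channel volume
#'
#' Rasterizes the requested channel roles (tubes and ellipsoids at their
#' stated radii), then applies PSF blur, Poisson shot noise and Gaussian read
#' noise in that order, clamping to the bit depth. The scene (ground truth) is
#' not modified. The noiseless signal depends only on the scene; noise depends
#' only on `seed`.
#'
#' @param scene a `gland_scene`.
#' @param imaging an [imaging_params()].
#' @param channels subset of
#'   `c("nuclei", "gland_marker", "epithelium", "lif", "vasculature")`.
#' @param seed noise seed; defaults to `scene$spec$seed + 1000`.
#' @return a [volume_image()] with one channel per requested role.
#' @export
render_volume <- function(scene, imaging = imaging_params(),
                          channels = c("gland_marker"),
                          seed = NULL) {
  stopifnot(inherits(scene, "gland_scene"), inherits(imaging, "imaging_params"))
  bad <- setdiff(channels, CHANNEL_ROLES)
  if (length(bad))
    stop(errorCondition(paste0("unknown channel role(s): ", paste(bad, collapse = ", ")),
                        class = c("glandmorph_config_error", "error", "condition")))
  if (is.null(seed)) seed <- scene$spec$seed + 1000L
  dims <- scene$volume_shape
  m <- scene_masks(scene)
  A <- imaging$signal_amplitude
  planes <- lapply(channels, function(ch) {
    sig <- array(0, dims)
    if (ch == "gland_marker") sig[m$gland_labels > 0] <- A
    if (ch == "epithelium") { sig[m$gland_labels > 0] <- A; sig[m$lumen] <- A }
    if (ch == "nuclei") {
      sig[m$embryo] <- 0.75 * A
      sig[m$icm] <- 1.5 * A
      sig[m$cell_labels > 0] <- A
    }
    if (ch == "lif" && !is.null(scene$lif_voxels)) sig[scene$lif_voxels] <- A
    sig
  })
  maxval <- 2^imaging$bit_depth - 1
  with_seed(seed, {
    planes <- lapply(planes, function(sig) {
      if (any(imaging$psf_sigma_um > 0)) {
        sv <- imaging$psf_sigma_um / scene$voxel_size_um
        sig <- array(cpp_gaussian_blur(sig, dims, sv), dims)
      }
      sig <- sig + imaging$background_level
      if (imaging$apply_poisson)
        sig <- array(rpois(length(sig), imaging$poisson_gain * sig) / imaging$poisson_gain, dims)
      if (imaging$gaussian_sd > 0)
        sig <- sig + array(rnorm(length(sig), 0, imaging$gaussian_sd), dims)
      array(pmin(pmax(round(sig), 0), maxval), dims)
    })
  })
  data <- array(0, c(dims, length(channels)))
  for (i in seq_along(planes)) data[, , , i] <- planes[[i]]
  if (length(channels) == 1L) data <- array(data, dims)
  volume_image(data, scene$voxel_size_um, channels)
}

#' Export a scene's ground truth as per-gland and edge-list tables
#'
#' @param scene a `gland_scene`.
#' @return list of two data.frames: `glands` (one row per gland: attachment,
#'   true branch points, true length, category) and `edges` (per-tree edge
#'   list with node coordinates in um).
#' @export
scene_truth_tables <- function(scene) {
  glands <- do.call(rbind, lapply(scene$glands, function(g) data.frame(
    gland_id = g$id,
    attach_z_um = g$attachment_um[1], attach_y_um = g$attachment_um[2],
    attach_x_um = g$attachment_um[3],
    true_branch_points = g$true_branch_points,
    true_length_um = g$true_length_um,
    category = g$category,
    radius_um = g$radius_um)))
  edges <- do.call(rbind, lapply(scene$glands, function(g) data.frame(
    gland_id = g$id,
    from = g$edges[, 1], to = g$edges[, 2],
    z0 = g$nodes[g$edges[, 1], 1], y0 = g$nodes[g$edges[, 1], 2],
    x0 = g$nodes[g$edges[, 1], 3],
    z1 = g$nodes[g$edges[, 2], 1], y1 = g$nodes[g$edges[, 2], 2],
    x1 = g$nodes[g$edges[, 2], 3])))
  list(glands = glands, edges = edges)
}
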