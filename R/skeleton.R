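#' Skeletonize a binary gland mask by 3D thinning
#'
#' Topology-preserving medial-axis thinning: six face-direction subpasses per
#' iteration delete, in raster order, border voxels that are simple points and
#' not curve endpoints, until no voxel can be removed. The skeleton is a
#' subset of the mask with the same number of connected components.
#'
#' @param mask logical 3D array; binary, hole-filled, single 26-connected
#'   component.
#' @return logical 3D array containing the skeleton.
#' @export
skeletonize_3d <- function(mask) {
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
    mask <- array(as.logical(mask), dim(mask))
  }
  if (!any(mask)) stop("mask is empty")
  ncomp <- max(label_components_3d(mask, 26L))
  if (ncomp > 1)
    stop("mask has ", ncomp, " connected components; run separate_glands() ",
         "and skeletonize each gland on its own")
  array(cpp_thin(mask, dim(mask)), dim(mask))
}

# ---- brute-force reference thinning (pure R) ---------------------------------------

# 3x3x3 neighborhood of linear index i; out-of-bounds = FALSE
local_neighborhood <- function(m, dims, i) {
  co <- arrayInd(i, dims)
  nb <- array(FALSE, c(3, 3, 3))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    z <- co[1] + dz; y <- co[2] + dy; x <- co[3] + dx
    if (z >= 1 && z <= dims[1] && y >= 1 && y <= dims[2] && x >= 1 && x <= dims[3])
      nb[dz + 2, dy + 2, dx + 2] <- m[z, y, x]
  }
  nb
}

# simple-point test on a 3x3x3 occupancy array (center (2,2,2))
is_simple_nb <- function(nb) {
  # condition 1: exactly one 26-component of foreground among the 26 neighbors
  fg <- nb; fg[2, 2, 2] <- FALSE
  comp1 <- 0
  seen <- array(FALSE, c(3, 3, 3))
  for (s in which(fg)) {
    if (seen[s]) next
    comp1 <- comp1 + 1
    if (comp1 > 1) return(FALSE)
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      c0 <- stack[length(stack)]; stack <- stack[-length(stack)]
      cc <- arrayInd(c0, c(3, 3, 3))
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        z <- cc[1] + dz; y <- cc[2] + dy; x <- cc[3] + dx
        if (z < 1 || z > 3 || y < 1 || y > 3 || x < 1 || x > 3) next
        if (z == 2 && y == 2 && x == 2) next
        if (fg[z, y, x] && !seen[z, y, x]) {
          seen[z, y, x] <- TRUE
          stack <- c(stack, (x - 1) * 9 + (y - 1) * 3 + z)
        }
      }
    }
  }
  if (comp1 != 1) return(FALSE)
  # condition 2: one 6-component of background within N18, 6-adjacent to center
  manh <- array(0L, c(3, 3, 3))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    manh[dz + 2, dy + 2, dx + 2] <- abs(dz) + abs(dy) + abs(dx)
  bg18 <- !nb & manh >= 1 & manh <= 2
  seenb <- array(FALSE, c(3, 3, 3))
  comp2 <- 0
  six <- which(manh == 1)
  for (s in six) {
    if (!bg18[s] || seenb[s]) next
    comp2 <- comp2 + 1
    if (comp2 > 1) return(FALSE)
    stack <- s
    seenb[s] <- TRUE
    while (length(stack)) {
      c0 <- stack[length(stack)]; stack <- stack[-length(stack)]
      cc <- arrayInd(c0, c(3, 3, 3))
      for (k in 1:6) {
        d <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))[[k]]
        z <- cc[1] + d[1]; y <- cc[2] + d[2]; x <- cc[3] + d[3]
        if (z < 1 || z > 3 || y < 1 || y > 3 || x < 1 || x > 3) next
        if (bg18[z, y, x] && !seenb[z, y, x]) {
          seenb[z, y, x] <- TRUE
          stack <- c(stack, (x - 1) * 9 + (y - 1) * 3 + z)
        }
      }
    }
  }
  comp2 == 1
}

#' Brute-force reference thinning (pure R)
#'
#' A deliberately naive, slow re-implementation of the thinning rule used by
#' [skeletonize_3d()], written with explicit neighborhood extraction and
#' breadth-first component labeling. Used to validate the optimized
#' implementation on small masks; not intended for production volumes.
#'
#' @param mask logical 3D array.
#' @return logical 3D array containing the skeleton.
#' @export
thin_reference <- function(mask) {
  dims <- dim(mask)
  m <- array(as.logical(mask), dims)
  dirs <- matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
                 ncol = 3, byrow = TRUE)
  repeat {
    changed <- FALSE
    for (d in 1:6) {
      idx <- which(m)
      if (!length(idx)) break
      co <- arrayInd(idx, dims)
      nz <- co[, 1] + dirs[d, 1]; ny <- co[, 2] + dirs[d, 2]; nx <- co[, 3] + dirs[d, 3]
      inb <- nz >= 1 & nz <= dims[1] & ny >= 1 & ny <= dims[2] & nx >= 1 & nx <= dims[3]
      facebg <- !inb
      facebg[inb] <- !m[cbind(nz[inb], ny[inb], nx[inb])]
      for (i in idx[facebg]) {
        if (!m[i]) next
        nb <- local_neighborhood(m, dims, i)
        nb_count <- sum(nb) - 1
        if (nb_count < 2) next
        if (is_simple_nb(nb)) { m[i] <- FALSE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  m
}

# ---- skeleton graph ----------------------------------------------------------------

#' Build a spatial graph from a skeleton voxel set
#'
#' Junction voxels (>= 3 skeleton neighbors under 26-connectivity) that touch
#' each other are merged into single junction nodes; voxels with one neighbor
#' become endpoint nodes. Edges follow the voxel chains between nodes and
#' carry anisotropy-weighted polyline lengths in micrometres.
#'
#' @param skeleton logical 3D array from [skeletonize_3d()].
#' @param voxel_size_um numeric(3) spacing in um.
#' @param origin_um physical offset added to all coordinates (used when the
#'   skeleton was computed on a cropped subvolume).
#' @return an object of class `skeleton_graph`: `nodes` (data.frame: `node`,
#'   `z_um`, `y_um`, `x_um`, `type`), `edges` (data.frame: `from`, `to`,
#'   `length_um`), `paths` (list of polyline matrices, um).
#' @export
skeleton_to_graph <- function(skeleton, voxel_size_um, origin_um = c(0, 0, 0)) {
  voxel_size_um <- check_voxel_size(voxel_size_um)
  dims <- dim(skeleton)
  idx <- which(skeleton)
  if (!length(idx)) stop("empty skeleton")
  n <- length(idx)
  vox_id <- array(0L, dims)
  vox_id[idx] <- seq_len(n)
  coord <- arrayInd(idx, dims)
  um <- sweep(coord - 1, 2, voxel_size_um, "*")
  um <- sweep(um, 2, origin_um, "+")
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  pf <- integer(0); pt <- integer(0)
  for (k in seq_len(nrow(offs))) {
    cz <- coord[, 1] + offs[k, 1]; cy <- coord[, 2] + offs[k, 2]; cx <- coord[, 3] + offs[k, 3]
    ok <- cz >= 1 & cz <= dims[1] & cy >= 1 & cy <= dims[2] & cx >= 1 & cx <= dims[3]
    nb <- integer(n)
    nb[ok] <- vox_id[cbind(cz[ok], cy[ok], cx[ok])]
    sel <- which(nb > 0)
    pf <- c(pf, sel); pt <- c(pt, nb[sel])
  }
  deg <- tabulate(pf, n)
  adj <- split(pt, factor(pf, levels = seq_len(n)))
  node_of <- integer(n)
  node_type <- character(0)
  next_node <- 0L
  # junction clusters
  jv <- which(deg >= 3)
  if (length(jv)) {
    in_j <- logical(n); in_j[jv] <- TRUE
    sel <- in_j[pf] & in_j[pt]
    gj <- igraph::graph_from_data_frame(
      data.frame(from = as.character(pf[sel]), to = as.character(pt[sel])),
      directed = FALSE, vertices = data.frame(name = as.character(jv)))
    cmp <- igraph::components(gj)$membership
    for (v in jv) node_of[v] <- cmp[[as.character(v)]]
    next_node <- max(cmp)
    node_type <- rep("junction", next_node)
  }
  for (v in which(deg <= 1)) {
    next_node <- next_node + 1L
    node_of[v] <- next_node
    node_type <- c(node_type, if (deg[v] == 0) "isolated" else "endpoint")
  }
  is_nodevox <- node_of > 0
  path_len <- function(ids) {
    if (length(ids) < 2) return(0)
    sum(sqrt(rowSums((um[ids[-1], , drop = FALSE] - um[ids[-length(ids)], , drop = FALSE])^2)))
  }
  ef <- integer(0); et <- integer(0); el <- numeric(0)
  paths <- list()
  visited <- logical(n)
  direct_seen <- character(0)
  for (v in which(is_nodevox)) {
    for (u in adj[[v]]) {
      if (is_nodevox[u]) {
        if (node_of[u] == node_of[v]) next
        key <- paste(min(v, u), max(v, u))
        if (key %in% direct_seen) next
        direct_seen <- c(direct_seen, key)
        ef <- c(ef, node_of[v]); et <- c(et, node_of[u])
        el <- c(el, path_len(c(v, u)))
        paths[[length(paths) + 1L]] <- um[c(v, u), , drop = FALSE]
      } else {
        if (visited[u]) next
        pth <- c(v, u); prev <- v; cur <- u
        repeat {
          visited[cur] <- TRUE
          nbs <- adj[[cur]]
          nxt <- nbs[nbs != prev][1]
          pth <- c(pth, nxt)
          if (is_nodevox[nxt]) break
          prev <- cur; cur <- nxt
        }
        ef <- c(ef, node_of[v]); et <- c(et, node_of[pth[length(pth)]])
        el <- c(el, path_len(pth))
        paths[[length(paths) + 1L]] <- um[pth, , drop = FALSE]
      }
    }
  }
  # pure cycles with no node voxel: anchor a loop node and close the cycle
  leftover <- which(!visited & !is_nodevox & deg == 2)
  while (length(leftover)) {
    s <- leftover[1]
    next_node <- next_node + 1L
    node_of[s] <- next_node
    node_type <- c(node_type, "loop")
    pth <- s
    prev <- s; cur <- adj[[s]][1]
    while (cur != s) {
      visited[cur] <- TRUE
      pth <- c(pth, cur)
      nbs <- adj[[cur]]
      nxt <- nbs[nbs != prev][1]
      prev <- cur; cur <- nxt
    }
    pth <- c(pth, s)
    visited[s] <- TRUE
    ef <- c(ef, next_node); et <- c(et, next_node)
    el <- c(el, path_len(pth))
    paths[[length(paths) + 1L]] <- um[pth, , drop = FALSE]
    leftover <- which(!visited & node_of == 0 & deg == 2)
  }
  node_ids <- seq_len(next_node)
  pos <- t(vapply(node_ids, function(nd) {
    colMeans(um[node_of == nd, , drop = FALSE])
  }, numeric(3)))
  nodes <- data.frame(node = node_ids, z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
                      type = node_type, stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 edges = data.frame(from = ef, to = et, length_um = el),
                 paths = paths,
                 voxel_size_um = voxel_size_um),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("skeleton_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      count_branch_points(x), "branch point(s)\n")
  invisible(x)
}

#' Node degrees of a skeleton graph (self-loops count twice)
#' @param graph a `skeleton_graph`.
#' @return integer vector indexed by node id.
#' @export
graph_degree <- function(graph) {
  tabulate(c(graph$edges$from, graph$edges$to), nbins = nrow(graph$nodes))
}

#' Count branch points (nodes of degree >= 3)
#' @param graph a (pruned) `skeleton_graph`.
#' @return nonnegative integer.
#' @export
count_branch_points <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  sum(graph_degree(graph) >= 3)
}

# drop nodes, renumber edges/paths consistently
renumber_graph <- function(graph, keep) {
  map <- integer(nrow(graph$nodes))
  map[keep] <- seq_along(keep)
  graph$nodes <- graph$nodes[keep, , drop = FALSE]
  graph$nodes$node <- seq_along(keep)
  graph$edges$from <- map[graph$edges$from]
  graph$edges$to <- map[graph$edges$to]
  graph
}

#' Prune short terminal spurs from a skeleton graph
#'
#' Iteratively removes terminal edges (one end a leaf, the other a junction)
#' shorter than `min_spur_length_um`, dissolving junctions that drop to
#' degree 2 by merging their two incident edges. Idempotent at the fixpoint;
#' `min_spur_length_um = 0` is the identity. Thinning of thick tubes produces
#' short side twigs at surface bumps and junction clumps; this removes them
#' the way interactive filament curation would.
#'
#' @param graph a `skeleton_graph`.
#' @param min_spur_length_um spur threshold in um (>= 0).
#' @param merge_junction_dist_um junction pairs connected by a path shorter
#'   than this are merged into one branch point (thinning splits junction
#'   clumps by a voxel or two on coarse grids); default 20 um, a few voxel
#'   diagonals at 7 um z-spacing.
#' @return a pruned `skeleton_graph`.
#' @export
prune_spurs <- function(graph, min_spur_length_um,
                        merge_junction_dist_um = 20) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (min_spur_length_um < 0) stop("min_spur_length_um must be >= 0")
  if (min_spur_length_um == 0 || nrow(graph$edges) == 0) return(graph)
  contract_edge <- function(graph, i) {
    a <- graph$edges$from[i]; b <- graph$edges$to[i]
    graph$edges <- graph$edges[-i, , drop = FALSE]
    graph$paths <- graph$paths[-i]
    if (a != b) {
      graph$edges$from[graph$edges$from == b] <- a
      graph$edges$to[graph$edges$to == b] <- a
      graph <- renumber_graph(graph, setdiff(seq_len(nrow(graph$nodes)), b))
    }
    graph
  }
  # tubular trees have no cycles: every skeleton cycle is a thinning artifact
  # (parallel "ladder" paths at coarse anisotropic spacing). Reduce to the
  # minimum spanning forest, which drops the longest edge of every cycle
  # (self-loops and the longer of parallel edges included).
  if (nrow(graph$edges) >= nrow(graph$nodes)) {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = graph$edges$from, to = graph$edges$to,
                 weight = graph$edges$length_um, eid = seq_len(nrow(graph$edges))),
      directed = FALSE, vertices = data.frame(name = seq_len(nrow(graph$nodes))))
    kept <- sort(igraph::edge_attr(igraph::mst(ig), "eid"))
    graph$edges <- graph$edges[kept, , drop = FALSE]
    graph$paths <- graph$paths[kept]
  }
  repeat {
    deg <- graph_degree(graph)
    e <- graph$edges
    spur <- which((deg[e$from] == 1 & deg[e$to] >= 3) |
                    (deg[e$to] == 1 & deg[e$from] >= 3))
    spur <- spur[e$length_um[spur] < min_spur_length_um]
    if (!length(spur)) {
      # only once no spur remains: merge junction clumps split across a
      # voxel or two (merging earlier would let chains of artifact spur
      # bases telescope genuine arm segments into a single node)
      jj <- which(deg[e$from] >= 3 & deg[e$to] >= 3 & e$from != e$to &
                    e$length_um < merge_junction_dist_um)
      if (!length(jj)) break
      graph <- contract_edge(graph, jj[which.min(e$length_um[jj])])
      next
    }
    drop <- spur[which.min(e$length_um[spur])]
    leaf <- if (deg[e$from[drop]] == 1) e$from[drop] else e$to[drop]
    graph$edges <- graph$edges[-drop, , drop = FALSE]
    graph$paths <- graph$paths[-drop]
    # dissolve any junction left at degree 2
    repeat {
      deg <- graph_degree(graph)
      d2 <- which(deg == 2 & graph$nodes$type == "junction")
      d2 <- d2[vapply(d2, function(nd) {
        inc <- which(graph$edges$from == nd | graph$edges$to == nd)
        length(inc) == 2                        # not a self-loop
      }, logical(1))]
      if (!length(d2)) break
      nd <- d2[1]
      inc <- which(graph$edges$from == nd | graph$edges$to == nd)
      e1 <- graph$edges[inc[1], ]; e2 <- graph$edges[inc[2], ]
      p1 <- graph$paths[[inc[1]]]; p2 <- graph$paths[[inc[2]]]
      a <- if (e1$from == nd) e1$to else e1$from
      b <- if (e2$from == nd) e2$to else e2$from
      # orient paths a -> nd -> b
      if (e1$from == nd) p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE]
      if (e2$to == nd) p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
      newp <- rbind(p1, p2[-1, , drop = FALSE])
      graph$edges <- graph$edges[-inc, , drop = FALSE]
      graph$paths <- graph$paths[-inc]
      graph$edges <- rbind(graph$edges,
                           data.frame(from = a, to = b,
                                      length_um = e1$length_um + e2$length_um))
      graph$paths[[length(graph$paths) + 1L]] <- newp
    }
    # drop now-disconnected nodes (the removed leaf, dissolved junctions)
    deg <- graph_degree(graph)
    keep <- which(deg > 0)
    if (!length(keep)) keep <- leaf                  # degenerate: keep one node
    graph <- renumber_graph(graph, keep)
  }
  graph
}

#' Gland length: attachment point to furthest skeleton tip (straight line)
#'
#' The chord distance from the lumen-attachment point to the furthest
#' skeleton endpoint, not the geodesic path length.
#'
#' @param gland a `gland_object` (or a numeric(3) attachment point in um).
#' @param graph a pruned `skeleton_graph` of that gland.
#' @return length in um; 0 with a warning when the graph has no endpoints.
#' @export
gland_length <- function(gland, graph) {
  att <- if (inherits(gland, "gland_object")) gland$attachment_point_um else as.numeric(gland)
  stopifnot(inherits(graph, "skeleton_graph"), length(att) == 3)
  deg <- graph_degree(graph)
  tips <- graph$nodes[deg == 1, , drop = FALSE]
  if (nrow(tips) == 0) {
    warning("skeleton graph has no endpoints; returning length 0")
    return(0)
  }
  max(sqrt((tips$z_um - att[1])^2 + (tips$y_um - att[2])^2 + (tips$x_um - att[3])^2))
}

#' Per-gland morphometry: skeletonize, prune, count branches, measure length
#'
#' Runs the full skeleton pipeline on each gland object: crop, thin, build the
#' spatial graph, prune spurs, count branch points, and measure the chord
#' length from the attachment point to the furthest tip (plus the geodesic
#' path length as a secondary column).
#'
#' @param glands list of `gland_object`s from [separate_glands()].
#' @param min_spur_length_um spur-pruning threshold; the default (36 um) is
#'   sized to exceed the crotch/staircase twigs that thinning produces
#'   (observed up to ~32 um at these tube radii) while staying below genuine
#'   terminal branch segments (>= ~55 um under the generator's margins).
#' @param merge_junction_dist_um junction-merge radius passed to
#'   [prune_spurs()]; 24 um sits between the junction-split artifact scale
#'   (up to about four tube radii in thick crotches) and the closest
#'   genuine junction pairs (>= ~35 um under the generator margins).
#' @param resample_z replicate z-slices to near-isotropic spacing before
#'   thinning (default TRUE). At 7 um optical sections a tube is only two
#'   voxels thick, and thinning such ribbons fragments junctions; slice
#'   replication removes those grid artifacts at modest cost.
#' @param sample_id identifier copied into every record.
#' @return data.frame of morphometry records: `sample_id`, `gland_label`,
#'   `length_um`, `length_path_um`, `n_branch_points`, `branch_category`,
#'   `volume_um3`, `n_voxels`, `touches_border`.
#' @export
gland_morphometry <- function(glands, min_spur_length_um = 36,
                              merge_junction_dist_um = 24,
                              resample_z = TRUE, sample_id = NA_character_) {
  if (!length(glands)) stop("no gland objects supplied")
  rows <- lapply(glands, function(g) {
    dims <- g$dims
    co <- arrayInd(g$voxels, dims)
    lo <- pmax(apply(co, 2, min) - 1L, 1L)
    hi <- pmin(apply(co, 2, max) + 1L, dims)
    sub <- array(FALSE, hi - lo + 1L)
    sub[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L, co[, 3] - lo[3] + 1L)] <- TRUE
    vs <- g$voxel_size_um
    if (resample_z) {
      f <- max(1L, round(vs[1] / vs[2]))
      if (f > 1L) {
        sub <- sub[rep(seq_len(dim(sub)[1]), each = f), , , drop = FALSE]
        vs <- c(vs[1] / f, vs[2], vs[3])
      }
    }
    skel <- skeletonize_3d(sub)
    gr <- skeleton_to_graph(skel, vs,
                            origin_um = (lo - 1) * g$voxel_size_um)
    gr <- prune_spurs(gr, min_spur_length_um, merge_junction_dist_um)
    nbp <- count_branch_points(gr)
    len <- suppressWarnings(gland_length(g, gr))
    # geodesic (path) length from the node nearest the attachment to the farthest tip
    lp <- NA_real_
    if (nrow(gr$edges) > 0) {
      dd <- sqrt((gr$nodes$z_um - g$attachment_point_um[1])^2 +
                   (gr$nodes$y_um - g$attachment_point_um[2])^2 +
                   (gr$nodes$x_um - g$attachment_point_um[3])^2)
      root <- which.min(dd)
      ig <- igraph::graph_from_data_frame(
        data.frame(from = gr$edges$from, to = gr$edges$to, weight = gr$edges$length_um),
        directed = FALSE, vertices = data.frame(name = gr$nodes$node))
      dmat <- igraph::distances(ig, v = as.character(root))
      lp <- max(dmat[is.finite(dmat)])
    }
    data.frame(sample_id = sample_id, gland_label = g$label,
               length_um = len, length_path_um = lp,
               n_branch_points = nbp,
               branch_category = as.character(branch_category(nbp)),
               volume_um3 = g$volume_um3, n_voxels = g$n_voxels,
               touches_border = g$touches_border,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-group branch-category percentages
#'
#' Tabulates the percentage of glands with 0, 1-3 and >3 branch points per
#' group; counts are retained for downstream two-proportion Z-tests.
#'
#' @param records morphometry data.frame with a `n_branch_points` column.
#' @param group vector of group labels (length `nrow(records)`), or the name
#'   of a column of `records`.
#' @return data.frame with one row per group x category: `group`, `category`,
#'   `n`, `n_group`, `percent`; percentages sum to 100 within each group.
#' @export
branch_category_table <- function(records, group) {
  if (length(group) == 1 && is.character(group) && group %in% names(records))
    group <- records[[group]]
  if (length(group) != nrow(records))
    stop("group must match the number of records")
  if (nrow(records) == 0) stop("no records")
  g <- as.character(group)
  if (any(is.na(g))) stop("missing group labels")
  cat_ <- branch_category(records$n_branch_points)
  tab <- table(group = g, category = cat_)
  if (any(rowSums(tab) == 0)) stop("empty group in branch_category_table")
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n"
  ng <- rowSums(tab)
  out$n_group <- as.integer(ng[out$group])
  out$percent <- 100 * out$n / out$n_group
  out[order(out$group, match(out$category, BRANCH_CATEGORIES)), , drop = FALSE]
}
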