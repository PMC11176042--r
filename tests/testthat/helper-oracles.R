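# Independent oracles used across test files.

# Exact two-sided Mann-Whitney p by full enumeration over all group
# assignments of the pooled tie-free sample (the R convention: double the
# smaller tail of the exact U distribution, capped at 1).
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Kruskal-Wallis H from the textbook rank-sum formula (no ties)
kw_hand_h <- function(groups) {
  x <- unlist(groups)
  stopifnot(!anyDuplicated(x))
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  rs <- tapply(r, idx, sum)
  ns <- vapply(groups, length, integer(1))
  12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
}

# folded-angle oracle: arccos of the normalized dot product after the same
# in-plane projection used by compute_axis_angle
axis_angle_oracle <- function(v, m) {
  m <- m / sqrt(sum(m^2))
  w <- c(0, v[2], v[3])
  wp <- w - sum(w * m) * m
  if (sqrt(sum(wp^2)) < 1e-12) return(if (abs(sum(v * m)) > 0) 0 else 90)
  what <- wp / sqrt(sum(wp^2))
  vp <- c(sum(v * m), sum(v * what))
  acos(abs(vp[1]) / sqrt(sum(vp^2))) * 180 / pi
}

# brute-force Otsu: sweep all midpoints between sorted unique values and
# minimize within-class variance
otsu_bruteforce <- function(values) {
  u <- sort(unique(values))
  cuts <- (u[-1] + u[-length(u)]) / 2
  wcv <- vapply(cuts, function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    (length(lo) * stats::var(lo) * (length(lo) - 1) / length(lo)) +
      (length(hi) * stats::var(hi) * (length(hi) - 1) / length(hi))
  }, numeric(1))
  wcv[is.na(wcv)] <- Inf
  cuts[which.min(wcv)]
}

# collapse all degree-2 vertices of a tree edge list (topology skeleton:
# junctions and tips only)
contract_deg2 <- function(edges) {
  edges <- as.matrix(edges)
  repeat {
    deg <- tabulate(c(edges), max(edges))
    v <- which(deg == 2)[1]
    if (is.na(v)) break
    inc <- which(edges[, 1] == v | edges[, 2] == v)
    if (length(inc) != 2) break              # self-loop guard
    ends <- setdiff(c(edges[inc, ]), v)
    if (length(ends) == 1) ends <- c(ends, ends)
    edges <- rbind(edges[-inc, , drop = FALSE], ends)
  }
  edges
}

# small solid tube mask builder (via the package rasterizer is avoided here;
# direct voxel-center distance to a segment keeps the oracle independent)
tube_mask <- function(dims, spacing, p0, p1, radius) {
  m <- array(FALSE, dims)
  for (x in seq_len(dims[3])) for (y in seq_len(dims[2])) for (z in seq_len(dims[1])) {
    p <- c((z - 1) * spacing[1], (y - 1) * spacing[2], (x - 1) * spacing[3])
    d <- p1 - p0
    t <- if (sum(d^2) == 0) 0 else max(0, min(1, sum((p - p0) * d) / sum(d^2)))
    q <- p0 + t * d
    if (sum((q - p)^2) <= radius^2) m[z, y, x] <- TRUE
  }
  m
}
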