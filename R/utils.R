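#' @useDynLib glandmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif pnorm setNames median quantile
#' @importFrom utils write.csv read.csv head packageVersion
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so simulation functions do not disturb the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

# Voxel offsets (dz, dy, dx) of an ellipsoidal structuring element that is a
# sphere of `diameter_um` in physical space, on an anisotropic grid.
ball_offsets <- function(diameter_um, voxel_size_um) {
  r <- diameter_um / 2
  if (r < min(voxel_size_um) / 2)
    stop("structuring-element diameter (", diameter_um,
         " um) is smaller than one voxel; increase the diameter")
  rv <- pmax(0L, as.integer(floor(r / voxel_size_um)))
  grid <- expand.grid(dz = -rv[1]:rv[1], dy = -rv[2]:rv[2], dx = -rv[3]:rv[3])
  d2 <- (grid$dz * voxel_size_um[1])^2 + (grid$dy * voxel_size_um[2])^2 +
    (grid$dx * voxel_size_um[3])^2
  m <- as.matrix(grid[d2 <= r^2, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

check_voxel_size <- function(voxel_size_um) {
  if (length(voxel_size_um) != 3 || any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0))
    stop("voxel_size_um must be three strictly positive finite numbers (z, y, x)")
  as.numeric(voxel_size_um)
}

# stable content hash without extra dependencies: md5 of a serialized temp file
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
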