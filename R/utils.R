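# Internal helpers shared across modules.
#
# Conventions (used everywhere):
#   * arrays are indexed [x, y, z]; voxel centers sit at (index - 0.5) * spacing
#     with the world origin at the volume corner, right-handed axes;
#   * lengths in mm, velocities in cm/s, time in ms, flux in mL/s.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

vec_norm <- function(x) sqrt(sum(x^2))

normalize <- function(x) {
  n <- vec_norm(x)
  if (n == 0) stopf("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthonormal in-plane basis (e1, e2) for a unit normal; deterministic.
plane_basis <- function(normal) {
  normal <- normalize(normal)
  up <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- normalize(cross3(up, normal))
  e2 <- cross3(normal, e1)
  list(e1 = e1, e2 = e2, normal = normal)
}

# Round half away from zero (matches integer presentation of flow tables).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Wrap phase into (-pi, pi].
wrap_phase <- function(phi) {
  w <- ((phi + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

# --- trilinear sampling -----------------------------------------------------

# Sample a 3D volume at world points (mm). `pts` is an n x 3 matrix.
# Points outside the physical volume [0, dim*spacing] give NA; points between
# the boundary and the first voxel-center plane are edge-extended.
trilinear <- function(vol, pts, spacing) {
  dm <- dim(vol)
  n <- nrow(pts)
  out <- rep(NA_real_, n)
  inside <- pts[, 1] >= 0 & pts[, 1] <= dm[1] * spacing[1] &
    pts[, 2] >= 0 & pts[, 2] <= dm[2] * spacing[2] &
    pts[, 3] >= 0 & pts[, 3] <= dm[3] * spacing[3]
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  gx <- pmin(pmax(p[, 1] / spacing[1] + 0.5, 1), dm[1])
  gy <- pmin(pmax(p[, 2] / spacing[2] + 0.5, 1), dm[2])
  gz <- pmin(pmax(p[, 3] / spacing[3] + 0.5, 1), dm[3])
  i0 <- pmin(floor(gx), dm[1] - 1); wx <- gx - i0
  j0 <- pmin(floor(gy), dm[2] - 1); wy <- gy - j0
  k0 <- pmin(floor(gz), dm[3] - 1); wz <- gz - k0
  if (dm[1] == 1) { i0 <- rep(1, length(gx)); wx <- rep(0, length(gx)) }
  if (dm[2] == 1) { j0 <- rep(1, length(gy)); wy <- rep(0, length(gy)) }
  if (dm[3] == 1) { k0 <- rep(1, length(gz)); wz <- rep(0, length(gz)) }
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  base <- (i0 - 1) + (j0 - 1) * nx + (k0 - 1) * nxy + 1
  v000 <- vol[base]
  v100 <- vol[base + 1]
  v010 <- vol[base + nx]
  v110 <- vol[base + nx + 1]
  v001 <- vol[base + nxy]
  v101 <- vol[base + nxy + 1]
  v011 <- vol[base + nxy + nx]
  v111 <- vol[base + nxy + nx + 1]
  val <- (1 - wz) * ((1 - wy) * ((1 - wx) * v000 + wx * v100) +
                       wy * ((1 - wx) * v010 + wx * v110)) +
    wz * ((1 - wy) * ((1 - wx) * v001 + wx * v101) +
            wy * ((1 - wx) * v011 + wx * v111))
  out[inside] <- val
  out
}

# --- array neighbourhood machinery ------------------------------------------

# Shift a logical/numeric 3D array by one voxel along axis (+1/-1), padding
# with `fill`. Used by the wavefront (BFS) operations.
shift3 <- function(a, axis, dir, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  idx_src <- lapply(dm, seq_len)
  idx_dst <- idx_src
  n <- dm[axis]
  if (n == 1) return(out)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:n
    idx_src[[axis]] <- 1:(n - 1)
  } else {
    idx_dst[[axis]] <- 1:(n - 1)
    idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# 6-neighbour linear-index offsets for an array of dim `dm`.
neighbour_offsets <- function(dm) {
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  c(-1, 1, -nx, nx, -nxy, nxy)
}

# Flood fill a logical mask from seed linear indices (6-connectivity),
# fully vectorised wavefront growth. Returns a logical array.
flood_fill <- function(mask, seeds) {
  dm <- dim(mask)
  reach <- array(FALSE, dm)
  seeds <- seeds[mask[seeds]]
  if (length(seeds) == 0) return(reach)
  reach[seeds] <- TRUE
  repeat {
    grown <- reach
    for (ax in 1:3) for (dr in c(-1, 1)) grown <- grown | shift3(reach, ax, dr)
    grown <- grown & mask
    if (!any(grown & !reach)) break
    reach <- grown
  }
  reach
}

# Mean over the 4th dimension of a 4D array without apply() copies.
mean4 <- function(a) {
  dm <- dim(a)
  m <- array(0, dm[1:3])
  for (f in seq_len(dm[4])) m <- m + a[, , , f]
  m / dm[4]
}

check_geometry_match <- function(a, b, what = "inputs") {
  if (!isTRUE(all.equal(dim(a$v)[1:3], dim(b$v)[1:3])) ||
      !isTRUE(all.equal(a$spacing, b$spacing)) ||
      dim(a$v)[5] != dim(b$v)[5])
    stopf("geometry mismatch between %s", what)
  invisible(TRUE)
}
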