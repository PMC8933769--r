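#' Define a 3-D sampling grid
#'
#' A grid couples integer voxel dimensions with a 4x4 affine mapping 0-based
#' voxel indices to world coordinates in mm (RAS+ convention). All volumes,
#' masks and deformation fields in the package live on such a grid.
#'
#' @param dims Integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm Positive numeric vector of length 3 (ignored when
#'   `affine` is supplied; then derived from it).
#' @param affine Optional 4x4 voxel-index-to-world matrix. Default places the
#'   grid symmetrically around the world origin with the given voxel size.
#' @return An object of class `aq_grid` with fields `dims`, `voxel_size_mm`,
#'   `affine`.
#' @examples
#' g <- grid3d(c(91, 109, 91), 2)
#' voxel_volume_cc(g) # 0.008 cc per voxel
#' @export
grid3d <- function(dims, voxel_size_mm = 2, affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  if (is.null(affine)) {
    vs <- rep_len(as.numeric(voxel_size_mm), 3)
    stopifnot(all(vs > 0))
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(vs)
    # centre the field of view on the world origin (voxel centres)
    affine[1:3, 4] <- -vs * (dims - 1) / 2
  } else {
    affine <- as.matrix(affine)
    stopifnot(all(dim(affine) == c(4, 4)))
    if (abs(det(affine)) < 1e-12) stop("grid affine is not invertible")
    vs <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(vs <= 0)) stop("grid affine has a zero-length axis")
  }
  structure(list(dims = dims, voxel_size_mm = vs, affine = affine),
            class = "aq_grid")
}

#' Default 2 mm MNI-style analysis grid
#'
#' 91 x 109 x 91 voxels at 2 mm isotropic spacing, matching the common 2 mm
#' MNI152 grid, with the anterior-commissure origin at voxel (45, 63, 36)
#' (0-based). One voxel is 8 mm^3, so 300 voxels correspond to 2.4 cc.
#' @return An `aq_grid`.
#' @export
default_grid <- function() {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(c(2, 2, 2))
  aff[1:3, 4] <- c(-90, -126, -72)
  grid3d(c(91L, 109L, 91L), affine = aff)
}

#' Voxel volume of a grid in cc
#' @param grid An `aq_grid`.
#' @return Volume of one voxel in cubic centimetres.
#' @export
voxel_volume_cc <- function(grid) {
  abs(det(grid$affine[1:3, 1:3])) / 1000
}

#' @export
print.aq_grid <- function(x, ...) {
  cat(sprintf("<aq_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) && all(abs(a$affine - b$affine) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b)) stop(sprintf("grid mismatch between %s", what))
  invisible(TRUE)
}

# 0-based voxel indices (n x 3) -> world mm (n x 3)
voxel_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  h <- cbind(idx, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

# world mm (n x 3) -> 0-based voxel coordinates (n x 3, fractional)
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  h <- cbind(xyz, 1) %*% t(solve(grid$affine))
  h[, 1:3, drop = FALSE]
}

# all voxel centres of a grid in world mm, fastest-varying first axis
grid_world_coords <- function(grid) {
  d <- grid$dims
  i <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  voxel_to_world(grid, cbind(i, j, k))
}
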