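# Core samplers. All public resampling ops funnel into sample_at_world(),
# which evaluates a source volume at arbitrary world-mm points by nearest or
# trilinear interpolation. Points outside the source field of view get
# `outside` (0 for image resampling, NA when the caller needs to drop them,
# e.g. registration cost evaluation).

sample_at_world <- function(v, xyz, interpolation = c("trilinear", "nearest"),
                            outside = 0) {
  interpolation <- match.arg(interpolation)
  u <- world_to_voxel(v$grid, xyz)            # fractional 0-based
  d <- v$grid$dims
  dat <- v$data
  n <- nrow(u)
  if (interpolation == "nearest") {
    ui <- round(u)
    ok <- ui[, 1] >= 0 & ui[, 1] <= d[1] - 1 &
          ui[, 2] >= 0 & ui[, 2] <= d[2] - 1 &
          ui[, 3] >= 0 & ui[, 3] <= d[3] - 1
    out <- rep(outside, n)
    if (any(ok)) {
      lin <- ui[ok, 1] + d[1] * (ui[ok, 2] + d[2] * ui[ok, 3]) + 1
      out[ok] <- dat[lin]
    }
    return(out)
  }
  ok <- u[, 1] >= 0 & u[, 1] <= d[1] - 1 &
        u[, 2] >= 0 & u[, 2] <= d[2] - 1 &
        u[, 3] >= 0 & u[, 3] <= d[3] - 1
  out <- rep(as.numeric(outside), n)
  if (!any(ok)) return(out)
  u <- u[ok, , drop = FALSE]
  i0 <- pmin(floor(u[, 1]), d[1] - 2); fx <- u[, 1] - i0
  j0 <- pmin(floor(u[, 2]), d[2] - 2); fy <- u[, 2] - j0
  k0 <- pmin(floor(u[, 3]), d[3] - 2); fz <- u[, 3] - k0
  base <- i0 + d[1] * (j0 + d[2] * k0) + 1
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  v000 <- dat[base]
  v100 <- dat[base + sx]
  v010 <- dat[base + sy]
  v110 <- dat[base + sx + sy]
  v001 <- dat[base + sz]
  v101 <- dat[base + sx + sz]
  v011 <- dat[base + sy + sz]
  v111 <- dat[base + sx + sy + sz]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Resample a volume onto a target grid
#'
#' Pull-back resampling: every target voxel centre is mapped to world space
#' and the source volume is sampled there. Voxels outside the source field of
#' view are set to 0.
#'
#' @param v Source `aq_vol`.
#' @param target Target [grid3d()].
#' @param interpolation `"trilinear"` (default) or `"nearest"`. Masks must use
#'   nearest to stay binary.
#' @return Volume on `target`.
#' @export
resample_to_grid <- function(v, target,
                             interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  xyz <- grid_world_coords(target)
  vals <- sample_at_world(v, xyz, interpolation, outside = 0)
  as_volume(array(vals, dim = target$dims), target, meta = v$meta)
}
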