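# Linear registration by normalized mutual information.
#
# A LinearTransform maps moving-image world coordinates to fixed-image world
# coordinates; applying it resamples the moving image by pull-back (each
# fixed-space voxel samples the moving image at t^-1 x). Optimization is
# multi-resolution (coarse 4 mm then fine 2 mm by default) cyclic
# coordinate-descent with golden-section line searches per parameter --
# a derivative-free scheme in the Powell family. NMI uses a 64 x 64 joint
# histogram over the 1st-99th intensity percentiles of each image.

#' Create a linear (rigid/affine) transform
#'
#' @param matrix 4x4 world-to-world homogeneous matrix (moving -> fixed mm).
#' @param kind `"rigid"` or `"affine"`. For rigid transforms the 3x3 block
#'   must be orthonormal within 1e-6.
#' @return An `aq_xfm` object.
#' @export
linear_transform <- function(matrix, kind = c("rigid", "affine")) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (abs(det(matrix)) < 1e-12) stop("transform is not invertible")
  if (kind == "rigid") {
    R <- matrix[1:3, 1:3]
    if (max(abs(t(R) %*% R - diag(3))) > 1e-6) {
      stop("rigid transform has a non-orthonormal rotation block")
    }
  }
  structure(list(matrix = matrix, kind = kind), class = "aq_xfm")
}

#' @export
print.aq_xfm <- function(x, ...) {
  cat(sprintf("<aq_xfm> %s\n", x$kind))
  print(round(x$matrix, 5))
  invisible(x)
}

#' Invert a linear transform
#' @param t An `aq_xfm`.
#' @return The inverse transform.
#' @export
invert_transform <- function(t) linear_transform(solve(t$matrix), t$kind)

#' Write / read a transform as a plain-text 4x4 matrix (one row per line)
#' @param t An `aq_xfm`.
#' @param path File path.
#' @return `path` / the transform.
#' @export
write_transform <- function(t, path) {
  utils::write.table(t$matrix, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @param kind Transform kind to attribute to the read matrix.
#' @export
read_transform <- function(path, kind = "affine") {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  linear_transform(m, kind)
}

# parameter vector -> 4x4 matrix; rotations/shears about `centre` (world mm).
# p = (tx,ty,tz, rx,ry,rz[deg]) for rigid, + (sx,sy,sz, hxy,hxz,hyz) affine
params_to_matrix <- function(p, kind, centre) {
  rot1 <- function(th, axis) {
    c_ <- cos(th); s_ <- sin(th); R <- diag(3)
    ax <- setdiff(1:3, axis)
    R[ax[1], ax[1]] <- c_; R[ax[2], ax[2]] <- c_
    R[ax[1], ax[2]] <- -s_; R[ax[2], ax[1]] <- s_
    R
  }
  ang <- p[4:6] * pi / 180
  R <- rot1(ang[3], 3) %*% rot1(ang[2], 2) %*% rot1(ang[1], 1)
  A <- R
  if (kind == "affine") {
    S <- diag(p[7:9])
    H <- diag(3); H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
    A <- R %*% S %*% H
  }
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- p[1:3] + centre - A %*% centre
  M
}

percentile_range <- function(x) {
  q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) q <- range(x)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  q
}

bin_index <- function(x, rng, bins) {
  b <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1
  pmin.int(pmax.int(b, 1L), bins)
}

# normalized mutual information (H(A)+H(B))/H(A,B) from paired samples
nmi_from_samples <- function(bf, bm, bins) {
  joint <- tabulate(bf + bins * (bm - 1L), bins * bins)
  p <- joint / sum(joint)
  pj <- p[p > 0]
  hj <- -sum(pj * log(pj))
  pf <- rowSums(matrix(p, bins)); pf <- pf[pf > 0]
  pm <- colSums(matrix(p, bins)); pm <- pm[pm > 0]
  (-sum(pf * log(pf)) - sum(pm * log(pm))) / hj
}

#' Normalized mutual information between two volumes
#'
#' Evaluated on the fixed grid; the moving volume is resampled there first if
#' its grid differs. Voxels falling outside the moving field of view are
#' excluded.
#' @param fixed,moving `aq_vol` objects.
#' @param bins Histogram bins per axis.
#' @return NMI value (1 = independent, 2 = identical).
#' @export
nmi <- function(fixed, moving, bins = 64) {
  xyz <- grid_world_coords(fixed$grid)
  mv <- sample_at_world(moving, xyz, "trilinear", outside = NA)
  ok <- !is.na(mv)
  bf <- bin_index(as.numeric(fixed$data)[ok], percentile_range(fixed$data), bins)
  bm <- bin_index(mv[ok], percentile_range(moving$data), bins)
  nmi_from_samples(bf, bm, bins)
}

# anti-aliased downsampling of a volume to an isotropic spacing (same FOV)
downsample_iso <- function(v, spacing) {
  if (all(v$grid$voxel_size_mm >= spacing - 1e-9)) return(v)
  sm <- gaussian_smooth(v, pmax(0, spacing - v$grid$voxel_size_mm) * 1.5)
  sm$meta <- v$meta
  nd <- pmax(2L, as.integer(ceiling(v$grid$dims * v$grid$voxel_size_mm / spacing)))
  aff <- v$grid$affine
  scl <- diag(c(spacing / v$grid$voxel_size_mm, 1))
  resample_to_grid(sm, grid3d(nd, affine = aff %*% scl))
}

#' Register a moving volume to a fixed volume
#'
#' Maximizes NMI over rigid (6) or affine (12) parameters by multi-resolution
#' coordinate-descent line searches, with seeded random restarts at the
#' coarsest level. Deterministic for a fixed `opts$seed`.
#'
#' @param moving,fixed Non-constant `aq_vol` objects.
#' @param kind `"rigid"` or `"affine"`.
#' @param opts List of optimizer settings: `seed` (default 0), `levels`
#'   (coarse-to-fine isotropic spacings in mm, default `c(4, 2)`), `sweeps`
#'   (max coordinate sweeps per level, default 8), `bins` (default 64),
#'   `restarts` (default 3), `tol` (convergence change in cost, default 1e-6).
#' @return An `aq_xfm` with attributes `nmi` (achieved value) and `converged`.
#' @export
register_linear <- function(moving, fixed, kind = c("rigid", "affine"),
                            opts = list()) {
  kind <- match.arg(kind)
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0) {
    stop("cannot register a constant image")
  }
  o <- utils::modifyList(list(seed = 0, levels = c(4, 2), sweeps = 8,
                              bins = 64, restarts = 3, tol = 1e-6), opts)
  centre <- drop(voxel_to_world(fixed$grid, matrix((fixed$grid$dims - 1) / 2, 1)))
  npar <- if (kind == "rigid") 6L else 12L
  p <- c(rep(0, 6), if (kind == "affine") c(1, 1, 1, 0, 0, 0))
  steps0 <- c(rep(8, 3), rep(8, 3), if (kind == "affine") c(rep(0.15, 3), rep(0.08, 3)))
  converged <- FALSE

  for (li in seq_along(o$levels)) {
    lev <- o$levels[li]
    fx <- downsample_iso(fixed, lev)
    mv <- downsample_iso(moving, lev)
    xyz <- grid_world_coords(fx$grid)
    # sub-voxel jitter of the sampling points (fixed per level, seeded):
    # without it NMI spikes at grid-aligned poses, where interpolation is
    # exact and the joint histogram artificially sharpens, trapping the
    # optimizer at identity-like parameters
    jst <- local_rng(o$seed + li)
    xyz <- xyz + matrix(stats::runif(length(xyz), -0.5, 0.5), ncol = 3) %*%
      diag(fx$grid$voxel_size_mm)
    restore_rng(jst)
    rng_f <- percentile_range(fx$data)
    rng_m <- percentile_range(mv$data)
    fvals <- sample_at_world(fx, xyz, "trilinear", outside = NA)
    keep <- !is.na(fvals)
    xyz <- xyz[keep, , drop = FALSE]
    bf_all <- bin_index(fvals[keep], rng_f, o$bins)
    cost <- function(pp) {
      M <- params_to_matrix(pp, kind, centre)
      s <- sample_at_world(mv, xyz %*% t(solve(M)[1:3, 1:3]) +
                             matrix(solve(M)[1:3, 4], nrow(xyz), 3, byrow = TRUE),
                           "trilinear", outside = NA)
      ok <- !is.na(s)
      if (sum(ok) < 100) return(1e6)
      -nmi_from_samples(bf_all[ok], bin_index(s[ok], rng_m, o$bins), o$bins)
    }
    scale_fac <- lev / o$levels[length(o$levels)]
    steps <- steps0 * scale_fac / (2^0)
    # seeded restarts at the coarsest level only
    if (li == 1 && o$restarts > 0) {
      starts <- list(p)
      rng_state <- local_rng(o$seed)
      on.exit(restore_rng(rng_state), add = TRUE)
      for (r in seq_len(o$restarts)) {
        jit <- p
        jit[1:6] <- jit[1:6] + stats::runif(6, -4, 4) * scale_fac
        starts[[r + 1]] <- jit
      }
      cs <- vapply(starts, cost, 0)
      p <- starts[[which.min(cs)]]
    }
    best <- cost(p)
    for (sw in seq_len(o$sweeps)) {
      prev <- best
      for (i in seq_len(npar)) {
        f1 <- function(x) { q <- p; q[i] <- x; cost(q) }
        op <- stats::optimize(f1, c(p[i] - steps[i], p[i] + steps[i]),
                              tol = max(steps[i] * 1e-3, 1e-4))
        if (op$objective < best) { best <- op$objective; p[i] <- op$minimum }
      }
      if (kind == "affine") {
        # joint line search along uniform scaling, the dominant affine mode:
        # per-axis scale moves barely change NMI on their own
        fu <- function(u) { q <- p; q[7:9] <- p[7:9] * u; cost(q) }
        op <- stats::optimize(fu, c(1 - 2 * steps[7], 1 + 2 * steps[7]),
                              tol = 1e-4)
        if (op$objective < best) { best <- op$objective; p[7:9] <- p[7:9] * op$minimum }
      }
      steps <- steps * 0.5
      if (prev - best < o$tol) { converged <- TRUE; break }
    }
    # joint simplex polish: line searches alone stall when translation,
    # rotation and scale trade off against each other
    ps <- c(rep(2, 3), rep(1, 3),
            if (kind == "affine") c(rep(0.05, 3), rep(0.02, 3))) * scale_fac
    nm <- stats::optim(p, cost, method = "Nelder-Mead",
                       control = list(parscale = ps, maxit = 150 * npar,
                                      reltol = 1e-9))
    if (nm$value < best) { best <- nm$value; p <- nm$par }
    converged <- converged || nm$convergence == 0
  }
  if (!converged) {
    warning("registration did not converge; returning best transform found")
  }
  tr <- linear_transform(params_to_matrix(p, kind, centre), kind)
  attr(tr, "nmi") <- -best
  attr(tr, "converged") <- converged
  attr(tr, "params") <- p
  tr
}

#' Apply a linear transform to a volume
#'
#' Pull-back resampling onto `target`: each target voxel samples the source
#' at \eqn{t^{-1} x}.
#' @param v Source volume.
#' @param t An `aq_xfm`.
#' @param target Target [grid3d()].
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return Volume on `target`.
#' @export
apply_linear <- function(v, t, target,
                         interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  Minv <- solve(t$matrix)
  xyz <- grid_world_coords(target)
  src <- xyz %*% t(Minv[1:3, 1:3]) +
    matrix(Minv[1:3, 4], nrow(xyz), 3, byrow = TRUE)
  vals <- sample_at_world(v, src, interpolation, outside = 0)
  as_volume(array(vals, dim = target$dims), target, meta = v$meta)
}

#' Create / read / apply a dense deformation field
#'
#' A deformation field stores, at every voxel of the target analysis grid, a
#' 3-vector displacement in mm: a point x on the target grid samples the
#' source image at x + d(x) (pull-back, the convention of SPM deformation
#' fields). Fields are exchanged as 5-D NIfTI (nx, ny, nz, 1, 3) volumes.
#'
#' @param grid Target [grid3d()].
#' @param displacement 4-D array `c(grid$dims, 3)` of mm displacements.
#' @return An `aq_deform`.
#' @export
deformation_field <- function(grid, displacement) {
  displacement <- as.array(displacement)
  if (!all(dim(displacement) == c(grid$dims, 3))) {
    stop("displacement shape must be dims x 3")
  }
  if (!all(is.finite(displacement))) stop("displacement contains non-finite values")
  structure(list(grid = grid, displacement = displacement), class = "aq_deform")
}

#' @rdname deformation_field
#' @param path NIfTI path holding a (nx, ny, nz, 1, 3) displacement image.
#' @export
read_deformation <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  dm <- dim(a)
  if (length(dm) == 5 && dm[4] == 1) { a <- array(a, dm[c(1:3, 5)]); dm <- dim(a) }
  if (length(dm) != 4 || dm[4] != 3) stop("expected a (nx,ny,nz,1,3) deformation NIfTI")
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE)); attributes(aff) <- list(dim = c(4L, 4L))
  deformation_field(grid3d(dm[1:3], affine = aff), a)
}

#' @rdname deformation_field
#' @param d An `aq_deform`.
#' @export
write_deformation <- function(d, path) {
  a <- array(d$displacement, dim = c(d$grid$dims, 1, 3))
  img <- RNifti::asNifti(a, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(d$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Apply a deformation field to a volume
#'
#' Output lives on the field's grid; a zero field reduces to plain
#' resampling onto that grid.
#' @param v Source volume.
#' @param d An `aq_deform`.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return Volume on `d$grid`.
#' @export
apply_deformation <- function(v, d,
                              interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  xyz <- grid_world_coords(d$grid)
  src <- xyz + matrix(d$displacement, ncol = 3)
  vals <- sample_at_world(v, src, interpolation, outside = NA)
  if (all(is.na(vals))) {
    stop("deformation field and volume do not overlap in world space")
  }
  vals[is.na(vals)] <- 0
  as_volume(array(vals, dim = d$grid$dims), d$grid, meta = v$meta)
}

# seeded RNG with caller-state restoration
local_rng <- function(seed) {
  state <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  state
}
restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
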