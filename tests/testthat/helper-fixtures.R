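# Shared fixtures. VOI sets are deterministic per grid, so they are built
# once and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached_voi_set <- function(n = 48, spacing = 2) {
  key <- sprintf("vs_%d_%g", n, spacing)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_voi_set(grid3d(rep(n, 3), spacing))
  }
  .fixture_cache[[key]]
}

# structured, smooth phantom used as a registration target
registration_phantom <- function(n = 40, spacing = 4) {
  key <- sprintf("reg_%d_%g", n, spacing)
  if (is.null(.fixture_cache[[key]])) {
    g <- grid3d(rep(n, 3), spacing)
    vs <- make_voi_set(g)
    .fixture_cache[[key]] <- make_phantom(
      phantom_spec(g, region_uptake = c(target = 1.8, WhlCbl = 1),
                   wm_uptake = 1.6, fwhm_blur_mm = 6), vs)$vol
  }
  .fixture_cache[[key]]
}

# one shared n=30 normative database on the 64^3 cohort grid (built once;
# used by the statistical z-map tests and the acceptance checks)
cached_norm_db <- function() {
  if (is.null(.fixture_cache$ndb)) {
    coh <- make_cohort(n_controls = 30, n_patients = 0, seed = 42)
    db <- suppressMessages(
      build_normative_db(coh$controls, coh$vs, "PiB", "WhlCbl", fwhm_mm = 8))
    .fixture_cache$ndb <- list(db = db, vs = coh$vs)
  }
  .fixture_cache$ndb
}

# a bare z-map object from explicit arrays, for cluster-geometry tests
manual_zmap <- function(z, mask, grid) {
  structure(list(
    z = as_volume(z, grid),
    mask = as_mask(mask, grid, "analysis"),
    n_sd_floored = 0L,
    db = list(tracer = "PiB", reference = "WhlCbl", n_controls = 2,
              fwhm_mm = 8, cl_threshold = 10)
  ), class = "aq_zmap")
}

rigid_matrix <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  rot1 <- function(th, axis) {
    R <- diag(3); ax <- setdiff(1:3, axis)
    R[ax[1], ax[1]] <- cos(th); R[ax[2], ax[2]] <- cos(th)
    R[ax[1], ax[2]] <- -sin(th); R[ax[2], ax[1]] <- sin(th)
    R
  }
  M <- diag(4)
  M[1:3, 1:3] <- rot1(rz * pi / 180, 3) %*% rot1(ry * pi / 180, 2) %*%
    rot1(rx * pi / 180, 1)
  M[1:3, 4] <- c(tx, ty, tz)
  M
}

# residual translation (mm) and rotation (deg) of t_hat composed with the
# generating transform; both ~0 when registration recovered the truth
registration_residual <- function(t_hat, m_gen) {
  res <- t_hat$matrix %*% m_gen
  list(trans = sqrt(sum(res[1:3, 4]^2)),
       rot = acos(pmin(1, (sum(diag(res[1:3, 1:3])) - 1) / 2)) * 180 / pi)
}
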