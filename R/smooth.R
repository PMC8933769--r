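# Separable Gaussian smoothing. FWHM is specified in mm and converted per
# axis to voxel units via the grid spacing; sigma = fwhm / (2 sqrt(2 ln 2)).
# The discrete kernel is truncated at 4 sigma and normalized to sum 1, so
# total image mass is preserved away from the boundary (zero-padded edges).

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox < 1e-6) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve along the first axis of a 3-D array with a centred 1-D kernel,
# zero padding at the edges, via a banded matrix product
conv_axis1 <- function(a, kern) {
  if (length(kern) == 1) return(a)
  n <- dim(a)[1]
  r <- (length(kern) - 1) / 2
  K <- matrix(0, n, n)
  for (off in -r:r) {
    w <- kern[off + r + 1]
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + w
  }
  d <- dim(a)
  array(K %*% matrix(a, n), dim = d)
}

#' Gaussian smoothing of a volume
#'
#' Separable 3-D Gaussian filter, FWHM given in mm (isotropic or per axis).
#' `fwhm_mm = 0` is the identity. The applied FWHM is recorded in the
#' volume's provenance tags so downstream Z-map construction can verify the
#' subject was smoothed identically to the normative database.
#'
#' @param v An `aq_vol`.
#' @param fwhm_mm Non-negative FWHM in mm, length 1 or 3.
#' @return Smoothed volume.
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  if (any(fwhm_mm < 0)) stop("fwhm must be non-negative")
  sig <- fwhm_mm * FWHM_TO_SIGMA / v$grid$voxel_size_mm
  a <- v$data
  a <- conv_axis1(a, gauss_kernel_1d(sig[1]))
  a <- aperm(conv_axis1(aperm(a, c(2, 1, 3)), gauss_kernel_1d(sig[2])), c(2, 1, 3))
  a <- aperm(conv_axis1(aperm(a, c(3, 2, 1)), gauss_kernel_1d(sig[3])), c(3, 2, 1))
  out <- as_volume(a, v$grid, meta = v$meta)
  prev <- out$meta$smoothed_fwhm_mm
  out$meta$smoothed_fwhm_mm <- if (is.null(prev)) fwhm_mm[1] else
    sqrt(prev^2 + fwhm_mm[1]^2)
  out
}

# voxelwise SD shrinkage factor of white noise under gaussian_smooth:
# product over axes of sqrt(sum(kernel^2)). Used by the synthetic cohort
# generator to express lesion amplitudes in post-smoothing control-SD units.
smoothing_noise_factor <- function(grid, fwhm_mm) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  sig <- fwhm_mm * FWHM_TO_SIGMA / grid$voxel_size_mm
  prod(vapply(sig, function(s) sqrt(sum(gauss_kernel_1d(s)^2)), 0))
}
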