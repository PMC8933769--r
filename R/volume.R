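#' Construct a volume
#'
#' The universal image carrier: a 3-D scalar array plus its sampling grid and
#' free-form provenance tags. Values must be finite.
#'
#' @param data 3-D numeric array matching `grid$dims`.
#' @param grid An [grid3d()] object.
#' @param meta Named list of provenance tags (e.g. smoothing FWHM applied,
#'   reference region used for normalization).
#' @return An object of class `aq_vol`.
#' @export
as_volume <- function(data, grid, meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("expected 3-D volume")
  if (!all(dim(data) == grid$dims)) stop("data shape does not match grid dims")
  if (!all(is.finite(data))) stop("volume contains non-finite (NaN/Inf) voxels")
  structure(list(data = data, grid = grid, meta = meta), class = "aq_vol")
}

#' @export
print.aq_vol <- function(x, ...) {
  cat(sprintf("<aq_vol> %d x %d x %d voxels; range [%.4g, %.4g]\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              min(x$data), max(x$data)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), vapply(x$meta, function(v)
      paste(format(v), collapse = ","), ""), sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Read a 3-D NIfTI volume
#'
#' Reads NIfTI-1/2 (`.nii` or `.nii.gz`). The file's sform/qform becomes the
#' grid affine (0-based voxel index to world mm). Non-finite voxel values are
#' an error rather than being silently zeroed, because silent zeros corrupt
#' SUVR region means downstream.
#'
#' @param path Path to a NIfTI file.
#' @return An [as_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))   # drop RNifti header attributes
  dm <- dim(a)
  # tolerate trailing singleton dimensions (3-D stored as 4-D with nt = 1)
  if (length(dm) > 3 && all(dm[-(1:3)] == 1)) {
    a <- array(a, dim = dm[1:3])
    dm <- dm[1:3]
  }
  if (length(dm) != 3) stop("expected 3-D volume")
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  g <- grid3d(dm, affine = aff)
  as_volume(a, g, meta = list(source = path))
}

#' Write a volume to NIfTI
#'
#' Stored as float32 with the grid affine in the sform.
#'
#' @param v An `aq_vol`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir))
  img <- RNifti::asNifti(v$data, datatype = "float")
  # sform only: RNifti's qform round-trip drops anisotropic scaling
  img <- RNifti::`sform<-`(img, structure(v$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Move the world origin to a chosen voxel
#'
#' Translates the affine so that the given voxel maps to world (0, 0, 0);
#' voxel data are untouched. This is the programmatic counterpart of manually
#' setting the image origin at the anterior commissure before registration.
#'
#' @param v An `aq_vol`.
#' @param voxel_index Integer triple, 0-based voxel index.
#' @return The re-origined volume.
#' @export
set_origin <- function(v, voxel_index) {
  voxel_index <- as.numeric(voxel_index)
  stopifnot(length(voxel_index) == 3)
  if (any(voxel_index < 0) || any(voxel_index > v$grid$dims - 1)) {
    stop("voxel index out of bounds")
  }
  world <- drop(voxel_to_world(v$grid, matrix(voxel_index, 1)))
  aff <- v$grid$affine
  aff[1:3, 4] <- aff[1:3, 4] - world
  v$grid <- grid3d(v$grid$dims, affine = aff)
  v
}

# tag provenance on a volume
tag_meta <- function(v, ...) {
  v$meta <- utils::modifyList(v$meta, list(...))
  v
}
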