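# Z-score mapping against a normative database of amyloid-negative controls.
#
# Processing order follows the quantification pipeline: each spatially
# standardized PET is smoothed, then divided by its reference-VOI mean
# (count normalization), and the analysis mask (target VOI minus white
# matter) is applied at statistics time -- data are never zeroed in place.
# The database stores the voxelwise mean and sample SD (n - 1 denominator)
# over controls whose global CL is below the amyloid-negativity threshold
# (default CL < 10).

#' Divide a PET volume by its reference-VOI mean
#'
#' After normalization the mean of the output over the reference mask is
#' exactly 1; the operation is idempotent and removes global intensity scale.
#' The reference used is recorded in the provenance tags.
#'
#' @param pet_std Spatially standardized `aq_vol`.
#' @param vs An `aq_voiset`.
#' @param reference Reference region name.
#' @return Normalized volume.
#' @export
normalize_by_reference <- function(pet_std, vs, reference) {
  reference <- canon_reference(reference)
  m <- mask_mean(pet_std, vs$reference_masks[[reference]])
  if (m <= 0) stop(sprintf("non-positive reference mean (%.4g) in '%s'", m, reference))
  out <- as_volume(pet_std$data / m, pet_std$grid, pet_std$meta)
  tag_meta(out, normalized_reference = reference)
}

#' Build the voxelwise analysis mask
#'
#' Target VOI minus an optional white-matter mask (white matter carries high
#' nonspecific counts and is removed before statistics).
#'
#' @param vs An `aq_voiset`.
#' @param wm_mask Optional `aq_mask`; `NULL` falls back to `vs$wm_mask`, and
#'   if that is also absent the analysis mask is the target mask itself.
#' @return An `aq_mask`.
#' @export
build_analysis_mask <- function(vs, wm_mask = NULL) {
  if (is.null(wm_mask)) wm_mask <- vs$wm_mask
  if (is.null(wm_mask)) {
    return(as_mask(vs$target_mask$data, vs$grid, "analysis"))
  }
  stop_if_grid_mismatch(vs$grid, wm_mask$grid, "VOI set and WM mask")
  keep <- vs$target_mask$data == 1L & wm_mask$data == 0L
  if (!any(keep)) stop("empty analysis mask: white-matter mask covers the whole target")
  as_mask(keep, vs$grid, "analysis")
}

#' Build a normative database from amyloid-negative controls
#'
#' Controls with CL at or above `cl_threshold` are excluded (and reported);
#' survivors are smoothed, reference-normalized, and reduced to voxelwise
#' mean and sample SD images.
#'
#' @param controls List of `list(vol = <aq_vol>, cl = <numeric>)` entries
#'   (spatially standardized, unsmoothed PET), optionally with an `id`.
#' @param vs An `aq_voiset`.
#' @param tracer,reference Tracer and reference region labels.
#' @param fwhm_mm Smoothing FWHM in mm (default 8).
#' @param cl_threshold Amyloid-negativity cutoff in CL (default 10).
#' @param wm_mask Optional white-matter mask for [build_analysis_mask()].
#' @return An `aq_ndb` with `mean_vol`, `sd_vol`, `n_controls`,
#'   `analysis_mask`, `excluded` (tibble) and provenance fields.
#' @export
build_normative_db <- function(controls, vs, tracer, reference,
                               fwhm_mm = 8, cl_threshold = 10,
                               wm_mask = NULL) {
  tracer <- canon_tracer(tracer)
  reference <- canon_reference(reference)
  ids <- vapply(seq_along(controls), function(i) {
    id <- controls[[i]]$id
    if (is.null(id)) sprintf("control_%02d", i) else as.character(id)
  }, "")
  cls <- vapply(controls, function(ct) as.numeric(ct$cl), 0)
  keep <- cls < cl_threshold
  excluded <- tibble::tibble(id = ids[!keep], cl = cls[!keep])
  if (nrow(excluded) > 0) {
    message(sprintf("excluding %d control(s) with CL >= %g: %s",
                    nrow(excluded), cl_threshold,
                    paste(sprintf("%s (CL %.1f)", excluded$id, excluded$cl),
                          collapse = ", ")))
  }
  if (sum(keep) < 2) stop("fewer than 2 controls survive the CL filter")
  g <- vs$grid
  nv <- prod(g$dims)
  X <- matrix(0, nv, sum(keep))
  col <- 0
  for (i in which(keep)) {
    v <- controls[[i]]$vol
    stop_if_grid_mismatch(v$grid, g, "control and VOI set")
    v <- gaussian_smooth(v, fwhm_mm)
    v <- normalize_by_reference(v, vs, reference)
    col <- col + 1
    X[, col] <- as.numeric(v$data)
  }
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  structure(list(
    tracer = tracer, reference = reference,
    mean_vol = as_volume(array(mu, g$dims), g),
    sd_vol = as_volume(array(sdv, g$dims), g),
    n_controls = ncol(X),
    analysis_mask = build_analysis_mask(vs, wm_mask),
    cl_threshold = cl_threshold, fwhm_mm = fwhm_mm,
    sd_denominator = "n-1",
    control_ids = ids[keep], excluded = excluded
  ), class = "aq_ndb")
}

#' @export
print.aq_ndb <- function(x, ...) {
  cat(sprintf("<aq_ndb> %s / %s: n=%d controls (CL < %g), fwhm %g mm, mask %d voxels\n",
              x$tracer, x$reference, x$n_controls, x$cl_threshold, x$fwhm_mm,
              mask_count(x$analysis_mask)))
  invisible(x)
}

#' Persist / load a normative database directory
#'
#' Layout: `mean.nii.gz`, `sd.nii.gz`, `mask.nii.gz`, `db.json` (tracer,
#' reference, n, fwhm, CL threshold, per-control provenance).
#' @param db An `aq_ndb`.
#' @param dir Directory path.
#' @return `dir` / the database.
#' @export
write_normative_db <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(db$mean_vol, file.path(dir, "mean.nii.gz"))
  write_volume(db$sd_vol, file.path(dir, "sd.nii.gz"))
  write_volume(as_volume(array(as.numeric(db$analysis_mask$data),
                               db$analysis_mask$grid$dims),
                         db$analysis_mask$grid),
               file.path(dir, "mask.nii.gz"))
  meta <- list(tracer = db$tracer, reference = db$reference,
               n_controls = db$n_controls, fwhm_mm = db$fwhm_mm,
               cl_threshold = db$cl_threshold,
               sd_denominator = db$sd_denominator,
               control_ids = db$control_ids,
               excluded = db$excluded)
  jsonlite::write_json(meta, file.path(dir, "db.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_normative_db
#' @export
read_normative_db <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "db.json"), simplifyVector = TRUE)
  mean_vol <- read_volume(file.path(dir, "mean.nii.gz"))
  sd_vol <- read_volume(file.path(dir, "sd.nii.gz"))
  mask <- binarize(read_volume(file.path(dir, "mask.nii.gz")), "analysis")
  structure(list(
    tracer = meta$tracer, reference = meta$reference,
    mean_vol = mean_vol, sd_vol = sd_vol,
    n_controls = as.integer(meta$n_controls),
    analysis_mask = mask,
    cl_threshold = meta$cl_threshold, fwhm_mm = meta$fwhm_mm,
    sd_denominator = meta$sd_denominator,
    control_ids = meta$control_ids,
    excluded = tibble::as_tibble(meta$excluded)
  ), class = "aq_ndb")
}

#' Compute a subject's Z-score map
#'
#' Z = (subject - control mean) / control SD, inside the analysis mask. The
#' subject must have been smoothed and reference-normalized identically to
#' the database construction; this is verified from the volume's provenance
#' tags, and a mismatch is an error rather than a silent inconsistency.
#' Voxels whose control SD is below a floor (1e-6 times the mean SD over the
#' mask) are excluded from the mask and counted, never clamped.
#'
#' @param subject_norm Smoothed, reference-normalized subject `aq_vol`.
#' @param db An `aq_ndb`.
#' @return An `aq_zmap`: `z` (volume, 0 outside the mask), `mask` (after SD
#'   flooring), `n_sd_floored`, and database provenance.
#' @export
compute_zmap <- function(subject_norm, db) {
  stop_if_grid_mismatch(subject_norm$grid, db$mean_vol$grid, "subject and database")
  fw <- subject_norm$meta$smoothed_fwhm_mm
  if (is.null(fw) || abs(fw - db$fwhm_mm) > 1e-6) {
    stop(sprintf("provenance mismatch: subject smoothed at %s mm, database at %g mm",
                 if (is.null(fw)) "unknown/none" else format(fw), db$fwhm_mm))
  }
  ref <- subject_norm$meta$normalized_reference
  if (is.null(ref) || ref != db$reference) {
    stop(sprintf("provenance mismatch: subject normalized by '%s', database by '%s'",
                 if (is.null(ref)) "nothing" else ref, db$reference))
  }
  g <- db$mean_vol$grid
  inmask <- db$analysis_mask$data == 1L
  sdv <- db$sd_vol$data
  eps <- 1e-6 * mean(sdv[inmask])
  floored <- inmask & sdv < eps
  use <- inmask & !floored
  z <- array(0, g$dims)
  z[use] <- (subject_norm$data[use] - db$mean_vol$data[use]) / sdv[use]
  structure(list(
    z = as_volume(z, g, meta = list(db_tracer = db$tracer,
                                    db_reference = db$reference,
                                    db_n = db$n_controls)),
    mask = as_mask(use, g, "analysis"),
    n_sd_floored = sum(floored),
    db = list(tracer = db$tracer, reference = db$reference,
              n_controls = db$n_controls, fwhm_mm = db$fwhm_mm,
              cl_threshold = db$cl_threshold)
  ), class = "aq_zmap")
}

#' @export
print.aq_zmap <- function(x, ...) {
  zin <- x$z$data[x$mask$data == 1L]
  cat(sprintf("<aq_zmap> %s / %s (n=%d): %d mask voxels, z range [%.2f, %.2f], %d SD-floored\n",
              x$db$tracer, x$db$reference, x$db$n_controls,
              mask_count(x$mask), min(zin), max(zin), x$n_sd_floored))
  invisible(x)
}
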