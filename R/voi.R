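# VOI mask handling: the four reference regions (WhlCbl, CerebGry, Pons,
# WhlCblBrnStm), the global cortical+striatal target ("ctx"), and its
# partition into the five reporting regions.

REFERENCE_NAMES <- c("WhlCbl", "CerebGry", "Pons", "WhlCblBrnStm")
REGION_NAMES <- c("pcc_precuneus", "frontal", "temporal", "parietal", "striatum")

#' Construct a binary mask
#'
#' @param data Logical or 0/1 numeric 3-D array.
#' @param grid A [grid3d()].
#' @param name Label for error messages and reports.
#' @return An `aq_mask`.
#' @export
as_mask <- function(data, grid, name = "mask") {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("expected 3-D mask")
  if (!all(dim(data) == grid$dims)) stop("mask shape does not match grid dims")
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1, TRUE, FALSE))) stop("mask values must be 0/1")
  structure(list(data = array(as.integer(data != 0), grid$dims),
                 grid = grid, name = name), class = "aq_mask")
}

#' @export
print.aq_mask <- function(x, ...) {
  cat(sprintf("<aq_mask> '%s': %d voxels\n", x$name, sum(x$data)))
  invisible(x)
}

mask_count <- function(m) sum(m$data)

# binarize an aq_vol into an aq_mask at a threshold (> thr)
binarize <- function(v, name, threshold = 0.5) {
  as_mask(v$data > threshold, v$grid, name)
}

#' Assemble and validate a VOI set
#'
#' Enforces the structural invariants: every mask on one grid and non-empty,
#' the five region masks pairwise disjoint, and every region contained in the
#' global target mask.
#'
#' @param reference_masks Named list of `aq_mask` for
#'   `r paste(REFERENCE_NAMES, collapse = ", ")`.
#' @param target_mask Global cortical + striatal target `aq_mask` ("ctx").
#' @param region_masks Named list of `aq_mask` for
#'   `r paste(REGION_NAMES, collapse = ", ")`.
#' @param wm_mask Optional white-matter `aq_mask` used by
#'   [build_analysis_mask()].
#' @return An `aq_voiset`.
#' @export
voi_set <- function(reference_masks, target_mask, region_masks, wm_mask = NULL) {
  if (!setequal(names(reference_masks), REFERENCE_NAMES)) {
    stop("reference_masks must be named ", paste(REFERENCE_NAMES, collapse = ", "))
  }
  if (!setequal(names(region_masks), REGION_NAMES)) {
    stop("region_masks must be named ", paste(REGION_NAMES, collapse = ", "))
  }
  reference_masks <- reference_masks[REFERENCE_NAMES]
  region_masks <- region_masks[REGION_NAMES]
  all_masks <- c(reference_masks, list(ctx = target_mask), region_masks)
  if (!is.null(wm_mask)) all_masks <- c(all_masks, list(wm = wm_mask))
  g <- target_mask$grid
  for (nm in names(all_masks)) {
    if (!grids_equal(all_masks[[nm]]$grid, g)) {
      stop(sprintf("grid mismatch: mask '%s' is not on the target grid", nm))
    }
  }
  for (nm in names(c(reference_masks, list(ctx = target_mask), region_masks))) {
    if (mask_count(all_masks[[nm]]) == 0) stop(sprintf("empty mask: '%s'", nm))
  }
  for (i in seq_along(region_masks)) {
    for (j in seq_len(i - 1)) {
      ov <- sum(region_masks[[i]]$data & region_masks[[j]]$data)
      if (ov > 0) {
        stop(sprintf("region masks '%s' and '%s' overlap in %d voxel(s)",
                     names(region_masks)[i], names(region_masks)[j], ov))
      }
    }
  }
  for (nm in names(region_masks)) {
    out <- sum(region_masks[[nm]]$data & !target_mask$data)
    if (out > 0) {
      stop(sprintf("region '%s' has %d voxel(s) outside the target mask", nm, out))
    }
  }
  structure(list(reference_masks = reference_masks, target_mask = target_mask,
                 region_masks = region_masks, wm_mask = wm_mask, grid = g),
            class = "aq_voiset")
}

#' @export
print.aq_voiset <- function(x, ...) {
  cat("<aq_voiset>\n")
  print(partition_report(x), n = Inf)
  invisible(x)
}

#' Load a VOI set from NIfTI mask files
#'
#' Masks are binarized at `threshold` (probabilistic template edges become
#' 0/1) and validated via [voi_set()].
#'
#' @param paths Named character vector/list mapping mask names (the four
#'   reference names, `ctx`, the five region names, optionally `wm`) to
#'   NIfTI paths.
#' @param threshold Binarization threshold (default 0.5).
#' @return An `aq_voiset`.
#' @export
load_voi_set <- function(paths, threshold = 0.5) {
  paths <- as.list(paths)
  need <- c(REFERENCE_NAMES, "ctx", REGION_NAMES)
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("missing VOI paths: ", paste(miss, collapse = ", "))
  rd <- function(nm) binarize(read_volume(paths[[nm]]), nm, threshold)
  voi_set(
    reference_masks = stats::setNames(lapply(REFERENCE_NAMES, rd), REFERENCE_NAMES),
    target_mask = rd("ctx"),
    region_masks = stats::setNames(lapply(REGION_NAMES, rd), REGION_NAMES),
    wm_mask = if ("wm" %in% names(paths)) rd("wm") else NULL
  )
}

#' Canonical VOI filenames in a directory
#'
#' Maps a `--voi-dir` style directory to mask paths using the canonical names
#' `voi_<name>_2mm.nii(.gz)`; `.nii.gz` wins when both exist.
#' @param dir Directory containing the mask files.
#' @return Named list of paths suitable for [load_voi_set()].
#' @export
voi_dir_paths <- function(dir) {
  need <- c(REFERENCE_NAMES, "ctx", REGION_NAMES, "wm")
  p <- lapply(need, function(nm) {
    for (ext in c(".nii.gz", ".nii")) {
      f <- file.path(dir, paste0("voi_", nm, "_2mm", ext))
      if (file.exists(f)) return(f)
    }
    NULL
  })
  names(p) <- need
  p[!vapply(p, is.null, TRUE)]
}

#' Write a VOI set to a directory using the canonical filenames
#' @param vs An `aq_voiset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_voi_set <- function(vs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(m, nm) write_volume(
    as_volume(array(as.numeric(m$data), m$grid$dims), m$grid),
    file.path(dir, paste0("voi_", nm, "_2mm.nii.gz")))
  for (nm in REFERENCE_NAMES) wr(vs$reference_masks[[nm]], nm)
  wr(vs$target_mask, "ctx")
  for (nm in REGION_NAMES) wr(vs$region_masks[[nm]], nm)
  if (!is.null(vs$wm_mask)) wr(vs$wm_mask, "wm")
  invisible(dir)
}

#' Mean of a volume over a mask
#'
#' Unweighted arithmetic mean of the voxel values where the mask is 1.
#' @param v An `aq_vol`.
#' @param m An `aq_mask` on the same grid.
#' @return Scalar mean.
#' @export
mask_mean <- function(v, m) {
  stop_if_grid_mismatch(v$grid, m$grid, "volume and mask")
  n <- mask_count(m)
  if (n == 0) stop(sprintf("empty mask: '%s'", m$name))
  sum(v$data[m$data == 1L]) / n
}

#' Tabulate VOI sizes
#'
#' Per-mask voxel counts and volumes in cc (count x voxel volume).
#' @param vs An `aq_voiset`.
#' @return A tibble with columns `mask`, `role`, `voxels`, `volume_cc`.
#' @export
partition_report <- function(vs) {
  cc <- voxel_volume_cc(vs$grid)
  rows <- rbind(
    data.frame(mask = REFERENCE_NAMES, role = "reference",
               voxels = vapply(vs$reference_masks, mask_count, 0L)),
    data.frame(mask = "ctx", role = "target",
               voxels = mask_count(vs$target_mask)),
    data.frame(mask = REGION_NAMES, role = "region",
               voxels = vapply(vs$region_masks, mask_count, 0L))
  )
  rows$volume_cc <- rows$voxels * cc
  tibble::as_tibble(rows)
}
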