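# End-to-end drivers for the two processes: Centiloid quantification
# (reorient -> coregister -> standardize -> SUVR -> CL) and Z-score mapping
# (smooth -> normalize -> Z -> clusters -> regional calls). Both echo the
# fully resolved configuration and package version into their JSON outputs.

default_config <- function() {
  list(pet = NULL, mri = NULL, voi_dir = NULL, deformation = NULL,
       template = NULL, db = NULL, out = ".",
       tracer = "pib", reference = "whlcbl",
       fwhm = 8, z_threshold = 2.6, min_voxels = 300, connectivity = 18,
       cl_threshold = 10, seed = 0, skip_registration = FALSE)
}

resolve_config <- function(cfg) {
  out <- utils::modifyList(default_config(), cfg[!vapply(cfg, is.null, TRUE)])
  out$tracer <- canon_tracer(out$tracer)
  out$reference <- canon_reference(out$reference)
  out
}

config_meta <- function(cfg) {
  c(cfg, list(package = "amypet",
              version = as.character(utils::packageVersion("amypet"))))
}

#' Prepare a subject volume for Z-map comparison
#'
#' Smooths then reference-normalizes a spatially standardized PET, tagging
#' provenance so [compute_zmap()] can verify consistency with the database.
#' @param pet_std Standardized `aq_vol`.
#' @param vs An `aq_voiset`.
#' @param reference Reference region.
#' @param fwhm_mm Smoothing FWHM (default 8 mm).
#' @return Smoothed, normalized volume.
#' @export
prepare_subject <- function(pet_std, vs, reference, fwhm_mm = 8) {
  normalize_by_reference(gaussian_smooth(pet_std, fwhm_mm), vs, reference)
}

# spatial standardization stage shared by both drivers: returns the PET on
# the VOI grid
standardize_pet <- function(cfg, vs) {
  pet <- read_volume(cfg$pet)
  if (isTRUE(cfg$skip_registration)) {
    if (!grids_equal(pet$grid, vs$grid)) {
      pet <- resample_to_grid(pet, vs$grid)
    }
    return(pet)
  }
  if (is.null(cfg$mri)) stop("stage registration: --mri is required unless --skip-registration")
  mri <- read_volume(cfg$mri)
  t_pet_mri <- register_linear(pet, mri, "rigid", opts = list(seed = cfg$seed))
  pet_in_mri <- apply_linear(pet, t_pet_mri, mri$grid)
  if (!is.null(cfg$deformation)) {
    d <- read_deformation(cfg$deformation)
    return(apply_deformation(pet_in_mri, d))
  }
  if (!is.null(cfg$template)) {
    tmpl <- read_volume(cfg$template)
    t_mri_tmpl <- register_linear(mri, tmpl, "affine", opts = list(seed = cfg$seed))
    return(apply_linear(pet_in_mri, t_mri_tmpl, vs$grid))
  }
  stop("stage standardization: supply --deformation, --template, or --skip-registration")
}

load_vois_from_cfg <- function(cfg) {
  if (is.null(cfg$voi_dir)) stop("--voi-dir is required")
  load_voi_set(voi_dir_paths(cfg$voi_dir))
}

#' Run the Centiloid quantification process
#'
#' Standardizes the PET (unless pre-standardized), computes the SUVR over
#' the global target VOI against the chosen reference, converts to CL, and
#' writes `suvr_cl.json` (all intermediate means included) plus a CSV row.
#'
#' @param cfg Named list of configuration values; see [default_config()]
#'   fields (`pet`, `mri`, `voi_dir`, `deformation`, `template`, `tracer`,
#'   `reference`, `out`, `seed`, `skip_registration`).
#' @return The result list, invisibly; files under `cfg$out`.
#' @export
run_centiloid <- function(cfg) {
  cfg <- resolve_config(cfg)
  vs <- load_vois_from_cfg(cfg)
  pet_std <- standardize_pet(cfg, vs)
  su <- compute_suvr(pet_std, vs, cfg$reference)
  cl <- suvr_to_centiloid(su$suvr, cfg$tracer, cfg$reference)
  res <- list(subject = basename(cfg$pet),
              tracer = cl$tracer, reference = cl$reference,
              target_mean = su$target_mean, reference_mean = su$reference_mean,
              suvr = su$suvr, cl = cl$cl,
              config = config_meta(cfg))
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  jsonlite::write_json(res, file.path(cfg$out, "suvr_cl.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  row <- tibble::tibble(subject = res$subject, tracer = res$tracer,
                        reference = res$reference,
                        target_mean = res$target_mean,
                        reference_mean = res$reference_mean,
                        suvr = res$suvr, cl = res$cl)
  utils::write.csv(row, file.path(cfg$out, "suvr_cl.csv"), row.names = FALSE)
  invisible(res)
}

#' Run the Z-score mapping process
#'
#' Smooths and normalizes the standardized subject PET, compares it with a
#' stored normative database (tracer/reference/FWHM provenance must match),
#' thresholds the Z map into clusters, derives five-region positivity calls,
#' and writes `zmap.nii.gz`, `clusters.json`, `regional_calls.json` and
#' orthogonal slice PNGs under `cfg$out`.
#'
#' @param cfg Named list of configuration values (`pet`, `voi_dir`, `db`,
#'   `reference`, `fwhm`, `z_threshold`, `min_voxels`, `connectivity`,
#'   `out`, `skip_registration`, ...).
#' @return List with `zmap`, `clusters`, `calls`, invisibly.
#' @export
run_zmap <- function(cfg) {
  cfg <- resolve_config(cfg)
  if (is.null(cfg$db)) stop("--db (normative database directory) is required")
  db <- read_normative_db(cfg$db)
  if (db$tracer != cfg$tracer) {
    stop(sprintf("database is for tracer '%s' but run requests '%s'",
                 db$tracer, cfg$tracer))
  }
  if (db$reference != cfg$reference) {
    stop(sprintf("database reference is '%s' but run requests '%s'",
                 db$reference, cfg$reference))
  }
  if (abs(db$fwhm_mm - cfg$fwhm) > 1e-9) {
    stop(sprintf("database was built at %g mm FWHM but run requests %g mm; refusing to mix smoothing levels",
                 db$fwhm_mm, cfg$fwhm))
  }
  vs <- load_vois_from_cfg(cfg)
  pet_std <- standardize_pet(cfg, vs)
  subj <- prepare_subject(pet_std, vs, cfg$reference, cfg$fwhm)
  zm <- compute_zmap(subj, db)
  cs <- threshold_clusters(zm, cfg$z_threshold, cfg$min_voxels, cfg$connectivity)
  calls <- regional_positivity(cs, vs)
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  write_volume(zm$z, file.path(cfg$out, "zmap.nii.gz"))
  meta <- config_meta(cfg)
  jsonlite::write_json(
    list(clusters = tidy(cs), z_threshold = cs$z_threshold,
         min_voxels = cs$min_voxels, connectivity = cs$connectivity,
         n_sd_floored = zm$n_sd_floored, config = meta),
    file.path(cfg$out, "clusters.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(
    list(calls = calls, db = zm$db, config = meta),
    file.path(cfg$out, "regional_calls.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(calls, file.path(cfg$out, "regional_calls.csv"),
                   row.names = FALSE)
  render_overlay(zm, pet_std, vs,
                 opts = list(z_low = cfg$z_threshold,
                             z_high = cfg$z_threshold + 4.4,
                             min_voxels = cfg$min_voxels,
                             connectivity = cfg$connectivity,
                             out_dir = cfg$out))
  invisible(list(zmap = zm, clusters = cs, calls = calls))
}
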