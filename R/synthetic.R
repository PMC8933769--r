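# Synthetic fixtures: geometric phantom brains, VOI sets, control cohorts
# and patient cohorts with known ground truth. Geometry is deliberately
# schematic (ellipsoids and shell sectors) -- the quantification math is
# geometry-agnostic -- but every VOISet invariant of the real templates
# (shared grid, non-empty masks, disjoint regions contained in the target)
# holds by construction and is asserted at build time.

# normalized voxel coordinates in (0,1)^3, matrix nvox x 3
norm_coords <- function(grid) {
  d <- grid$dims
  i <- (rep.int(seq_len(d[1]), d[2] * d[3]) - 0.5) / d[1]
  j <- (rep.int(rep(seq_len(d[2]), each = d[1]), d[3]) - 0.5) / d[2]
  k <- (rep(seq_len(d[3]), each = d[1] * d[2]) - 0.5) / d[3]
  cbind(i, j, k)
}

ellipsoid_rho <- function(q, centre, radii) {
  sqrt(((q[, 1] - centre[1]) / radii[1])^2 +
       ((q[, 2] - centre[2]) / radii[2])^2 +
       ((q[, 3] - centre[3]) / radii[3])^2)
}

# phantom geometry in normalized units; axis 2 = anterior, axis 3 = superior
PHANTOM_GEOM <- list(
  cerebrum_centre = c(0.50, 0.55, 0.62), cerebrum_radii = c(0.33, 0.36, 0.30),
  shell_inner = 0.62,
  wm_outer = 0.50,
  striatum_offset = 0.11, striatum_radii = c(0.09, 0.12, 0.09),
  cereb_centre = c(0.50, 0.30, 0.22), cereb_radii = c(0.24, 0.18, 0.16),
  cereb_gry_inner = 0.60,
  pons_centre = c(0.50, 0.45, 0.30), pons_radii = c(0.16, 0.13, 0.14),
  stem_centre = c(0.50, 0.38, 0.18), stem_radii = c(0.08, 0.08, 0.14)
)

#' Generate a geometric VOI set
#'
#' Builds the full template family on a grid: ellipsoidal whole cerebellum
#' (with a cerebellar-gray outer shell), pons and brainstem reference
#' regions, a cortical-shell-plus-striatum target, the five-region partition
#' of the target (posterior cingulate/precuneus as a posterior medial sector,
#' frontal anterior, temporal inferior, parietal the remaining superior
#' shell, striatum as two deep nuclei), and a deep white-matter mask.
#'
#' @param grid An [grid3d()] with at least 40 voxels per axis.
#' @return An `aq_voiset` (including `wm_mask`).
#' @export
make_voi_set <- function(grid) {
  if (any(grid$dims < 40)) stop("grid too small: need >= 40 voxels per axis")
  G <- PHANTOM_GEOM
  q <- norm_coords(grid)
  d <- grid$dims

  rho_cer <- ellipsoid_rho(q, G$cerebrum_centre, G$cerebrum_radii)
  shell <- rho_cer >= G$shell_inner & rho_cer <= 1
  rho_l <- ellipsoid_rho(q, G$cerebrum_centre - c(G$striatum_offset, 0, 0),
                         G$striatum_radii * c(1, 1, 1))
  rho_r <- ellipsoid_rho(q, G$cerebrum_centre + c(G$striatum_offset, 0, 0),
                         G$striatum_radii)
  striatum <- rho_l <= 1 | rho_r <= 1
  wm <- rho_cer < G$wm_outer & !striatum

  # shell sectors via the ellipsoid-normalized direction
  u <- cbind((q[, 1] - G$cerebrum_centre[1]) / G$cerebrum_radii[1],
             (q[, 2] - G$cerebrum_centre[2]) / G$cerebrum_radii[2],
             (q[, 3] - G$cerebrum_centre[3]) / G$cerebrum_radii[3])
  w <- u / pmax(rho_cer, 1e-9)
  pcc <- shell & w[, 2] <= -0.1 & abs(w[, 1]) <= 0.45 & w[, 3] >= -0.2
  frontal <- shell & !pcc & w[, 2] > 0.1
  temporal <- shell & !pcc & !frontal & w[, 3] < -0.15
  parietal <- shell & !pcc & !frontal & !temporal

  # posterior-fossa structures exclude the cerebrum so reference regions
  # never sample the amyloid target compartment
  outside_cer <- rho_cer > 1
  rho_cb <- ellipsoid_rho(q, G$cereb_centre, G$cereb_radii)
  pons <- ellipsoid_rho(q, G$pons_centre, G$pons_radii) <= 1 & outside_cer
  whl_cbl <- rho_cb <= 1 & outside_cer & !pons
  cereb_gry <- whl_cbl & rho_cb >= G$cereb_gry_inner
  stem <- ellipsoid_rho(q, G$stem_centre, G$stem_radii) <= 1 & outside_cer
  whl_cbl_bs <- whl_cbl | pons | stem

  tomask <- function(v, nm) as_mask(array(v, d), grid, nm)
  vs <- voi_set(
    reference_masks = list(
      WhlCbl = tomask(whl_cbl, "WhlCbl"),
      CerebGry = tomask(cereb_gry, "CerebGry"),
      Pons = tomask(pons, "Pons"),
      WhlCblBrnStm = tomask(whl_cbl_bs, "WhlCblBrnStm")),
    target_mask = tomask(shell | striatum, "ctx"),
    region_masks = list(
      pcc_precuneus = tomask(pcc, "pcc_precuneus"),
      frontal = tomask(frontal, "frontal"),
      temporal = tomask(temporal, "temporal"),
      parietal = tomask(parietal, "parietal"),
      striatum = tomask(striatum, "striatum")),
    wm_mask = tomask(wm, "wm"))
  rep_ <- partition_report(vs)
  if (any(rep_$voxels[rep_$role == "reference"] < 500) ||
      any(rep_$voxels[rep_$role == "region"] < 400)) {
    stop("grid too small for the VOI geometry (reference >= 500, region >= 400 voxels)")
  }
  vs
}

#' Specify a synthetic phantom
#'
#' @param grid Grid for the phantom.
#' @param region_uptake Named numeric: relative uptake per VOI name. Accepts
#'   the reference names, the five region names, and `target` as shorthand
#'   for all five regions.
#' @param background Uptake of unlabeled tissue (default 1).
#' @param wm_uptake White-matter uptake (default `background`; white matter
#'   runs hot in real amyloid PET, so cohort templates set it higher).
#' @param noise_sd Additive Gaussian noise SD, relative to `background`
#'   (applied post-blur; default 0).
#' @param fwhm_blur_mm Scanner PSF emulation blur (default 0).
#' @param seed RNG seed (default 0); phantoms are deterministic per seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid, region_uptake = c(target = 1.5, WhlCbl = 1),
                         background = 1, wm_uptake = NULL,
                         noise_sd = 0, fwhm_blur_mm = 0, seed = 0) {
  stopifnot(all(unlist(region_uptake) >= 0), background >= 0,
            noise_sd >= 0, fwhm_blur_mm >= 0)
  structure(list(grid = grid, region_uptake = as.list(region_uptake),
                 background = background,
                 wm_uptake = if (is.null(wm_uptake)) background else wm_uptake,
                 noise_sd = noise_sd, fwhm_blur_mm = fwhm_blur_mm,
                 seed = seed), class = "phantom_spec")
}

# the piecewise-constant (pre-blur, pre-noise) uptake volume of a spec
phantom_truth_volume <- function(spec, vs) {
  a <- array(spec$background, spec$grid$dims)
  a[vs$wm_mask$data == 1L] <- spec$wm_uptake
  ru <- spec$region_uptake
  # broad reference compartments first, specific ones override
  for (nm in c("WhlCblBrnStm", "WhlCbl", "CerebGry", "Pons")) {
    if (!is.null(ru[[nm]])) a[vs$reference_masks[[nm]]$data == 1L] <- ru[[nm]]
  }
  if (!is.null(ru$target)) a[vs$target_mask$data == 1L] <- ru$target
  for (nm in REGION_NAMES) {
    if (!is.null(ru[[nm]])) a[vs$region_masks[[nm]]$data == 1L] <- ru[[nm]]
  }
  as_volume(a, spec$grid)
}

#' Generate a phantom PET volume with known ground truth
#'
#' Piecewise-constant uptake per VOI plus background and a white-matter
#' compartment, optionally blurred by a Gaussian scanner PSF and degraded by
#' additive Gaussian noise. Ground-truth SUVR is computed from the
#' pre-blur piecewise values; ground-truth CL follows from the published
#' calibration for every available (tracer, reference) pair.
#'
#' @param spec A [phantom_spec()].
#' @param vs An `aq_voiset` on `spec$grid`.
#' @return List with `vol` (`aq_vol`), `truth_suvr` (tibble: reference,
#'   suvr), `truth_cl` (tibble: tracer, reference, suvr, cl).
#' @export
make_phantom <- function(spec, vs) {
  stop_if_grid_mismatch(spec$grid, vs$grid, "phantom spec and VOI set")
  truth <- phantom_truth_volume(spec, vs)
  tm <- mask_mean(truth, vs$target_mask)
  refs <- vapply(REFERENCE_NAMES,
                 function(nm) mask_mean(truth, vs$reference_masks[[nm]]), 0)
  truth_suvr <- tibble::tibble(reference = REFERENCE_NAMES,
                               suvr = tm / refs)
  tab <- calibration_table()
  truth_cl <- tab
  truth_cl$suvr <- truth_suvr$suvr[match(tab$reference, truth_suvr$reference)]
  truth_cl$cl <- truth_cl$intercept + truth_cl$slope * truth_cl$suvr
  truth_cl <- truth_cl[, c("tracer", "reference", "suvr", "cl")]

  v <- truth
  if (spec$fwhm_blur_mm > 0) {
    v <- gaussian_smooth(v, spec$fwhm_blur_mm)
    v$meta$smoothed_fwhm_mm <- NULL    # PSF blur is acquisition, not processing
  }
  if (spec$noise_sd > 0) {
    st <- local_rng(spec$seed)
    on.exit(restore_rng(st), add = TRUE)
    v$data <- v$data + stats::rnorm(length(v$data),
                                    sd = spec$noise_sd * spec$background)
  }
  v$meta$phantom_seed <- spec$seed
  list(vol = v, truth_suvr = truth_suvr, truth_cl = truth_cl)
}

#' Generate a noiseless validation cohort across the CL range
#'
#' `n` blur-free, noise-free phantoms whose target uptake sweeps a range of
#' true SUVR values, for end-to-end validation of the quantification chain
#' against its own ground truth.
#'
#' @param n Number of phantoms (default 20).
#' @param vs An `aq_voiset`.
#' @param tracer,reference Labels for the ground-truth CL.
#' @param suvr_range True SUVR sweep (default 1.0 to 2.2).
#' @return Tibble-backed list with `vols` (list of `aq_vol`) and `truth`
#'   (tibble: subject, suvr_true, cl_true).
#' @export
make_validation_cohort <- function(n = 20, vs, tracer = "PiB",
                                   reference = "WhlCbl",
                                   suvr_range = c(1.0, 2.2)) {
  reference <- canon_reference(reference)
  su <- seq(suvr_range[1], suvr_range[2], length.out = n)
  vols <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    up <- stats::setNames(list(su[i], 1), c("target", reference))
    ph <- make_phantom(phantom_spec(vs$grid, region_uptake = up), vs)
    vols[[i]] <- ph$vol
    tr <- ph$truth_cl
    row <- tr[tr$tracer == canon_tracer(tracer) & tr$reference == reference, ]
    truth[[i]] <- tibble::tibble(subject = sprintf("phantom_%02d", i),
                                 suvr_true = row$suvr, cl_true = row$cl)
  }
  list(vols = vols, truth = do.call(rbind, truth))
}

#' Generate a control + patient cohort with known regional ground truth
#'
#' Controls are i.i.d. draws around a fixed amyloid-negative template
#' (gray-matter uptake 1, hot white matter, scanner PSF blur, additive voxel
#' noise). Patients add a compact lesion whose amplitude is expressed in
#' units of the post-smoothing control SD (computed analytically from the
#' noise SD and the smoothing kernel), so `effect_profile = c(pcc_precuneus
#' = 5)` injects a lesion expected to read ~5 on the Z map at the lesion
#' core.
#'
#' @param n_controls Number of controls (>= 2).
#' @param n_patients Number of patients.
#' @param effect_profile Named numeric mapping region name to Z-effect size
#'   (empty or zeros for null patients).
#' @param seed RNG seed.
#' @param vs VOI set; default is `make_voi_set(grid)`.
#' @param grid Grid when `vs` is absent: 64^3 voxels at 2 mm, so the default
#'   cluster rule (300 voxels = 2.4 cc) applies unchanged.
#' @param noise_sd Voxel noise SD relative to background (default 0.05).
#' @param fwhm_blur_mm Scanner PSF (default 4).
#' @param fwhm_smooth_mm Analysis smoothing the cohort is destined for
#'   (default 8); used only to express effects in post-smoothing SD units.
#' @param lesion_voxels Lesion extent in voxels (default 600), carved as the
#'   most compact subset of the region around its centroid.
#' @param tracer,reference Labels used to assign each control a nominal CL
#'   via the quantification chain.
#' @return List: `vs`, `controls` (list of `list(vol, cl, id)`), `patients`
#'   (list of `list(vol, id)`), `truth` (tibble of per-patient true regional
#'   positivity), `params`.
#' @export
make_cohort <- function(n_controls, n_patients = 0, effect_profile = c(),
                        seed = 0, vs = NULL, grid = NULL,
                        noise_sd = 0.05, fwhm_blur_mm = 4,
                        fwhm_smooth_mm = 8, lesion_voxels = 600,
                        tracer = "PiB", reference = "WhlCbl") {
  stopifnot(n_controls >= 2)
  reference <- canon_reference(reference)
  if (is.null(vs)) {
    if (is.null(grid)) grid <- grid3d(c(64, 64, 64), 2)
    vs <- make_voi_set(grid)
  }
  g <- vs$grid
  template_spec <- phantom_spec(
    g, region_uptake = stats::setNames(
      list(1, 1, 1, 1, 1), c("target", REFERENCE_NAMES)),
    background = 1, wm_uptake = 1.6, noise_sd = 0, fwhm_blur_mm = fwhm_blur_mm)
  template <- make_phantom(template_spec, vs)$vol
  sd_abs <- noise_sd * template_spec$background
  # post-smoothing SD of the voxel noise, and its value after reference
  # normalization (reference mean of the template is ~1 by construction)
  ref_mean <- mask_mean(template, vs$reference_masks[[reference]])
  sd_post <- sd_abs * smoothing_noise_factor(g, fwhm_smooth_mm)

  st <- local_rng(seed)
  on.exit(restore_rng(st), add = TRUE)
  draw <- function() {
    v <- as_volume(template$data + stats::rnorm(prod(g$dims), sd = sd_abs), g)
    v
  }
  controls <- lapply(seq_len(n_controls), function(i) {
    v <- draw()
    cl <- suvr_to_centiloid(compute_suvr(v, vs, reference)$suvr,
                            tracer, reference)$cl
    list(vol = v, cl = cl, id = sprintf("control_%03d", i))
  })

  effect_profile <- effect_profile[effect_profile != 0]
  lesion_delta <- array(0, g$dims)
  lesion_regions <- names(effect_profile)
  lesion_idx <- list()
  if (length(effect_profile)) {
    stopifnot(all(lesion_regions %in% REGION_NAMES))
    for (nm in lesion_regions) {
      idx <- which(vs$region_masks[[nm]]$data == 1L)
      co <- voxel_to_world(g, arrayInd(idx, g$dims) - 1)
      # seed at mid-shell depth along the region's mean direction (the raw
      # centroid of a curved sector sits off mid-thickness, which would carve
      # a flattened, smoothing-vulnerable patch), then grow the most compact
      # ball of voxels around the seed
      G <- PHANTOM_GEOM
      q <- (arrayInd(idx, g$dims) - 0.5) / matrix(g$dims, length(idx), 3,
                                                  byrow = TRUE)
      u <- (q - matrix(G$cerebrum_centre, nrow(q), 3, byrow = TRUE)) /
        matrix(G$cerebrum_radii, nrow(q), 3, byrow = TRUE)
      rho <- sqrt(rowSums(u^2))
      wdir <- colMeans(u / rho)
      if (nm == "striatum" || sqrt(sum(wdir^2)) < 0.2) {
        # deep nuclei (or a wrap-around sector): plain centroid seed
        cen <- colMeans(co)
        seed_i <- which.min(rowSums((co - matrix(cen, nrow(co), 3,
                                                 byrow = TRUE))^2))
      } else {
        wdir <- wdir / sqrt(sum(wdir^2))
        u_tgt <- wdir * (G$shell_inner + 1) / 2
        seed_i <- which.min(rowSums((u - matrix(u_tgt, nrow(u), 3,
                                                byrow = TRUE))^2))
      }
      dist <- sqrt(rowSums((co - matrix(co[seed_i, ], nrow(co), 3,
                                        byrow = TRUE))^2))
      take <- idx[order(dist)][seq_len(min(lesion_voxels, length(idx)))]
      lesion_idx[[nm]] <- take
      # the analysis smoothing attenuates a compact lesion's profile, so a
      # raw injection of k*SD reads below k on the Z map; scale by the
      # kernel's mean attenuation over the lesion support so the delivered
      # mean effect in the Z-comparison domain equals the requested one
      ind <- array(0, g$dims); ind[take] <- 1
      att <- mean(gaussian_smooth(as_volume(ind, g), fwhm_smooth_mm)$data[take])
      lesion_delta[take] <- lesion_delta[take] +
        effect_profile[[nm]] * sd_post * ref_mean / att
    }
  }
  patients <- lapply(seq_len(n_patients), function(i) {
    v <- draw()
    v$data <- v$data + lesion_delta
    list(vol = v, id = sprintf("patient_%03d", i))
  })
  truth <- tibble::tibble(
    region = REGION_NAMES,
    positive = REGION_NAMES %in% lesion_regions,
    effect_z = vapply(REGION_NAMES, function(nm) {
      if (nm %in% lesion_regions) effect_profile[[nm]] else 0
    }, 0))
  list(vs = vs, controls = controls, patients = patients, truth = truth,
       lesion_idx = lesion_idx,
       params = list(seed = seed, noise_sd = noise_sd, sd_post = sd_post,
                     fwhm_blur_mm = fwhm_blur_mm,
                     fwhm_smooth_mm = fwhm_smooth_mm,
                     lesion_voxels = lesion_voxels,
                     tracer = canon_tracer(tracer), reference = reference))
}

#' Write a self-contained simulation bundle to disk
#'
#' NIfTI volumes, the VOI set under canonical names, and
#' `ground_truth.json`; the layout is directly consumable by the CLI
#' commands.
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_voi_set(cohort$vs, file.path(dir, "voi"))
  cdir <- file.path(dir, "controls"); dir.create(cdir, showWarnings = FALSE)
  pdir <- file.path(dir, "patients"); dir.create(pdir, showWarnings = FALSE)
  for (ct in cohort$controls) {
    write_volume(ct$vol, file.path(cdir, paste0(ct$id, ".nii.gz")))
  }
  for (pt in cohort$patients) {
    write_volume(pt$vol, file.path(pdir, paste0(pt$id, ".nii.gz")))
  }
  gt <- list(truth = cohort$truth, params = cohort$params,
             controls = data.frame(
               id = vapply(cohort$controls, `[[`, "", "id"),
               cl = vapply(cohort$controls, `[[`, 0, "cl")))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
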