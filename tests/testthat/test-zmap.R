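test_that("reference normalization fixes the reference mean at 1 and is idempotent", {
  vs <- cached_voi_set(48)
  g <- vs$grid
  expect_true(all(abs(normalize_by_reference(
    as_volume(array(3, g$dims), g), vs, "WhlCbl")$data - 1) < 1e-12))

  set.seed(6)
  v <- as_volume(array(runif(prod(g$dims), 0.5, 2), g$dims), g)
  n1 <- normalize_by_reference(v, vs, "WhlCbl")
  expect_equal(mask_mean(n1, vs$reference_masks$WhlCbl), 1, tolerance = 1e-12)
  n2 <- normalize_by_reference(n1, vs, "WhlCbl")
  expect_lt(max(abs(n2$data - n1$data)), 1e-12)
  expect_identical(n1$meta$normalized_reference, "WhlCbl")
})

test_that("the analysis mask is the target minus white matter", {
  vs <- cached_voi_set(48)
  m0 <- build_analysis_mask(vs, wm_mask = NULL)
  # the fixture ships a WM mask, so NULL falls back to it
  expect_equal(mask_count(m0),
               sum(vs$target_mask$data == 1L & vs$wm_mask$data == 0L))
  vs_nowm <- vs; vs_nowm$wm_mask <- NULL
  expect_equal(mask_count(build_analysis_mask(vs_nowm)),
               mask_count(vs$target_mask))

  all_wm <- as_mask(array(1, vs$grid$dims), vs$grid, "wm")
  expect_error(build_analysis_mask(vs, all_wm), "empty analysis mask")

  disjoint <- as_mask(array(0, vs$grid$dims), vs$grid, "wm")
  expect_equal(mask_count(build_analysis_mask(vs, disjoint)),
               mask_count(vs$target_mask))
})

test_that("normative DB filters controls at the CL threshold and logs exclusions", {
  vs <- cached_voi_set(40)
  g <- vs$grid
  set.seed(7)
  mk <- function(cl) list(vol = as_volume(array(runif(prod(g$dims), 0.9, 1.1),
                                                g$dims), g), cl = cl)
  expect_message(
    db <- build_normative_db(list(mk(3), mk(7), mk(12)), vs, "PiB", "WhlCbl",
                             fwhm_mm = 4, cl_threshold = 10),
    "excluding 1 control")
  expect_equal(db$n_controls, 2L)
  expect_equal(nrow(db$excluded), 1L)
  expect_equal(db$excluded$cl, 12)

  expect_error(suppressMessages(
    build_normative_db(list(mk(3), mk(12), mk(15)), vs, "PiB", "WhlCbl")),
    "fewer than 2")

  # two identical controls have an identically zero SD image
  cvol <- mk(1)
  db0 <- build_normative_db(list(cvol, cvol), vs, "PiB", "WhlCbl", fwhm_mm = 4)
  expect_true(all(db0$sd_vol$data == 0))
})

test_that("voxelwise mean/SD and Z equal brute-force per-voxel statistics", {
  vs <- cached_voi_set(40)
  g <- vs$grid
  set.seed(8)
  vols <- lapply(1:10, function(i)
    list(vol = as_volume(array(runif(prod(g$dims), 0.8, 1.2), g$dims), g),
         cl = 0))
  db <- build_normative_db(vols, vs, "PiB", "WhlCbl", fwhm_mm = 6)
  # recompute what the db should hold, voxel by voxel, on a random sample
  proc <- lapply(vols, function(ct)
    normalize_by_reference(gaussian_smooth(ct$vol, 6), vs, "WhlCbl")$data)
  pick <- sample(prod(g$dims), 250)
  for (j in pick) {
    xs <- vapply(proc, `[[`, 0, j)
    expect_equal(db$mean_vol$data[j], mean(xs), tolerance = 1e-9)
    expect_equal(db$sd_vol$data[j], stats::sd(xs), tolerance = 1e-9)
  }

  subj <- prepare_subject(vols[[1]]$vol, vs, "WhlCbl", 6)
  zm <- compute_zmap(subj, db)
  inm <- which(zm$mask$data == 1L)
  j <- sample(inm, 200)
  expect_equal(zm$z$data[j],
               (subj$data[j] - db$mean_vol$data[j]) / db$sd_vol$data[j],
               tolerance = 1e-9)

  # trivial identities
  zm_mean <- compute_zmap(
    amypet:::tag_meta(db$mean_vol, smoothed_fwhm_mm = 6,
                      normalized_reference = "WhlCbl"), db)
  expect_true(all(abs(zm_mean$z$data[zm_mean$mask$data == 1L]) < 1e-9))
  plus1 <- as_volume(db$mean_vol$data + db$sd_vol$data, g,
                     meta = list(smoothed_fwhm_mm = 6,
                                 normalized_reference = "WhlCbl"))
  zm1 <- compute_zmap(plus1, db)
  expect_true(all(abs(zm1$z$data[zm1$mask$data == 1L] - 1) < 1e-9))
})

test_that("provenance mismatches between subject and DB are refused", {
  vs <- cached_voi_set(40)
  g <- vs$grid
  set.seed(9)
  vols <- lapply(1:3, function(i)
    list(vol = as_volume(array(runif(prod(g$dims), 0.9, 1.1), g$dims), g), cl = 0))
  db <- build_normative_db(vols, vs, "PiB", "WhlCbl", fwhm_mm = 8)
  raw <- vols[[1]]$vol
  expect_error(compute_zmap(raw, db), "provenance mismatch")
  wrong_fwhm <- prepare_subject(raw, vs, "WhlCbl", 4)
  expect_error(compute_zmap(wrong_fwhm, db), "provenance mismatch")
  wrong_ref <- prepare_subject(raw, vs, "Pons", 8)
  expect_error(compute_zmap(wrong_ref, db), "provenance mismatch")
})

test_that("Z-maps are invariant to global rescaling of the subject PET", {
  nd <- cached_norm_db()
  cp <- make_cohort(n_controls = 2, n_patients = 1,
                    effect_profile = c(frontal = 5), seed = 101, vs = nd$vs)
  raw <- cp$patients[[1]]$vol
  z1 <- compute_zmap(prepare_subject(raw, nd$vs, "WhlCbl", 8), nd$db)
  scaled <- as_volume(raw$data * 12.3, raw$grid)
  z2 <- compute_zmap(prepare_subject(scaled, nd$vs, "WhlCbl", 8), nd$db)
  expect_lt(max(abs(z1$z$data - z2$z$data)), 1e-6)
})

test_that("normative DB directories round-trip", {
  nd <- cached_norm_db()
  d <- withr::local_tempdir()
  write_normative_db(nd$db, d)
  db2 <- read_normative_db(d)
  expect_equal(db2$n_controls, nd$db$n_controls)
  expect_equal(db2$fwhm_mm, nd$db$fwhm_mm)
  expect_equal(db2$mean_vol$data, nd$db$mean_vol$data, tolerance = 1e-6)
  expect_equal(db2$sd_vol$data, nd$db$sd_vol$data, tolerance = 1e-6)
  expect_equal(mask_count(db2$analysis_mask), mask_count(nd$db$analysis_mask))
})
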