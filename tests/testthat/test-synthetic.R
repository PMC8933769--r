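test_that("generated VOI sets satisfy all structural invariants across grids", {
  for (spec in list(c(40, 2), c(64, 2))) {
    vs <- cached_voi_set(spec[1], spec[2])
    rep_ <- partition_report(vs)
    expect_true(all(rep_$voxels[rep_$role == "reference"] >= 500))
    expect_true(all(rep_$voxels[rep_$role == "region"] >= 400))
    # pairwise disjoint regions contained in the target
    acc <- array(0L, vs$grid$dims)
    for (m in vs$region_masks) acc <- acc + m$data
    expect_lte(max(acc), 1L)
    expect_true(all(vs$target_mask$data[acc == 1L] == 1L))
  }
  expect_error(make_voi_set(grid3d(c(30, 40, 40), 2)), "too small")
})

test_that("phantoms are deterministic per seed and recover injected SUVR", {
  vs <- cached_voi_set(48)
  g <- vs$grid
  sp <- phantom_spec(g, region_uptake = c(target = 1.8, WhlCbl = 1.2),
                     noise_sd = 0.05, fwhm_blur_mm = 4, seed = 3)
  p1 <- make_phantom(sp, vs)
  p2 <- make_phantom(sp, vs)
  expect_identical(p1$vol$data, p2$vol$data)
  p3 <- make_phantom(phantom_spec(g, region_uptake = c(target = 1.8, WhlCbl = 1.2),
                                  noise_sd = 0.05, fwhm_blur_mm = 4, seed = 4), vs)
  expect_false(identical(p1$vol$data, p3$vol$data))

  # noiseless, blur-free: measured SUVR is exactly the uptake ratio
  p0 <- make_phantom(phantom_spec(g, region_uptake = c(target = 1.8, WhlCbl = 1.2)), vs)
  tr <- p0$truth_suvr
  expect_equal(unname(tr$suvr[tr$reference == "WhlCbl"]), 1.5,
               tolerance = 1e-12)
  expect_equal(compute_suvr(p0$vol, vs, "WhlCbl")$suvr, 1.5, tolerance = 1e-6)

  # ground-truth CL uses the published equations
  row <- p0$truth_cl[p0$truth_cl$tracer == "PiB" &
                       p0$truth_cl$reference == "WhlCbl", ]
  expect_equal(unname(row$cl), -94.64 + 93.75 * 1.5, tolerance = 1e-9)

  # with a 6 mm PSF the measured SUVR stays within 5% of truth
  pb <- make_phantom(phantom_spec(g, region_uptake = c(target = 1.8, WhlCbl = 1.2),
                                  fwhm_blur_mm = 6), vs)
  su <- compute_suvr(pb$vol, vs, "WhlCbl")$suvr
  expect_lt(abs(su - 1.5) / 1.5, 0.05)
})

test_that("cohorts differ across seeds and null patients look like controls", {
  nd <- cached_norm_db()
  c1 <- make_cohort(n_controls = 2, n_patients = 1, seed = 1, vs = nd$vs)
  c2 <- make_cohort(n_controls = 2, n_patients = 1, seed = 2, vs = nd$vs)
  expect_false(identical(c1$controls[[1]]$vol$data, c2$controls[[1]]$vol$data))
  expect_false(any(c1$truth$positive))

  # null subjects: the mean Z over the analysis mask stays near zero
  inm <- nd$db$analysis_mask$data == 1L
  mz <- vapply(1:20, function(i) {
    cp <- make_cohort(n_controls = 2, n_patients = 1, seed = 300 + i, vs = nd$vs)
    zm <- compute_zmap(prepare_subject(cp$patients[[1]]$vol, nd$vs, "WhlCbl", 8),
                       nd$db)
    mean(zm$z$data[inm])
  }, 0)
  expect_lt(mean(abs(mz)), 0.2)
})

test_that("the suprathreshold rate of null subjects is controlled", {
  nd <- cached_norm_db()
  inm <- nd$db$analysis_mask$data == 1L
  fr <- vapply(1:20, function(i) {
    cp <- make_cohort(n_controls = 2, n_patients = 0, seed = 500 + i, vs = nd$vs)
    zm <- compute_zmap(prepare_subject(cp$controls[[1]]$vol, nd$vs, "WhlCbl", 8),
                       nd$db)
    mean(zm$z$data[inm] >= 2.6)
  }, 0)
  expect_lt(mean(fr), 0.02)
})

test_that("simulation bundles are self-contained on disk", {
  coh <- make_cohort(n_controls = 3, n_patients = 1,
                     effect_profile = c(temporal = 5), seed = 77,
                     grid = grid3d(c(40, 40, 40), 2))
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  expect_length(list.files(file.path(d, "controls")), 3)
  expect_length(list.files(file.path(d, "patients")), 1)
  vs2 <- load_voi_set(voi_dir_paths(file.path(d, "voi")))
  expect_equal(mask_count(vs2$target_mask), mask_count(coh$vs$target_mask))
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_true(gt$truth$positive[gt$truth$region == "temporal"])
})
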