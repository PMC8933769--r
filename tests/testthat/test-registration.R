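test_that("apply_linear honours identity, inverse composition and rotations", {
  fx <- registration_phantom()
  g <- fx$grid
  ident <- linear_transform(diag(4), "rigid")
  expect_lt(max(abs(apply_linear(fx, ident, g)$data - fx$data)), 1e-6)

  tr <- linear_transform(rigid_matrix(tx = 6, ty = -4, tz = 2), "rigid")
  back <- apply_linear(apply_linear(fx, tr, g), invert_transform(tr), g)
  interior <- amypet:::ellipsoid_rho(amypet:::norm_coords(g), c(0.5, 0.5, 0.5),
                                     c(0.35, 0.35, 0.35)) <= 1
  expect_lt(mean(abs(back$data - fx$data)[interior]), 0.02 * max(fx$data))

  # a bar along x maps onto y under a 90 degree z-rotation
  bar <- array(0, g$dims)
  bar[6:(g$dims[1] - 5), 19:22, 19:22] <- 1
  bv <- as_volume(bar, g)
  rot <- linear_transform(rigid_matrix(rz = 90), "rigid")
  rb <- apply_linear(bv, rot, g, "nearest")
  on_y <- sum(rb$data[19:22, 6:(g$dims[2] - 5), 19:22])
  expect_gt(on_y / sum(rb$data), 0.95)
})

test_that("registering a volume to itself returns (near) identity", {
  fx <- registration_phantom()
  t0 <- register_linear(fx, fx, "rigid", opts = list(levels = c(8), sweeps = 4))
  res <- registration_residual(t0, diag(4))
  expect_lt(res$trans, 0.1)
  expect_lt(res$rot, 0.1)
})

test_that("rigid registration recovers a known translation+rotation and raises NMI", {
  fx <- registration_phantom()
  m_gen <- rigid_matrix(tx = 6, ty = -4, tz = 2, rz = 5)
  mv <- apply_linear(fx, linear_transform(m_gen, "rigid"), fx$grid)
  nmi_before <- nmi(fx, mv)
  t_hat <- register_linear(mv, fx, "rigid", opts = list(levels = c(8, 4)))
  res <- registration_residual(t_hat, m_gen)
  expect_lt(res$trans, 0.5)
  expect_lt(res$rot, 0.5)
  moved <- apply_linear(mv, t_hat, fx$grid)
  expect_gt(nmi(fx, moved), nmi_before)
  expect_error(register_linear(as_volume(array(1, fx$grid$dims), fx$grid),
                               fx, "rigid"), "constant")
})

test_that("affine registration recovers a 5% global scale within 1%", {
  fx <- registration_phantom()
  S <- diag(4); S[1:3, 1:3] <- diag(rep(1.05, 3))
  mv <- apply_linear(fx, linear_transform(S, "affine"), fx$grid)
  t_hat <- register_linear(mv, fx, "affine", opts = list(levels = c(8, 4)))
  scales <- sqrt(colSums((t_hat$matrix %*% S)[1:3, 1:3]^2))
  expect_true(all(abs(scales - 1) < 0.01))
})

test_that("transforms serialize as plain-text matrices", {
  tr <- linear_transform(rigid_matrix(tx = 1.5, rz = 10), "rigid")
  f <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, f)
  tr2 <- read_transform(f, "rigid")
  expect_equal(tr2$matrix, tr$matrix, tolerance = 1e-12)
  expect_error(linear_transform(diag(c(2, 1, 1, 1)), "rigid"),
               "orthonormal")
})

test_that("deformation fields: zero field resamples, constant field translates", {
  fx <- registration_phantom()
  g <- fx$grid
  zero <- deformation_field(g, array(0, c(g$dims, 3)))
  expect_lt(max(abs(apply_deformation(fx, zero)$data -
                      resample_to_grid(fx, g)$data)), 1e-9)

  disp <- array(0, c(g$dims, 3)); disp[, , , 1] <- 2
  shifted <- apply_deformation(fx, deformation_field(g, disp))
  tr <- linear_transform(rigid_matrix(tx = -2), "rigid")
  ref <- apply_linear(fx, tr, g)
  interior <- amypet:::ellipsoid_rho(amypet:::norm_coords(g), c(0.5, 0.5, 0.5),
                                     c(0.4, 0.4, 0.4)) <= 1
  expect_lt(max(abs(shifted$data - ref$data)[interior]), 1e-6)
})

test_that("a radial deformation changes a sphere's volume per its Jacobian", {
  g <- grid3d(c(40, 40, 40), 2)
  xyz <- amypet:::grid_world_coords(g)
  sphere <- array(as.numeric(sqrt(rowSums(xyz^2)) <= 16), g$dims)
  sv <- as_volume(sphere, g)
  alpha <- 0.08   # x -> x + alpha * x, uniform expansion of the lookup point
  disp <- array(alpha * xyz, c(g$dims, 3))
  out <- apply_deformation(sv, deformation_field(g, disp))
  # pull-back by (1+alpha) shrinks the image; compare total mass against a
  # numeric-Jacobian oracle of the mapping x -> (1+alpha) x
  eps <- 1e-3
  dfun <- function(p) p * (1 + alpha)
  J <- (dfun(diag(3) * eps) - dfun(-diag(3) * eps)) / (2 * eps)
  det_j <- det(J)
  expect_equal(sum(out$data) / sum(sphere), 1 / det_j, tolerance = 0.02)
})

test_that("deformation fields round-trip through 5-D NIfTI", {
  g <- grid3d(c(10, 11, 12), 2)
  set.seed(4)
  disp <- array(rnorm(prod(g$dims) * 3), c(g$dims, 3))
  d <- deformation_field(g, disp)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_deformation(d, f)
  d2 <- read_deformation(f)
  expect_equal(d2$displacement, d$displacement, tolerance = 1e-6)
  expect_equal(d2$grid$affine, g$affine, tolerance = 1e-5)
})

test_that("rigid registration recovers randomized small poses on noiseless phantoms", {
  fx <- registration_phantom()
  set.seed(11)
  for (rep in 1:2) {
    m_gen <- rigid_matrix(tx = runif(1, -10, 10), ty = runif(1, -10, 10),
                          tz = runif(1, -10, 10), rx = runif(1, -10, 10),
                          rz = runif(1, -10, 10))
    mv <- apply_linear(fx, linear_transform(m_gen, "rigid"), fx$grid)
    t_hat <- register_linear(mv, fx, "rigid", opts = list(levels = c(8, 4)))
    res <- registration_residual(t_hat, m_gen)
    expect_lt(res$trans, 0.5)
    expect_lt(res$rot, 0.5)
  }
})
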