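blob3 <- function(d, ctr, s = 6) {
  g <- expand.grid(z = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1, x = seq_len(d[3]) - 1)
  array(exp(-((g$z - ctr[1])^2 + (g$y - ctr[2])^2 + (g$x - ctr[3])^2) / (2 * s^2)), dim = d)
}

test_that("preprocessing resamples to isotropic spacing and clears background", {
  v <- volume4d(array(runif(2 * 40 * 40 * 40), c(2, 40, 40, 40)), c(1, 1, 1), 0.005)
  out <- preprocess_volume(v, intensity_threshold = 0)
  expect_equal(dim(out$data), c(2, 20, 20, 20))
  expect_equal(out$spacing, c(2, 2, 2))
  # already isotropic at 2 um, threshold 0: unchanged
  v2 <- volume4d(array(runif(2 * 8 * 8 * 8), c(2, 8, 8, 8)), c(2, 2, 2), 0.005)
  expect_equal(preprocess_volume(v2, 0)$data, v2$data)
  # thresholding zeroes sub-threshold voxels
  out3 <- preprocess_volume(v2, 0.5)
  expect_true(all(out3$data[out3$data > 0] >= 0.5))
  # an all-background series comes out all zero
  v4 <- volume4d(array(0.01, c(1, 8, 8, 8)), c(2, 2, 2), 0.005)
  expect_true(all(preprocess_volume(v4, 0.5)$data == 0))
})

test_that("demons returns a zero field on identical inputs", {
  d <- c(24, 24, 24)
  ref <- blob3(d, c(12, 12, 12))
  df <- demons_register(ref, ref, iterations = c(20, 10, 5), spacing_um = 2)
  expect_lt(max(abs(df$field)), 1e-3)
})

test_that("demons recovers pure translations of a smooth blob", {
  d <- c(48, 48, 48)   # blob comfortably inside the field of view
  ref <- blob3(d, c(24, 24, 24))
  mov <- blob3(d, c(24, 25.5, 24))   # 1.5 voxels along y
  df <- demons_register(ref, mov, spacing_um = 2)
  w <- ref > 0.1
  f <- df$field / 2
  epe <- sqrt(f[, , , 1][w]^2 + (f[, , , 2][w] - 1.5)^2 + f[, , , 3][w]^2)
  expect_lt(mean(epe), 0.5)
})

test_that("demons recovers the phantom shell displacement", {
  rc <- reg_cycle()
  hb <- rc$heart
  r0 <- array(hb$volume$data[1, , , ], rc$cfg$grid)
  shell <- which(r0 > 0.5)
  ai <- arrayInd(shell, rc$cfg$grid)
  pts <- (ai - 1) * rc$cfg$voxel_um
  tru <- hb$truth$displacement(pts, 0, 1)
  f <- rc$fields[[1]]$field
  est <- cbind(f[, , , 1][shell], f[, , , 2][shell], f[, , , 3][shell])
  epe <- sqrt(rowSums((est - tru)^2)) / rc$cfg$voxel_um
  expect_lt(mean(epe), 0.5)
})

test_that("velocity is displacement over the frame interval, masked", {
  d <- c(4, 4, 4)
  f1 <- structure(list(field = array(4, dim = c(d, 3)), from = 0, to = 1,
                       spacing = c(2, 2, 2)), class = "displacement_field")
  vf <- displacement_to_velocity(list(f1), 0.005)
  expect_equal(unique(as.vector(vf$v)), 800)
  mask <- array(FALSE, d); mask[1, 1, 1] <- TRUE
  vfm <- displacement_to_velocity(list(f1), 0.005, mask)
  expect_equal(sum(vfm$v != 0), 3)
  f0 <- f1; f0$field[] <- 0
  expect_true(all(displacement_to_velocity(list(f0), 0.005)$v == 0))
  expect_error(displacement_to_velocity(list(f1), 0), "positive")
})

test_that("composed demons displacements close over one phantom cycle", {
  rc <- reg_cycle()
  pts <- rc$heart$truth$boundary_points(200, t = 0)
  p <- pts
  h <- rc$cfg$voxel_um
  for (t in seq_len(rc$cfg$period)) {
    f <- rc$fields[[t]]$field
    d <- vapply(1:3, function(k)
      cardio4d:::trilinear(f[, , , k], p[, 1] / h, p[, 2] / h, p[, 3] / h),
      numeric(nrow(p)))
    p <- p + d
  }
  err <- sqrt(rowSums((p - pts)^2)) / h
  expect_lt(max(err), 1)
})

test_that("temporal smoothing is circular and conserves the cycle mean", {
  set.seed(7)
  v <- array(rnorm(10 * 3 * 3 * 3 * 3), dim = c(10, 3, 3, 3, 3))
  vf <- vector_field4d(v, NULL, 2, 0.005)
  sm <- smooth_temporal(vf, 7)
  expect_equal(apply(sm$v, 2:5, mean), apply(vf$v, 2:5, mean))
  expect_equal(smooth_temporal(vf, 1)$v, vf$v)
  expect_error(smooth_temporal(vf, 4), "odd")
  expect_error(smooth_temporal(vf, 11), "cycle")
  # constant-in-time field is unchanged
  vc <- vector_field4d(array(rep(rnorm(81), each = 10), dim = c(10, 3, 3, 3, 3)),
                       NULL, 2, 0.005)
  expect_equal(smooth_temporal(vc, 5)$v, vc$v)
  # a unit impulse spreads to 1/7 over seven frames, circularly
  vi <- array(0, dim = c(10, 2, 2, 2, 3)); vi[1, 1, 1, 1, 1] <- 1
  si <- smooth_temporal(vector_field4d(vi, NULL, 2, 0.005), 7)
  got <- si$v[, 1, 1, 1, 1]
  expect_equal(got, c(rep(1 / 7, 4), 0, 0, 0, rep(1 / 7, 3)))
})

test_that("velocity gradients match an independent finite-difference loop", {
  set.seed(8)
  d <- c(3, 5, 6, 7)
  v <- array(rnorm(prod(c(d, 3))), dim = c(d, 3))
  mask <- array(runif(prod(d[2:4])) > 0.3, dim = d[2:4])
  vf <- vector_field4d(v, mask, c(2, 2, 2), 0.005)
  G <- velocity_gradient(vf)
  bf <- array(0, dim = c(d, 3, 3))
  for (t in 1:d[1]) for (z in 1:d[2]) for (y in 1:d[3]) for (x in 1:d[4]) {
    if (!mask[z, y, x]) next
    for (k in 1:3) for (ax in 1:3) {
      i <- c(z, y, x)
      ip <- i; ip[ax] <- ip[ax] + 1
      im <- i; im[ax] <- im[ax] - 1
      okp <- ip[ax] <= d[ax + 1] && mask[ip[1], ip[2], ip[3]]
      okm <- im[ax] >= 1 && mask[im[1], im[2], im[3]]
      vp <- if (okp) vf$v[t, ip[1], ip[2], ip[3], k] else vf$v[t, z, y, x, k]
      vm <- if (okm) vf$v[t, im[1], im[2], im[3], k] else vf$v[t, z, y, x, k]
      st <- sum(okp, okm)
      bf[t, z, y, x, k, ax] <- if (st > 0) (vp - vm) / (st * 2) else 0
    }
  }
  expect_lt(max(abs(G - bf)), 1e-12)
})

test_that("linear and uniform fields have the expected gradients", {
  d <- c(2, 6, 6, 6)
  vu <- vector_field4d(array(3, dim = c(d, 3)), NULL, 2, 0.005)
  expect_true(all(velocity_gradient(vu) == 0))
  # v_x = c * x gives dv_x/dx = c in the interior
  v <- array(0, dim = c(d, 3))
  for (x in 1:6) v[, , , x, 3] <- 5 * (x - 1) * 2
  G <- velocity_gradient(vector_field4d(v, NULL, 2, 0.005))
  expect_equal(unique(as.vector(G[, , , 2:5, 3, 3])), 5)
})

test_that("the speed heatmap is the voxel-wise velocity norm", {
  v <- array(0, dim = c(1, 2, 2, 2, 3))
  v[1, 1, 1, 1, ] <- c(3, 4, 0)
  vf <- vector_field4d(v, NULL, 2, 0.005)
  hm <- speed_heatmap(vf)
  expect_equal(hm[1, 1, 1, 1], 5)
  expect_equal(sum(hm != 0), 1)
  set.seed(9)
  vr <- array(rnorm(2 * 3 * 3 * 3 * 3), dim = c(2, 3, 3, 3, 3))
  vfr <- vector_field4d(vr, NULL, 2, 0.005)
  hr <- speed_heatmap(vfr)
  for (k in 1:3) expect_true(all(hr >= abs(vfr$v[, , , , k]) - 1e-12))
})

test_that("kymograph and vector-field deformation rates agree on the phantom", {
  rc <- reg_cycle()
  cfg <- rc$cfg
  vf <- smooth_temporal(displacement_to_velocity(rc$fields, 1 / cfg$fps), 5)
  ctr <- cfg$shell_center
  ext <- (cfg$grid - 1) * cfg$voxel_um
  aligned <- rbind(c(ctr[1], 5, ctr[3]), c(ctr[1], ext[2] - 5, ctr[3]))
  ka <- kymograph_deformation_rate(rc$heart$volume, aligned, vf)
  expect_gt(cor(ka$rate_kymograph, ka$rate_vector_field), 0.8)
  # a static scene has (near) zero deformation rates
  still <- rc$heart$volume
  still$data <- still$data[rep(1L, 4), , , , drop = FALSE]
  vf0 <- vf; vf0$v <- vf0$v[1:4, , , , , drop = FALSE] * 0
  k0 <- kymograph_deformation_rate(still, aligned, vf0)
  expect_lt(max(abs(k0$rate_kymograph)), 1e-6)
  expect_true(all(k0$rate_vector_field == 0))
  # a line missing the shell raises an error naming the frame
  faraway <- rbind(c(ctr[1], 1, 1), c(ctr[1], 5, 1))
  expect_error(kymograph_deformation_rate(rc$heart$volume, faraway, vf),
               "frame")
})

test_that("a tilted sampling line inflates the kymograph rate by ~1/cos", {
  rc <- reg_cycle()
  cfg <- rc$cfg
  vf <- smooth_temporal(displacement_to_velocity(rc$fields, 1 / cfg$fps), 5)
  ctr <- cfg$shell_center
  ext <- (cfg$grid - 1) * cfg$voxel_um
  aligned <- rbind(c(ctr[1], 5, ctr[3]), c(ctr[1], ext[2] - 5, ctr[3]))
  ka <- kymograph_deformation_rate(rc$heart$volume, aligned, vf)
  # 60 degrees incidence at the detected (outer half-maximum) boundary
  rb <- cfg$shell_radii[3] + cfg$wall_thickness / 2
  d <- rb * sin(pi / 3)
  tilted <- rbind(c(ctr[1], 5, ctr[3] + d), c(ctr[1], ext[2] - 5, ctr[3] + d))
  kt <- kymograph_deformation_rate(rc$heart$volume, tilted, vf)
  ratio <- sqrt(mean(kt$rate_kymograph^2)) / sqrt(mean(ka$rate_kymograph^2))
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.6)
  # and the tilted kymograph rate exceeds the projected vector-field rate
  expect_gt(sqrt(mean(kt$rate_kymograph^2)), sqrt(mean(kt$rate_vector_field^2)))
})
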