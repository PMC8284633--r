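test_that("the principal plane comes out of the covariance eigenvectors", {
  set.seed(12)
  n <- 200
  pts <- cbind(rnorm(n, 0, 0.001), rnorm(n, 0, 5), rnorm(n, 0, 9))  # z ~ 0 plane
  pl <- fit_principal_plane(pts)
  expect_lt(min(sum((pl$normal - c(1, 0, 0))^2), sum((pl$normal + c(1, 0, 0))^2)), 1e-4)
  # rotating the cloud rotates the recovered normal
  R <- rotation_matrix(0.4, -0.7, 1.1)
  flat <- cbind(0, rnorm(n, 0, 5), rnorm(n, 0, 9))
  pl2 <- fit_principal_plane(flat %*% t(R))
  nr <- R %*% c(1, 0, 0)
  ang <- acos(min(1, abs(sum(pl2$normal * nr))))
  expect_lt(ang, 1e-6)
  expect_error(fit_principal_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "degenerate")
  line <- outer(seq_len(30), c(1, 2, 3))
  expect_error(fit_principal_plane(line), "collinear")
})

test_that("theta is the in-plane angle about the center", {
  pl <- list(center = c(0, 0, 0), e1 = c(0, 0, 1), e2 = c(0, 1, 0),
             normal = c(1, 0, 0))
  expect_equal(compute_theta(rbind(c(0, 0, 5)), c(0, 0, 0), pl), 0)
  expect_equal(compute_theta(rbind(c(0, 3, 0)), c(0, 0, 0), pl), pi / 2)
  th <- compute_theta(rbind(c(0, 2, 2), c(0, -2, -2)), c(0, 0, 0), pl)
  expect_equal(abs(diff(th)), pi)
  expect_error(compute_theta(rbind(c(0, 0, 0)), c(0, 0, 0), pl), "coincides")
  # the branch cut moves into the largest gap: an arc straddling +-pi stays
  # continuous
  a <- c(seq(2.8, pi, length.out = 5), seq(-pi, -2.8, length.out = 5))
  pts <- cbind(0, 10 * sin(a), 10 * cos(a))
  th2 <- compute_theta(pts, c(0, 0, 0), pl)
  expect_lt(diff(range(th2)), 1)
})

test_that("a quartic-in-theta curve is recovered to machine precision", {
  th <- seq(-1.6, 1.6, length.out = 60)
  coefs <- matrix(c(30, 2, -1, 0.5, -0.2,
                    60, -8, 3, 1, 0.3,
                    70, 10, -2, -0.8, 0.15), 5, 3)
  pts <- cardio4d:::vander(th, 4) %*% coefs
  cl <- fit_centerline(pts, theta = th)
  expect_lt(max(abs(coef(cl) - coefs) / pmax(abs(coefs), 1e-12)), 1e-6)
  expect_lt(max(abs(residuals(cl))), 1e-8)
  # predict() reproduces the fitted points
  expect_equal(predict(cl, th), unclass(fitted(cl)), tolerance = 1e-9)
  # tangents are unit and arc length increases
  expect_equal(row_norms <- sqrt(rowSums(cl$tangents^2)), rep(1, 200))
  expect_true(all(diff(cl$arc_length) > 0))
})

test_that("degenerate centerline inputs are rejected", {
  th <- seq(0, 0.5, length.out = 20)   # span below pi/4
  pts <- cbind(0, 40 * sin(th), 40 * cos(th)) + matrix(rnorm(60, 0, 0.1), 20)
  expect_error(fit_centerline(pts, center = c(0, 0, 0)), "span")
  expect_error(fit_centerline(matrix(rnorm(9), 3, 3)), "at least")
})

test_that("noise grows the fit error sublinearly with residuals near sigma", {
  arc <- arc_centerline()
  tp <- arc$points
  err_at <- function(sig) {
    es <- sapply(1:10, function(i) {
      set.seed(100 * sig + i)
      P <- tp + matrix(rnorm(length(tp), sd = sig), nrow(tp))
      cl <- fit_centerline(P, center = arc$center)
      d2 <- outer(rowSums(tp^2), rowSums(cl$samples^2), "+") - 2 * tp %*% t(cl$samples)
      c(sqrt(max(apply(d2, 1, min))), stats::sd(cl$residuals))
    })
    rowMeans(es)
  }
  e1 <- err_at(1); e2 <- err_at(2)
  expect_lt(e2[1], 2 * e1[1])          # sublinear curve-error growth
  # residual sd tracks sigma (slightly below it: the tangential noise
  # component is absorbed into the angular parameterization)
  expect_gt(e1[2], 0.6); expect_lt(e1[2], 1.05)
  expect_equal(e2[2] / e1[2], 2, tolerance = 0.15)
})

test_that("the AV-canal end can be designated by position", {
  arc <- arc_centerline()
  cl_min <- fit_centerline(arc$points, center = arc$center, av_end = "theta_min")
  cl_max <- fit_centerline(arc$points, center = arc$center, av_end = "theta_max")
  expect_equal(cl_min$samples, cl_max$samples[200:1, ])
  expect_equal(cl_min$tangents, -cl_max$tangents[200:1, ])
  # designating either end by position puts the curve start nearest to it
  for (end_pt in list(arc$points[1, ], arc$points[nrow(arc$points), ])) {
    cl_pt <- fit_centerline(arc$points, center = arc$center, av_point = end_pt)
    d_start <- sum((cl_pt$samples[1, ] - end_pt)^2)
    d_end <- sum((cl_pt$samples[200, ] - end_pt)^2)
    expect_lt(d_start, d_end)
  }
})

test_that("velocity projections follow the local tangent", {
  arc <- arc_centerline()
  cl <- arc$cl
  fr <- cardio4d:::transported_frames(cl)
  i <- c(40, 120)
  pos <- cl$samples[i, ]
  tan <- cl$tangents[i, ]
  mk <- function(vel) {
    tk <- data.frame(track_id = seq_len(nrow(pos)), frame = 0L,
                     z = pos[, 1], y = pos[, 2], x = pos[, 3],
                     vz = vel[, 1], vy = vel[, 2], vx = vel[, 3])
    class(tk) <- c("track_set", "data.frame")
    tk
  }
  # parallel to the tangent: projection is +|v|
  p1 <- project_flow_velocity(mk(300 * tan), cl)
  expect_equal(p1$velocity[1], 300, tolerance = 1e-9)
  expect_equal(p1$n_cells[1], 2L)
  # perpendicular: zero
  p2 <- project_flow_velocity(mk(250 * fr$u[i, ]), cl)
  expect_lt(abs(p2$velocity[1]), 1e-9)
  # |projection| <= |velocity| for random vectors
  set.seed(13)
  vr <- matrix(rnorm(6, 0, 400), 2, 3)
  p3 <- project_flow_velocity(mk(vr), cl)
  expect_lte(abs(p3$velocity[1]), mean(sqrt(rowSums(vr^2))))
  expect_error(project_flow_velocity(mk(vr)[, 1:5], cl), "velocities")
})

test_that("frames with no tracked cells are missing, not zero", {
  arc <- arc_centerline()
  tk <- data.frame(track_id = 1L, frame = c(0L, 3L),
                   z = arc$cl$samples[c(10, 20), 1], y = arc$cl$samples[c(10, 20), 2],
                   x = arc$cl$samples[c(10, 20), 3],
                   vz = c(1, 1), vy = c(0, 0), vx = c(0, 0))
  class(tk) <- c("track_set", "data.frame")
  p <- project_flow_velocity(tk, arc$cl)
  expect_true(all(is.na(p$velocity[p$frame %in% c(1, 2)])))
  expect_equal(p$n_cells[p$frame %in% c(1, 2)], c(0L, 0L))
})

test_that("reversal intervals are maximal runs below minus the threshold", {
  expect_equal(nrow(detect_reversal(c(10, 200, 1500), 1000)), 0)
  s <- rep(500, 50); s[31:36] <- -1500
  r <- detect_reversal(s, 1000)
  expect_equal(r$start, 31); expect_equal(r$end, 36)
  s2 <- rep(500, 50); s2[31:36] <- -800
  expect_equal(nrow(detect_reversal(s2, 1000)), 0)
  # data.frame input reports frame labels and ignores NA
  df <- data.frame(frame = 0:9, velocity = c(NA, -2000, -2000, 0, 0, -1800, 1, 1, NA, -1500))
  r2 <- detect_reversal(df, 1000)
  expect_equal(r2, data.frame(start = c(1L, 5L, 9L), end = c(2L, 5L, 9L)))
})

test_that("centerline coordinates round trip", {
  arc <- arc_centerline()
  cl <- arc$cl
  # a centerline sample maps to zero offsets
  cc0 <- to_centerline_coords(cl$samples[c(15, 110), ], cl)
  expect_lt(max(abs(c(cc0$u, cc0$w))), 1e-9)
  # displacement along the local normal axes is read back exactly
  fr <- cardio4d:::transported_frames(cl)
  i <- 80
  q <- cl$samples[i, ] + 7 * fr$u[i, ] - 4 * fr$w[i, ]
  cc1 <- to_centerline_coords(rbind(q), cl)
  expect_equal(cc1$u, 7, tolerance = 1e-6)
  expect_equal(cc1$w, -4, tolerance = 1e-6)
  # round trip within 0.5 um for interior points within 30 um of the curve
  set.seed(14)
  base <- cl$samples[sample(20:180, 30), ]
  off <- matrix(runif(90, -15, 15), 30, 3)
  q2 <- base + off
  cc2 <- to_centerline_coords(q2, cl)
  back <- from_centerline_coords(cc2, cl)
  expect_lt(max(sqrt(rowSums((back - q2)^2))), 0.5)
})

test_that("segments partition the mask exactly with the stated geometry", {
  arc <- arc_centerline()
  cl <- arc$cl
  mask <- centerline_mask(cl, c(32, 64, 64), 2, radius_um = 16)
  lab <- partition_segments(mask, cl, 4, spacing_um = 2)
  expect_true(all(lab[mask] > 0))
  expect_true(all(lab[!mask] == 0))
  expect_equal(sum(lab > 0), sum(mask))
  expect_error(partition_segments(mask, cl, 3, spacing_um = 2), "even")
  # a voxel at arc fraction ~0.25 with positive lateral offset is segment 1
  fr <- cardio4d:::transported_frames(cl)
  i <- which.min(abs(cl$arc_length - 0.25 * max(cl$arc_length)))
  p <- cl$samples[i, ] + 5 * fr$u[i, ]
  expect_equal(partition_segments(rbind(p), cl, 4), 1L)
  expect_equal(partition_segments(rbind(cl$samples[i, ] - 5 * fr$u[i, ]), cl, 4), 2L)
  # distal half, both sides
  j <- which.min(abs(cl$arc_length - 0.75 * max(cl$arc_length)))
  expect_equal(partition_segments(rbind(cl$samples[j, ] + 5 * fr$u[j, ]), cl, 4), 3L)
  expect_equal(partition_segments(rbind(cl$samples[j, ] - 5 * fr$u[j, ]), cl, 4), 4L)
})

test_that("a symmetric point cloud splits evenly left and right", {
  arc <- arc_centerline()
  cl <- arc$cl
  smax <- max(cl$arc_length)
  grid <- expand.grid(s = seq(0.05, 0.95, length.out = 40) * smax,
                      u = seq(-12, 12, length.out = 11),
                      w = seq(-8, 8, length.out = 7))
  grid <- grid[abs(grid$u) > 1e-9, ]   # no points exactly on the axis
  pts <- from_centerline_coords(grid, cl)
  lab <- partition_segments(pts, cl, 4)
  left <- sum(lab %in% c(1, 3)); right <- sum(lab %in% c(2, 4))
  expect_lt(abs(left - right) / (left + right), 0.02)
})

test_that("segment statistics equal a brute-force summation", {
  set.seed(15)
  n <- 400
  v <- matrix(rnorm(3 * n, 0, 200), n, 3)
  lab <- sample(1:4, n, replace = TRUE)
  st <- segment_vector_stats(v, lab, 4)
  mag <- sqrt(rowSums(v^2))
  for (k in 1:4) {
    i <- which(lab == k)
    mv <- c(0, 0, 0); wv <- c(0, 0, 0); sw <- 0; mm <- 0
    for (j in i) {
      mv <- mv + v[j, ]
      wv <- wv + mag[j] * v[j, ]
      sw <- sw + mag[j]
      mm <- mm + mag[j]
    }
    mv <- mv / length(i); wv <- wv / sw; mm <- mm / length(i)
    r <- st[st$segment == k, ]
    expect_lt(max(abs(c(r$mean_vz, r$mean_vy, r$mean_vx) - mv) / pmax(abs(mv), 1e-12)), 1e-9)
    expect_lt(max(abs(c(r$wmean_vz, r$wmean_vy, r$wmean_vx) - wv) / pmax(abs(wv), 1e-12)), 1e-9)
    expect_equal(r$mean_mag, mm, tolerance = 1e-12)
    expect_equal(r$rel_velocity, mm / mean(mag), tolerance = 1e-12)
  }
  # voxel-count weighted mean of segment magnitudes equals the global mean
  expect_equal(sum(st$n_vox * st$mean_mag) / sum(st$n_vox), st$global_mag[1],
               tolerance = 1e-12)
})

test_that("uniform fields give unit relative velocity everywhere", {
  v <- matrix(rep(c(3, 4, 0), each = 100), 100, 3)
  st <- segment_vector_stats(v, rep(1:4, each = 25), 4)
  expect_equal(st$mean_mag, rep(5, 4))
  expect_equal(st$rel_velocity, rep(1, 4))
  # zero outside one segment
  v2 <- v; v2[26:100, ] <- 0
  st2 <- segment_vector_stats(v2, rep(1:4, each = 25), 4)
  expect_equal(st2$mean_mag[2:4], rep(0, 3))
  # empty segments are flagged missing
  st3 <- segment_vector_stats(v[1:50, ], rep(1:2, each = 25), 4)
  expect_true(all(is.na(st3$rel_velocity[3:4])))
  expect_equal(st3$n_vox[3:4], c(0L, 0L))
})

test_that("per-frame field statistics agree with the vector core", {
  set.seed(16)
  d <- c(3, 6, 6, 6)
  v <- array(rnorm(prod(c(d, 3)), 0, 100), dim = c(d, 3))
  lab <- array(0L, d[2:4]); lab[2:5, 2:5, 2:5] <- sample(1:4, 64, replace = TRUE)
  mask <- lab > 0
  vf <- vector_field4d(v, mask, 2, 0.005)
  st <- segment_statistics(vf, lab)
  expect_equal(nrow(st), 3 * 4)
  sel <- which(lab > 0)
  for (t in 1:3) {
    vt <- matrix(vf$v[t, , , , ], ncol = 3)[sel, ]
    ref <- segment_vector_stats(vt, lab[sel], 4)
    got <- as.data.frame(st)[st$frame == t - 1, names(ref)]
    rownames(got) <- NULL
    class(got) <- "data.frame"
    expect_equal(got, ref, tolerance = 1e-12)
  }
  badlab <- lab; badlab[sel[1]] <- 0L
  expect_error(segment_statistics(vf, badlab), "cover")
})

test_that("phase windows split the cycle at flow sign changes", {
  prof <- c(-500, 200, 800, 900, 400, 100, -300, -1200)
  w <- phase_windows(prof)
  expect_equal(w$systole, 2:6)
  expect_equal(w$diastole, c(1, 7, 8))
  st <- data.frame(frame = rep(0:7, each = 2), segment = rep(1:2, 8),
                   rel_velocity = rep(c(1.2, 0.8), 8))
  rel <- relative_velocity_by_phase(st, w$systole - 1, w$diastole - 1)
  expect_equal(rel$rel_velocity, c(1.2, 0.8, 1.2, 0.8))
})

test_that("rigid motions leave the scalar flow geometry invariant", {
  arc <- arc_centerline()
  set.seed(17)
  pts <- arc$points + matrix(rnorm(length(arc$points), 0, 0.5), nrow(arc$points))
  vel <- matrix(rnorm(length(pts), 0, 300), nrow(pts))
  tk <- data.frame(track_id = seq_len(nrow(pts)), frame = 0L,
                   z = pts[, 1], y = pts[, 2], x = pts[, 3],
                   vz = vel[, 1], vy = vel[, 2], vx = vel[, 3])
  class(tk) <- c("track_set", "data.frame")
  R <- rotation_matrix(0.7, -0.3, 1.9)
  shift <- c(40, -25, 60)
  ptsR <- sweep(pts %*% t(R), 2, shift, "+")
  velR <- vel %*% t(R)
  tkR <- tk
  tkR[, c("z", "y", "x")] <- ptsR
  tkR[, c("vz", "vy", "vx")] <- velR
  av <- pts[1, ]
  avR <- as.numeric(R %*% av + shift)
  cl <- fit_centerline(pts, av_point = av)
  clR <- fit_centerline(ptsR, av_point = avR)
  # arc length, residual norms, projections, relative velocities invariant
  expect_equal(max(clR$arc_length), max(cl$arc_length), tolerance = 1e-6)
  expect_equal(sort(sqrt(rowSums(residuals(clR)^2))),
               sort(sqrt(rowSums(residuals(cl)^2))), tolerance = 1e-6)
  p <- project_flow_velocity(tk, cl)$velocity
  pR <- project_flow_velocity(tkR, clR)$velocity
  expect_equal(pR, p, tolerance = 1e-6)
  lab <- partition_segments(pts, cl, 4)
  labR <- partition_segments(ptsR, clR, 4)
  st <- segment_vector_stats(vel, lab, 4)
  stR <- segment_vector_stats(velR, labR, 4)
  expect_equal(sort(stR$rel_velocity), sort(st$rel_velocity), tolerance = 1e-6)
  expect_equal(stR$global_mag, st$global_mag, tolerance = 1e-6)
  # magnitudes of the segment mean vectors are invariant as a multiset
  expect_equal(sort(sqrt(stR$wmean_vz^2 + stR$wmean_vy^2 + stR$wmean_vx^2)),
               sort(sqrt(st$wmean_vz^2 + st$wmean_vy^2 + st$wmean_vx^2)),
               tolerance = 1e-6)
})
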