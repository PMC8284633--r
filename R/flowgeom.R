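#' Principal plane of a 3-D point cloud
#'
#' Eigen-decomposition of the covariance matrix of the positions: the two
#' leading eigenvectors span the principal plane through the centroid, the
#' third is the plane normal. Eigenvector signs are fixed by making each
#' vector's largest-magnitude component positive, and the normal is
#' `e1 x e2` so the basis is right-handed.
#'
#' @param points n x 3 matrix of positions `(z, y, x)` in micrometers,
#'   n >= 3 and not collinear.
#' @return A list with `center`, `e1`, `e2`, `normal` and the eigenvalues
#'   `values`.
#' @export
fit_principal_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("degenerate geometry: at least 3 points required")
  ctr <- colMeans(points)
  cv <- stats::cov(points)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= 1e-10 * max(eg$values[1], 1e-300))
    stop("degenerate geometry: points are collinear")
  fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  e1 <- fix_sign(eg$vectors[, 1])
  e2 <- fix_sign(eg$vectors[, 2])
  list(center = ctr, e1 = e1, e2 = e2, normal = unit(cross3(e1, e2)),
       values = eg$values)
}

#' Angular coordinate of points about a center, in the principal plane
#'
#' Projects each point onto the principal plane and measures its angle
#' `theta = atan2(b, a)` about the center, where `(a, b)` are the in-plane
#' coordinates. The branch cut is placed in the largest angular gap of the
#' data so that `theta` is continuous along the arc the points occupy.
#'
#' @param points n x 3 matrix `(z, y, x)`, micrometers.
#' @param center 3-vector; angles are measured about this point.
#' @param plane a plane as returned by [fit_principal_plane()].
#' @return Numeric vector of angles (radians) on a continuous branch.
#' @export
compute_theta <- function(points, center, plane) {
  points <- as.matrix(points)
  d <- sweep(points, 2, center)
  a <- d %*% plane$e1
  b <- d %*% plane$e2
  r <- sqrt(a^2 + b^2)
  if (any(r < 1e-9)) stop("point coincides with the center")
  th <- atan2(b, a)
  n <- length(th)
  if (n > 1) {
    o <- order(th)
    gaps <- diff(th[o])
    wrap_gap <- 2 * pi - (th[o[n]] - th[o[1]])
    if (max(gaps) > wrap_gap) {
      # the occupied arc crosses the +/-pi cut: move the branch cut into
      # the largest interior gap so theta is continuous over the arc
      cut <- th[o[which.max(gaps) + 1]]
      th[th < cut] <- th[th < cut] + 2 * pi
    }
  }
  as.numeric(th)
}

vander <- function(theta, order) outer(theta, 0:order, "^")

#' Fit the flow centerline as polynomials in the angular coordinate
#'
#' Each spatial coordinate is regressed on `[1, theta, ..., theta^order]`
#' by ordinary least squares (the classic quartic-in-angle centerline),
#' evaluated densely, with unit tangents from the analytic derivative of
#' the polynomials. The curve is oriented so that it runs from the
#' atrioventricular canal to the outflow tract: by default the `theta_min`
#' end is the AV canal; pass `av_end = "theta_max"` or an explicit
#' `av_point` position to designate the other end.
#'
#' @param points n x 3 matrix of pooled tracer positions `(z, y, x)`,
#'   micrometers; at least `order + 1` points spanning more than `pi/4` in
#'   `theta` (>= 15 recommended).
#' @param center angle center; default the centroid of the points.
#' @param order polynomial order (4 in the standard analysis).
#' @param av_end which `theta` end is the AV canal (curve start).
#' @param av_point optional position (micrometers); the curve end nearer to
#'   it becomes the start. Overrides `av_end` and is rotation-safe.
#' @param theta optional precomputed angles (radians) per point; computed
#'   with [compute_theta()] when `NULL`.
#' @param n_samples dense evaluation count along the curve.
#' @return An object of class `centerline` with the plane basis, the
#'   `(order+1) x 3` coefficient matrix, dense `samples`, unit `tangents`
#'   oriented AV canal -> OFT, `arc_length`, and per-point `residuals`.
#'   Methods: `print`, `coef`, `predict(theta =)`, `fitted`, `residuals`,
#'   `plot`.
#' @export
fit_centerline <- function(points, center = NULL, order = 4L,
                           av_end = c("theta_min", "theta_max"),
                           av_point = NULL, theta = NULL, n_samples = 200L) {
  av_end <- match.arg(av_end)
  points <- as.matrix(points)
  if (nrow(points) < order + 1)
    stop(sprintf("at least %d points are required for an order-%d fit", order + 1, order))
  plane <- fit_principal_plane(points)
  center <- center %||% plane$center
  if (is.null(theta)) theta <- compute_theta(points, center, plane)
  span <- diff(range(theta))
  if (span <= pi / 4)
    stop("theta span too small (<= pi/4): the polynomial fit is ill-conditioned")
  X <- vander(theta, order)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("ill-conditioned design matrix: theta values do not span the fit order")
  coefs <- qr.coef(qx, points)           # (order+1) x 3
  fitted_pts <- X %*% coefs

  thg <- seq(min(theta), max(theta), length.out = n_samples)
  S <- vander(thg, order) %*% coefs
  dcoefs <- coefs[-1, , drop = FALSE] * (1:order)
  Tg <- vander(thg, order - 1L) %*% dcoefs
  Tg <- Tg / row_norms(Tg)

  flip <- switch(av_end, theta_min = FALSE, theta_max = TRUE)
  if (!is.null(av_point)) {
    av_point <- as.numeric(av_point)
    d_first <- sum((S[1, ] - av_point)^2)
    d_last <- sum((S[n_samples, ] - av_point)^2)
    flip <- d_last < d_first
  }
  if (flip) {
    S <- S[n_samples:1, , drop = FALSE]
    Tg <- -Tg[n_samples:1, , drop = FALSE]
    thg <- rev(thg)
  }
  arc <- c(0, cumsum(row_norms(diff(S))))

  structure(list(center = as.numeric(center), plane = plane,
                 coefficients = coefs, order = order,
                 theta = theta, theta_range = range(theta), theta_grid = thg,
                 samples = S, tangents = Tg, arc_length = arc,
                 av_end = if (flip) "theta_max" else "theta_min",
                 points = points, fitted = fitted_pts,
                 residuals = points - fitted_pts),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: order-%d polynomial in theta over [%.3f, %.3f] rad\n",
              x$order, x$theta_range[1], x$theta_range[2]))
  cat(sprintf("  %d points, arc length %.1f um, AV canal at the %s end\n",
              nrow(x$points), max(x$arc_length), x$av_end))
  cat(sprintf("  RMS residual %.3g um per coordinate\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.centerline <- function(object, ...) object$coefficients

#' @rdname fit_centerline
#' @param object a `centerline`.
#' @param ... unused.
#' @export
predict.centerline <- function(object, theta = NULL, ...) {
  theta <- theta %||% object$theta
  vander(theta, object$order) %*% object$coefficients
}

#' @export
fitted.centerline <- function(object, ...) object$fitted

#' @export
residuals.centerline <- function(object, ...) object$residuals

#' @export
plot.centerline <- function(x, ...) {
  d <- sweep(x$points, 2, x$center)
  a <- d %*% x$plane$e1; b <- d %*% x$plane$e2
  ds <- sweep(x$samples, 2, x$center)
  as <- ds %*% x$plane$e1; bs <- ds %*% x$plane$e2
  plot(a, b, pch = 16, cex = 0.5, col = "grey40",
       xlab = "in-plane a (um)", ylab = "in-plane b (um)",
       main = "flow centerline (principal-plane projection)", asp = 1, ...)
  lines(as, bs, col = "red3", lwd = 2)
  points(as[1], bs[1], pch = 17, col = "blue3")
  legend("topright", legend = c("tracers", "centerline", "AV canal end"),
         col = c("grey40", "red3", "blue3"), pch = c(16, NA, 17),
         lty = c(NA, 1, NA), bty = "n")
  invisible(x)
}

nearest_sample <- function(points, cl) {
  S <- cl$samples
  # chunked nearest-neighbor against the dense polyline
  n <- nrow(points)
  idx <- integer(n)
  step <- 20000L
  for (s in seq(1, n, by = step)) {
    e <- min(n, s + step - 1L)
    P <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rowSums(S^2), "+") - 2 * P %*% t(S)
    idx[s:e] <- max.col(-d2, ties.method = "first")
  }
  idx
}

# parallel-transported cross-section frames (u, w) along the dense samples
transported_frames <- function(cl) {
  Tg <- cl$tangents
  M <- nrow(Tg)
  U <- matrix(0, M, 3); W <- matrix(0, M, 3)
  u <- cross3(Tg[1, ], cl$plane$normal)
  u <- unit(u)
  for (i in seq_len(M)) {
    t <- Tg[i, ]
    u <- u - sum(u * t) * t
    u <- unit(u)
    U[i, ] <- u
    W[i, ] <- cross3(t, u)
  }
  list(u = U, w = W)
}

#' Mean projected flow velocity per frame
#'
#' Projects every per-cell velocity onto the unit tangent of the nearest
#' centerline point and averages the signed projections per frame: positive
#' values point from the AV canal toward the outflow tract. Frames with no
#' tracked cell are reported as `NA`, not zero.
#'
#' @param tracks a `track_set` with velocity columns (see
#'   [track_velocities()]).
#' @param centerline a fitted [fit_centerline()] object.
#' @return A `data.frame` with `frame` (0-based), `velocity` (um/s, signed)
#'   and `n_cells`.
#' @export
project_flow_velocity <- function(tracks, centerline) {
  if (!all(c("vz", "vy", "vx") %in% names(tracks)))
    stop("tracks carry no velocities; run track_velocities() first")
  tr <- as.data.frame(tracks)
  ok <- !is.na(tr$vz)
  tr <- tr[ok, , drop = FALSE]
  frames <- 0:max(c(tracks$frame, 0))
  out <- data.frame(frame = frames, velocity = NA_real_, n_cells = 0L)
  if (nrow(tr)) {
    P <- as.matrix(tr[, c("z", "y", "x")])
    V <- as.matrix(tr[, c("vz", "vy", "vx")])
    idx <- nearest_sample(P, centerline)
    proj <- rowSums(V * centerline$tangents[idx, , drop = FALSE])
    agg_m <- tapply(proj, tr$frame, mean)
    agg_n <- tapply(proj, tr$frame, length)
    f <- as.integer(names(agg_m))
    out$velocity[match(f, frames)] <- as.numeric(agg_m)
    out$n_cells[match(f, frames)] <- as.integer(agg_n)
  }
  out
}

#' Detect flow-reversal intervals
#'
#' Maximal contiguous runs of frames where the projected flow velocity is
#' negative with magnitude above a threshold (1000 um/s in the standard
#' analysis): retrograde flow across the valves at the end of systole and
#' diastole.
#'
#' @param series signed velocity per frame: a numeric vector or the
#'   `data.frame` from [project_flow_velocity()]. `NA` frames never count
#'   as reversal.
#' @param magnitude_threshold minimum reversal magnitude, um/s.
#' @return A `data.frame` with columns `start` and `end`: frame labels if
#'   the input has a `frame` column, else 1-based indices.
#' @export
detect_reversal <- function(series, magnitude_threshold = 1000) {
  if (is.data.frame(series)) {
    frames <- series$frame
    x <- series$velocity
  } else {
    frames <- seq_along(series)
    x <- as.numeric(series)
  }
  cond <- !is.na(x) & x < -abs(magnitude_threshold)
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = frames[starts[keep]], end = frames[ends[keep]])
}

#' Transform points into centerline-referenced coordinates
#'
#' Maps each point to the arc length of its nearest centerline sample and
#' its signed offsets along the two cross-section axes. The cross-section
#' frames are built by parallel transport of `tangent x plane-normal` along
#' the curve, so they never flip between neighboring samples.
#'
#' @param points n x 3 matrix `(z, y, x)`, micrometers.
#' @param centerline a [fit_centerline()] object.
#' @return A `data.frame` with `s` (arc length), `u`, `w` (signed offsets,
#'   micrometers) and `index` (nearest dense sample).
#' @export
to_centerline_coords <- function(points, centerline) {
  points <- as.matrix(points)
  fr <- transported_frames(centerline)
  S <- centerline$samples
  arc <- centerline$arc_length
  M <- nrow(S)
  idx <- nearest_sample(points, centerline)
  n <- nrow(points)
  s <- u <- w <- numeric(n)
  for (i in seq_len(n)) {
    # project onto the polyline segments adjacent to the nearest sample so
    # the tangential residual vanishes and the round trip is exact up to
    # the curvature of one segment
    j <- idx[i]
    best <- c(Inf, j, 0)
    for (j0 in unique(pmax(1L, pmin(M - 1L, c(j - 1L, j))))) {
      seg <- S[j0 + 1L, ] - S[j0, ]
      L2 <- sum(seg^2)
      tpar <- if (L2 > 0) sum((points[i, ] - S[j0, ]) * seg) / L2 else 0
      tpar <- max(0, min(1, tpar))
      p <- S[j0, ] + tpar * seg
      d2 <- sum((points[i, ] - p)^2)
      if (d2 < best[1]) best <- c(d2, j0, tpar)
    }
    j0 <- best[2]; tpar <- best[3]
    s[i] <- arc[j0] * (1 - tpar) + arc[j0 + 1L] * tpar
    ui <- fr$u[j0, ] * (1 - tpar) + fr$u[j0 + 1L, ] * tpar
    wi <- fr$w[j0, ] * (1 - tpar) + fr$w[j0 + 1L, ] * tpar
    p0 <- S[j0, ] * (1 - tpar) + S[j0 + 1L, ] * tpar
    d <- points[i, ] - p0
    u[i] <- sum(d * ui)
    w[i] <- sum(d * wi)
  }
  data.frame(s = s, u = u, w = w, index = idx)
}

#' Back-transform centerline coordinates to world positions
#'
#' Inverse of [to_centerline_coords()]: reconstructs
#' `sample(s) + u * U(s) + w * W(s)` using the same parallel-transported
#' frames, interpolating the curve at the requested arc length.
#'
#' @param coords `data.frame` with `s`, `u`, `w` (as returned by
#'   [to_centerline_coords()]).
#' @param centerline a [fit_centerline()] object.
#' @return n x 3 matrix of positions, micrometers.
#' @export
from_centerline_coords <- function(coords, centerline) {
  fr <- transported_frames(centerline)
  arc <- centerline$arc_length
  S <- centerline$samples
  M <- nrow(S)
  n <- length(coords$s)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- min(max(coords$s[i], arc[1]), arc[M])
    j0 <- max(1L, min(M - 1L, findInterval(s, arc)))
    tpar <- if (arc[j0 + 1L] > arc[j0]) (s - arc[j0]) / (arc[j0 + 1L] - arc[j0]) else 0
    p0 <- S[j0, ] * (1 - tpar) + S[j0 + 1L, ] * tpar
    ui <- fr$u[j0, ] * (1 - tpar) + fr$u[j0 + 1L, ] * tpar
    wi <- fr$w[j0, ] * (1 - tpar) + fr$w[j0 + 1L, ] * tpar
    out[i, ] <- p0 + coords$u[i] * ui + coords$w[i] * wi
  }
  out
}

#' Ventricle mask around the flow centerline
#'
#' The ventricular region is defined as all voxels within a given radius of
#' the flow centerline.
#'
#' @param centerline a [fit_centerline()] object.
#' @param dim voxel grid `(Z, Y, X)`.
#' @param spacing_um voxel spacing `(z, y, x)`, micrometers.
#' @param radius_um mask radius in micrometers.
#' @return Logical `(Z, Y, X)` array.
#' @export
centerline_mask <- function(centerline, dim, spacing_um, radius_um = 30) {
  spacing_um <- rep_len(spacing_um, 3L)
  g <- expand.grid(z = (seq_len(dim[1]) - 1) * spacing_um[1],
                   y = (seq_len(dim[2]) - 1) * spacing_um[2],
                   x = (seq_len(dim[3]) - 1) * spacing_um[3])
  P <- as.matrix(g)
  S <- centerline$samples
  n <- nrow(P)
  near <- logical(n)
  step <- 20000L
  r2 <- radius_um^2
  for (s in seq(1, n, by = step)) {
    e <- min(n, s + step - 1L)
    d2 <- outer(rowSums(P[s:e, , drop = FALSE]^2), rowSums(S^2), "+") -
      2 * P[s:e, , drop = FALSE] %*% t(S)
    near[s:e] <- apply(d2, 1, min) <= r2
  }
  array(near, dim = dim)
}

#' Partition the ventricle into centerline-referenced segments
#'
#' For the standard 4-segment analysis each voxel is classified as
#' proximal/distal by whether its nearest centerline arc length falls in
#' the first or last half of the curve, and left/right by the sign of its
#' offset along the lateral axis (`tangent x plane-normal`, parallel
#' transported for consistent handedness). For general even `n`, the arc
#' length is split into `n/2` equal bins times left/right. Segment labels
#' are `2*bin + 1` (left) and `2*bin + 2` (right), ordered from the AV
#' canal.
#'
#' @param x either a logical/numeric `(Z, Y, X)` mask array (requires
#'   `spacing_um`) or an n x 3 matrix of points in micrometers.
#' @param centerline a [fit_centerline()] object.
#' @param n_segments even number of segments.
#' @param spacing_um voxel spacing when `x` is an array.
#' @return Integer labels: an array of the mask's shape (0 outside the
#'   mask) or a vector for point input.
#' @export
partition_segments <- function(x, centerline, n_segments = 4L, spacing_um = NULL) {
  if (n_segments %% 2 != 0 || n_segments < 2)
    stop("n_segments must be even: segments pair left/right about the centerline")
  half <- n_segments %/% 2L
  is_array <- !is.null(dim(x)) && length(dim(x)) == 3
  if (is_array) {
    if (is.null(spacing_um)) stop("spacing_um is required for mask input")
    spacing_um <- rep_len(spacing_um, 3L)
    sel <- which(x != 0)
    d <- dim(x)
    ai <- arrayInd(sel, d)
    P <- sweep(ai - 1, 2, spacing_um, "*")
  } else {
    P <- as.matrix(x)
  }
  fr <- transported_frames(centerline)
  idx <- nearest_sample(P, centerline)
  arc <- centerline$arc_length
  frac <- arc[idx] / arc[length(arc)]
  bin <- pmin(floor(frac * half), half - 1L)
  dvec <- P - centerline$samples[idx, , drop = FALSE]
  lat <- rowSums(dvec * fr$u[idx, , drop = FALSE])
  lab <- as.integer(2L * bin + ifelse(lat >= 0, 1L, 2L))
  if (is_array) {
    out <- array(0L, dim = dim(x))
    out[sel] <- lab
    out
  } else lab
}

#' Segmental statistics of a set of velocity vectors
#'
#' Core per-frame summary: for each segment the voxel count, the unweighted
#' mean vector, the magnitude-weighted mean vector
#' `sum(|v| v) / sum(|v|)`, and the mean magnitude; globally the mean
#' magnitude over all labeled voxels; and the relative velocity
#' (segment mean magnitude / global mean magnitude). Empty segments yield
#' `NA` statistics.
#'
#' @param v n x 3 matrix of velocity vectors (um/s).
#' @param labels integer segment label per row (> 0).
#' @param n_segments number of segments; default `max(labels)`.
#' @return A `data.frame`, one row per segment.
#' @export
segment_vector_stats <- function(v, labels, n_segments = NULL) {
  v <- as.matrix(v)
  labels <- as.integer(labels)
  if (nrow(v) != length(labels)) stop("one label per vector required")
  n_segments <- n_segments %||% max(labels, 1L)
  mag <- row_norms(v)
  global <- mean(mag)
  out <- lapply(seq_len(n_segments), function(k) {
    i <- labels == k
    n <- sum(i)
    if (n == 0) {
      return(data.frame(segment = k, n_vox = 0L,
                        mean_vz = NA_real_, mean_vy = NA_real_, mean_vx = NA_real_,
                        wmean_vz = NA_real_, wmean_vy = NA_real_, wmean_vx = NA_real_,
                        mean_mag = NA_real_, global_mag = global, rel_velocity = NA_real_))
    }
    vi <- v[i, , drop = FALSE]
    mi <- mag[i]
    mv <- colMeans(vi)
    sw <- sum(mi)
    wv <- if (sw > 0) colSums(vi * mi) / sw else c(0, 0, 0)
    data.frame(segment = k, n_vox = n,
               mean_vz = mv[1], mean_vy = mv[2], mean_vx = mv[3],
               wmean_vz = wv[1], wmean_vy = wv[2], wmean_vx = wv[3],
               mean_mag = mean(mi), global_mag = global,
               rel_velocity = mean(mi) / global)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-frame segmental wall-motion statistics
#'
#' Applies [segment_vector_stats()] to every frame of a velocity field,
#' using a segment label volume from [partition_segments()]. The
#' magnitude-weighted mean vector is the default reported segmental
#' velocity; the unweighted mean vector is returned alongside because both
#' estimators are in common use (see the package vignette).
#'
#' @param vf a [vector_field4d()].
#' @param labels integer `(Z, Y, X)` label array covering the field's mask.
#' @return A `data.frame` of class `segment_stats` with one row per frame
#'   and segment.
#' @export
segment_statistics <- function(vf, labels) {
  stopifnot(inherits(vf, "vector_field4d"))
  if (!identical(dim(labels), dim(vf$v)[2:4]))
    stop("label volume shape must match the field")
  if (!is.null(vf$mask) && any(vf$mask & labels == 0))
    stop("labels do not cover the field's mask")
  sel <- which(labels > 0)
  lab <- labels[sel]
  nseg <- max(lab)
  T <- dim(vf$v)[1]
  nvox <- prod(dim(vf$v)[2:4])
  out <- vector("list", T)
  for (t in seq_len(T)) {
    vt <- matrix(vf$v[t, , , , ], nrow = nvox)[sel, , drop = FALSE]
    st <- segment_vector_stats(vt, lab, nseg)
    out[[t]] <- cbind(frame = t - 1L, st)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("segment_stats", "data.frame")
  out
}

#' Default systole/diastole windows from the projected flow
#'
#' Splits the cycle at the sign changes of the mean projected flow
#' velocity: the longest contiguous run of forward (positive) flow is
#' labeled one phase window and the remaining frames the other. Intended
#' as a default when no physiological annotation is supplied.
#'
#' @param series numeric velocity per frame or the `data.frame` from
#'   [project_flow_velocity()].
#' @return A list with integer frame positions `systole` and `diastole`
#'   (1-based positions in the series).
#' @export
phase_windows <- function(series) {
  x <- if (is.data.frame(series)) series$velocity else as.numeric(series)
  n <- length(x)
  pos <- !is.na(x) & x > 0
  # longest positive run with circular wrap
  pp <- rep(pos, 2)
  r <- rle(pp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths == max(r$lengths[r$values]))
  if (!length(cand)) return(list(systole = integer(), diastole = seq_len(n)))
  s <- starts[cand[1]]
  idx <- ((s:(s + r$lengths[cand[1]] - 1L) - 1L) %% n) + 1L
  idx <- unique(idx)
  list(systole = sort(idx), diastole = setdiff(seq_len(n), idx))
}

#' Cycle-level relative segmental velocity by cardiac phase
#'
#' Averages the per-frame relative velocity (segment mean magnitude over
#' global mean magnitude) within user-declared systole and diastole frame
#' windows, the quantity used to compare segmental contraction and
#' relaxation across hearts.
#'
#' @param stats a `segment_stats` from [segment_statistics()].
#' @param systole,diastole integer vectors of 0-based frame indices.
#' @return A `data.frame` with `segment`, `phase` and `rel_velocity`.
#' @export
relative_velocity_by_phase <- function(stats, systole, diastole) {
  agg <- function(frames, name) {
    sub <- stats[stats$frame %in% frames, , drop = FALSE]
    m <- tapply(sub$rel_velocity, sub$segment, mean, na.rm = TRUE)
    data.frame(segment = as.integer(names(m)), phase = name,
               rel_velocity = as.numeric(m))
  }
  out <- rbind(agg(systole, "systole"), agg(diastole, "diastole"))
  rownames(out) <- NULL
  out
}
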