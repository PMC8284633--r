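#' Resample a volume series to isotropic spacing and remove background
#'
#' Linearly resamples every frame to an isotropic target spacing (2 um by
#' default, the working resolution of the registration and tracking stages)
#' and zeroes voxels below an intensity threshold. When no threshold is
#' given, Otsu's method on the pooled intensity histogram is used.
#'
#' @param v a [volume4d()].
#' @param intensity_threshold background threshold; `NULL` for Otsu.
#' @param target_um isotropic output spacing in micrometers.
#' @return A [volume4d()] at isotropic spacing with background zeroed.
#' @export
preprocess_volume <- function(v, intensity_threshold = NULL, target_um = 2) {
  stopifnot(inherits(v, "volume4d"))
  if (any(v$spacing <= 0)) stop("voxel spacing must be positive")
  T <- n_frames(v)
  f1 <- resample_iso(get_frame(v, 1), v$spacing, target_um)
  out <- array(0, dim = c(T, dim(f1)))
  out[1, , , ] <- f1
  if (T > 1) for (t in 2:T) out[t, , , ] <- resample_iso(get_frame(v, t), v$spacing, target_um)
  if (is.null(intensity_threshold)) intensity_threshold <- otsu_threshold(out)
  out[out < intensity_threshold] <- 0
  volume4d(out, rep(target_um, 3), v$frame_interval, v$phase_origin)
}

otsu_threshold <- function(x) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("EBImage is required for automatic Otsu thresholding; pass intensity_threshold")
  rg <- range(x)
  if (diff(rg) == 0) return(rg[1])
  EBImage::otsu(matrix(as.numeric(x)), range = rg)
}

downsample2 <- function(vol) {
  d <- dim(vol)
  vol <- blur3(vol, 1)
  vol[seq(1, d[1], by = 2), seq(1, d[2], by = 2), seq(1, d[3], by = 2), drop = FALSE]
}

upsample_field2 <- function(field, newdim) {
  out <- array(0, dim = c(newdim, 3))
  zq <- (seq_len(newdim[1]) - 1) / 2
  yq <- (seq_len(newdim[2]) - 1) / 2
  xq <- (seq_len(newdim[3]) - 1) / 2
  g <- expand.grid(z = zq, y = yq, x = xq)
  for (k in 1:3)
    out[, , , k] <- 2 * array(trilinear(field[, , , k], g$z, g$y, g$x), dim = newdim)
  out
}

#' Demons deformable registration between two volumes
#'
#' Classic (Thirion) demons: an intensity-driven displacement update
#' proportional to the local mismatch and the fixed-image gradient is
#' accumulated at every voxel and the field is Gaussian-regularized after
#' each iteration. The registration runs coarse to fine over an image
#' pyramid (downsampling factor 2 per level) with the given iteration
#' counts, 100/50/25 from coarsest to finest by default.
#'
#' The returned field maps reference-frame voxel positions to their
#' positions in the moving frame, i.e. the transformation
#' `T: (x, y, z) -> (x', y', z')`, read as the motion of material located at
#' the reference frame.
#'
#' @param reference,moving numeric 3-D `(z, y, x)` arrays of equal shape on
#'   an isotropic grid.
#' @param iterations iterations per pyramid level, coarsest first; the
#'   number of levels is `length(iterations)`.
#' @param smoothing_sigma Gaussian regularization sigma in voxels.
#' @param spacing_um isotropic voxel spacing; the output field is in
#'   micrometers.
#' @param from,to frame indices recorded on the result (metadata only).
#' @return An object of class `displacement_field`: `field` is a
#'   `(Z, Y, X, 3)` array of `(dz, dy, dx)` displacements in micrometers.
#' @export
demons_register <- function(reference, moving, iterations = c(100, 50, 25),
                            smoothing_sigma = 1.5, spacing_um = 2,
                            from = NA_integer_, to = NA_integer_) {
  if (!identical(dim(reference), dim(moving)))
    stop("reference and moving volumes must have equal shapes")
  n_levels <- length(iterations)
  pyr_f <- list(reference)
  pyr_m <- list(moving)
  if (n_levels > 1) for (l in 2:n_levels) {
    pyr_f[[l]] <- downsample2(pyr_f[[l - 1]])
    pyr_m[[l]] <- downsample2(pyr_m[[l - 1]])
  }
  field <- NULL
  for (l in n_levels:1) {  # coarse -> fine
    dl <- dim(pyr_f[[l]])
    field <- if (is.null(field)) array(0, dim = c(dl, 3)) else upsample_field2(field, dl)
    res <- cpp_demons_level(as.double(pyr_f[[l]]), as.double(pyr_m[[l]]),
                            as.integer(dl), as.double(field),
                            as.integer(iterations[n_levels - l + 1]),
                            smoothing_sigma, as.integer(l))
    field <- array(res, dim = c(dl, 3))
  }
  structure(list(field = field * spacing_um, from = from, to = to,
                 spacing = rep(spacing_um, 3)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mg <- sqrt(x$field[, , , 1]^2 + x$field[, , , 2]^2 + x$field[, , , 3]^2)
  cat(sprintf("displacement_field: %s voxels, |d| max %.3g um (frames %s -> %s)\n",
              paste(dim(x$field)[1:3], collapse = " x "), max(mg), x$from, x$to))
  invisible(x)
}

#' Convert per-frame displacement fields to a velocity field series
#'
#' Divides each inter-frame displacement by the frame interval and masks the
#' result to the ventricular region. The field list is expected to cover one
#' full cycle with the last pair wrapping back to the first frame, so every
#' frame carries a velocity.
#'
#' @param fields list of `displacement_field`s for consecutive frame pairs.
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param mask logical `(Z, Y, X)` ventricle mask, or `NULL`.
#' @return A [vector_field4d()] in micrometers per second.
#' @export
displacement_to_velocity <- function(fields, frame_interval_s, mask = NULL) {
  if (frame_interval_s <= 0) stop("frame interval must be positive")
  T <- length(fields)
  d <- dim(fields[[1]]$field)
  v <- array(0, dim = c(T, d))
  for (t in seq_len(T)) v[t, , , , ] <- fields[[t]]$field / frame_interval_s
  vector_field4d(v, mask, fields[[1]]$spacing, frame_interval_s)
}

#' Temporal smoothing of a velocity field over the cardiac cycle
#'
#' Per-voxel, per-component circular moving average: time wraps around the
#' cycle, so the per-voxel cycle mean is conserved exactly. A 7-frame window
#' (30 ms at 200 Hz) keeps successive maps smooth.
#'
#' @param vf a [vector_field4d()] covering one cycle.
#' @param window odd window length in frames, at most the cycle length.
#' @return The smoothed [vector_field4d()].
#' @export
smooth_temporal <- function(vf, window = 7L) {
  stopifnot(inherits(vf, "vector_field4d"))
  stopifnot_odd(window, "temporal window")
  T <- dim(vf$v)[1]
  if (window > T) stop("window exceeds the cycle length")
  if (window == 1) return(vf)
  hw <- (window - 1L) %/% 2L
  out <- array(0, dim = dim(vf$v))
  for (off in -hw:hw) {
    idx <- ((seq_len(T) - 1 + off) %% T) + 1
    out <- out + vf$v[idx, , , , , drop = FALSE]
  }
  vf$v <- out / window
  vf
}

shift_spatial <- function(a, axis, by, fill = 0) {
  # shift an array along one of its axes, padding with `fill`
  d <- dim(a)
  idx <- rep(list(quote(expr = )), length(d))
  src <- seq_len(d[axis]) + by
  ok <- src >= 1 & src <= d[axis]
  out <- array(fill, dim = d)
  if (!any(ok)) return(out)
  idx_to <- idx; idx_to[[axis]] <- which(ok)
  idx_from <- idx; idx_from[[axis]] <- src[ok]
  out_call <- as.call(c(quote(`[<-`), quote(out), idx_to,
                        as.call(c(quote(`[`), quote(a), idx_from))))
  eval(out_call)
}

#' Spatial gradients of a velocity field
#'
#' Central finite differences of each velocity component along each spatial
#' axis (units 1/s), falling back to one-sided differences at the borders of
#' the region mask so gradients never mix masked and unmasked voxels.
#'
#' @param vf a [vector_field4d()].
#' @return A `(T, Z, Y, X, 3, 3)` array: component x differentiation axis.
#' @export
velocity_gradient <- function(vf) {
  stopifnot(inherits(vf, "vector_field4d"))
  v <- vf$v
  d <- dim(v)
  mask <- vf$mask %||% array(TRUE, d[2:4])
  G <- array(0, dim = c(d, 3))
  mnum <- array(as.numeric(mask), dim = dim(mask))
  for (ax in 1:3) {
    sp <- vf$spacing[ax]
    vp <- shift_spatial(v, ax + 1, 1)   # value at i+1
    vm <- shift_spatial(v, ax + 1, -1)  # value at i-1
    okp <- shift_spatial(mnum, ax, 1)   # neighbor i+1 inside mask
    okm <- shift_spatial(mnum, ax, -1)
    # broadcast the (Z,Y,X) validity over time and components
    okp5 <- aperm(array(okp, dim = c(d[2:4], d[1], d[5])), c(4, 1, 2, 3, 5))
    okm5 <- aperm(array(okm, dim = c(d[2:4], d[1], d[5])), c(4, 1, 2, 3, 5))
    hi <- vp * okp5 + v * (1 - okp5)
    lo <- vm * okm5 + v * (1 - okm5)
    steps <- okp5 + okm5
    g <- array(0, dim = d)
    nz <- steps > 0
    g[nz] <- (hi[nz] - lo[nz]) / (steps[nz] * sp)
    m5 <- aperm(array(mnum, dim = c(d[2:4], d[1], d[5])), c(4, 1, 2, 3, 5))
    G[, , , , , ax] <- g * m5
  }
  G
}

#' Voxel-wise speed map
#'
#' Euclidean norm of the velocity at every voxel and frame, the quantity
#' shown as segmental wall-motion heatmaps.
#'
#' @param vf a [vector_field4d()].
#' @return A `(T, Z, Y, X)` array in micrometers per second.
#' @export
speed_heatmap <- function(vf) {
  stopifnot(inherits(vf, "vector_field4d"))
  d <- dim(vf$v)
  array(sqrt(rowSums(matrix(vf$v, ncol = 3)^2)), dim = d[1:4])
}

#' Kymograph deformation rate versus vector-field deformation rate
#'
#' Samples the intensity along a fixed line for every frame (the
#' kymograph), locates the two outer wall boundaries by threshold crossing,
#' and differentiates the boundary distance in time to get the
#' kymograph-based deformation rate. In parallel, the velocity field is
#' sampled at the two boundary points and the difference of the two
#' velocities projected on the line gives the vector-field deformation
#' rate. A line tilted away from the local motion direction inflates the
#' kymograph rate by about `1/cos(tilt)` while the projected vector-field
#' rate does not, which is the angle dependence this cross-check exposes.
#'
#' @param v4d a [volume4d()] (one cardiac cycle).
#' @param line 2 x 3 matrix of line endpoints in micrometers `(z, y, x)`.
#' @param vf the matching [vector_field4d()].
#' @param n_samples intensity samples along the line.
#' @param threshold boundary threshold; default half the kymograph maximum.
#' @return A list with `kymograph` (T x n), `distance` (um per frame),
#'   `rate_kymograph` and `rate_vector_field` (um/s per frame, forward
#'   differences wrapping around the cycle) and `boundaries` (T x 2
#'   positions along the line, um).
#' @export
kymograph_deformation_rate <- function(v4d, line, vf, n_samples = 200L, threshold = NULL) {
  stopifnot(inherits(v4d, "volume4d"), inherits(vf, "vector_field4d"))
  line <- matrix(as.numeric(line), 2, 3)
  T <- n_frames(v4d)
  a <- line[1, ]; b <- line[2, ]
  lvec <- b - a
  llen <- sqrt(sum(lvec^2))
  lhat <- lvec / llen
  ds <- llen / (n_samples - 1)
  ss <- seq(0, llen, length.out = n_samples)
  pts <- outer(ss, lhat) + matrix(a, n_samples, 3, byrow = TRUE)

  kymo <- matrix(0, T, n_samples)
  for (t in seq_len(T)) {
    fr <- get_frame(v4d, t)
    kymo[t, ] <- trilinear(fr, pts[, 1] / v4d$spacing[1],
                           pts[, 2] / v4d$spacing[2], pts[, 3] / v4d$spacing[3])
  }
  if (is.null(threshold)) threshold <- 0.5 * max(kymo)

  bounds <- matrix(NA_real_, T, 2)
  for (t in seq_len(T)) {
    prof <- kymo[t, ]
    above <- prof >= threshold
    if (!any(above)) stop(sprintf("frame %d: no wall crossing on the sampling line", t))
    i1 <- which(above)[1]
    i2 <- tail(which(above), 1)
    if (i1 == i2) stop(sprintf("frame %d: fewer than two boundary crossings", t))
    # sub-sample refinement of the outer edges by linear interpolation
    s1 <- if (i1 > 1) (i1 - 1 - (prof[i1] - threshold) / (prof[i1] - prof[i1 - 1])) * ds
          else 0
    s2 <- if (i2 < n_samples) (i2 - 1 + (prof[i2] - threshold) / (prof[i2] - prof[i2 + 1])) * ds
          else llen
    bounds[t, ] <- c(s1, s2)
  }
  dist <- bounds[, 2] - bounds[, 1]
  dt <- v4d$frame_interval
  nxt <- c(2:T, 1)
  rate_kymo <- (dist[nxt] - dist) / dt

  rate_vf <- numeric(T)
  for (t in seq_len(T)) {
    p1 <- a + bounds[t, 1] * lhat
    p2 <- a + bounds[t, 2] * lhat
    v1 <- v2 <- numeric(3)
    for (k in 1:3) {
      v1[k] <- trilinear(array(vf$v[t, , , , k], dim = dim(vf$v)[2:4]),
                         p1[1] / vf$spacing[1], p1[2] / vf$spacing[2], p1[3] / vf$spacing[3])
      v2[k] <- trilinear(array(vf$v[t, , , , k], dim = dim(vf$v)[2:4]),
                         p2[1] / vf$spacing[1], p2[2] / vf$spacing[2], p2[3] / vf$spacing[3])
    }
    rate_vf[t] <- sum((v2 - v1) * lhat)
  }
  list(kymograph = kymo, distance = dist, rate_kymograph = rate_kymo,
       rate_vector_field = rate_vf, boundaries = bounds)
}
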