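#' Preprocess a tracer volume series for particle detection
#'
#' Resamples every frame to isotropic spacing and applies a Gaussian blur to
#' suppress reconstruction artifacts, optionally restricted to a region of
#' interest around the ventricle.
#'
#' @param v a [volume4d()].
#' @param sigma blur sigma in voxels of the resampled grid; 0 disables.
#' @param target_um isotropic output spacing in micrometers.
#' @param roi optional list of index ranges `list(z =, y =, x =)` (1-based,
#'   on the resampled grid) to crop to.
#' @return A [volume4d()].
#' @export
preprocess_particles <- function(v, sigma = 1, target_um = 2, roi = NULL) {
  stopifnot(inherits(v, "volume4d"))
  T <- n_frames(v)
  f1 <- resample_iso(get_frame(v, 1), v$spacing, target_um)
  out <- array(0, dim = c(T, dim(f1)))
  for (t in seq_len(T)) {
    fr <- if (t == 1) f1 else resample_iso(get_frame(v, t), v$spacing, target_um)
    if (sigma > 0) fr <- blur3(fr, sigma)
    out[t, , , ] <- fr
  }
  if (!is.null(roi)) out <- out[, roi$z, roi$y, roi$x, drop = FALSE]
  volume4d(out, rep(target_um, 3), v$frame_interval, v$phase_origin)
}

#' Detect tracer particles in a volume series
#'
#' Finds 26-connected local intensity maxima above a threshold, suppresses
#' maxima closer than `min_separation` to a brighter one, and refines each
#' position to sub-voxel accuracy by the intensity-weighted centroid of its
#' 3x3x3 neighborhood.
#'
#' @param v a preprocessed [volume4d()].
#' @param intensity_threshold absolute detection threshold.
#' @param min_separation minimum distance between detections, micrometers.
#' @return A `data.frame` (class `detection_table`) with columns `frame`
#'   (0-based), `z`, `y`, `x` (micrometers), `intensity` and `size`
#'   (RMS neighborhood radius, micrometers). May be empty.
#' @export
detect_particles <- function(v, intensity_threshold, min_separation = 6) {
  stopifnot(inherits(v, "volume4d"))
  T <- n_frames(v)
  sp <- v$spacing
  res <- vector("list", T)
  for (t in seq_len(T)) {
    fr <- get_frame(v, t)
    pk <- cpp_local_maxima(as.double(fr), as.integer(dim(fr)), intensity_threshold)
    if (nrow(pk) == 0) next
    inten <- fr[pk + 1L]
    ord <- order(inten, decreasing = TRUE)
    pos_um <- sweep(pk, 2, sp, "*")
    keep <- logical(nrow(pk))
    for (i in ord) {
      if (any(keep)) {
        dmin <- min(row_norms(sweep(pos_um[keep, , drop = FALSE], 2, pos_um[i, ])))
        if (dmin < min_separation) next
      }
      keep[i] <- TRUE
    }
    pk <- pk[keep, , drop = FALSE]
    inten <- inten[keep]
    n <- nrow(pk)
    cz <- cy <- cx <- sz <- numeric(n)
    d <- dim(fr)
    for (i in seq_len(n)) {
      z0 <- pk[i, 1]; y0 <- pk[i, 2]; x0 <- pk[i, 3]
      iz <- max(0, z0 - 1):min(d[1] - 1, z0 + 1)
      iy <- max(0, y0 - 1):min(d[2] - 1, y0 + 1)
      ix <- max(0, x0 - 1):min(d[3] - 1, x0 + 1)
      w <- fr[iz + 1, iy + 1, ix + 1, drop = FALSE]
      w <- pmax(w, 0)
      sw <- sum(w)
      g <- expand.grid(z = iz, y = iy, x = ix)
      cz[i] <- sum(g$z * w) / sw; cy[i] <- sum(g$y * w) / sw; cx[i] <- sum(g$x * w) / sw
      r2 <- (g$z - cz[i])^2 + (g$y - cy[i])^2 + (g$x - cx[i])^2
      sz[i] <- sqrt(sum(r2 * w) / sw) * mean(sp)
    }
    res[[t]] <- data.frame(frame = t - 1L, z = cz * sp[1], y = cy * sp[2], x = cx * sp[3],
                           intensity = inten, size = sz)
  }
  out <- do.call(rbind, res) %||% data.frame(frame = integer(), z = numeric(),
                                             y = numeric(), x = numeric(),
                                             intensity = numeric(), size = numeric())
  rownames(out) <- NULL
  class(out) <- c("detection_table", "data.frame")
  out
}

# minimum-cost bipartite matching with forbidden links; returns for each row
# the matched column index or NA. Costs >= `forbid` are never matched.
solve_assignment <- function(cost, forbid = 1e15, pad = 1e12) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  s <- max(n, m)
  sq <- matrix(pad, s, s)
  sq[seq_len(n), seq_len(m)] <- pmin(cost, forbid)
  a <- cpp_hungarian(sq)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- a[i]
    if (j <= m && sq[i, j] < pad) out[i] <- j
  }
  out
}

#' Link particle detections into trajectories
#'
#' Frame-to-frame assignment under an order-1 autoregressive (constant
#' velocity) motion model: each active track predicts its next position as
#' its last position plus its last inter-frame step (zero for new tracks),
#' candidate links farther than `max_displacement` from the prediction are
#' forbidden, and the per-frame assignment minimizes the total squared
#' prediction error via min-cost bipartite matching. Tracks missing from a
#' frame survive `max_gap` frames with the prediction carried forward, then
#' terminate.
#'
#' @param detections a `detection_table` from [detect_particles()].
#' @param max_displacement gating radius in micrometers; `NULL` uses 3x the
#'   median inter-frame nearest-neighbor step measured on the detections.
#' @param max_gap maximum number of consecutive missed frames bridged.
#' @return A `track_set`: a `data.frame` with `track_id`, `frame`, `z`,
#'   `y`, `x` (micrometers), ordered by track and frame, with the linking
#'   parameters in `attr(, "params")`.
#' @export
link_tracks <- function(detections, max_displacement = NULL, max_gap = 1L) {
  d <- as.data.frame(detections)
  if (nrow(d) == 0) {
    out <- data.frame(track_id = integer(), frame = integer(),
                      z = numeric(), y = numeric(), x = numeric())
    class(out) <- c("track_set", "data.frame")
    return(out)
  }
  d <- d[order(d$frame), , drop = FALSE]
  frames <- sort(unique(d$frame))

  if (is.null(max_displacement)) max_displacement <- default_gate(d, frames)

  next_id <- 1L
  active <- list()   # each: id, pos, vel (um/frame), last_frame, miss
  done <- list()
  rows <- list()

  for (f in frames) {
    det <- d[d$frame == f, , drop = FALSE]
    P <- as.matrix(det[, c("z", "y", "x")])
    # age predictions for frames skipped entirely and drop expired tracks
    if (length(active)) {
      keepers <- list()
      for (tr in active) {
        gap <- f - tr$last_frame - 1L
        if (gap > max_gap) done[[length(done) + 1L]] <- tr
        else keepers[[length(keepers) + 1L]] <- tr
      }
      active <- keepers
    }
    nA <- length(active)
    assigned_det <- rep(FALSE, nrow(det))
    if (nA > 0 && nrow(det) > 0) {
      pred <- t(vapply(active, function(tr)
        tr$pos + tr$vel * (f - tr$last_frame), numeric(3)))
      cost <- matrix(0, nA, nrow(det))
      for (i in seq_len(nA)) cost[i, ] <- rowSums(sweep(P, 2, pred[i, ])^2)
      cost[sqrt(cost) > max_displacement] <- 1e15
      match <- solve_assignment(cost)
      for (i in seq_len(nA)) {
        j <- match[i]
        if (!is.na(j)) {
          tr <- active[[i]]
          dt_f <- f - tr$last_frame
          tr$vel <- (P[j, ] - tr$pos) / dt_f
          tr$pos <- P[j, ]
          tr$last_frame <- f
          tr$miss <- 0L
          active[[i]] <- tr
          assigned_det[j] <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(track_id = tr$id, frame = f,
                                                  z = P[j, 1], y = P[j, 2], x = P[j, 3])
        } else {
          active[[i]]$miss <- active[[i]]$miss + 1L
        }
      }
    }
    for (j in which(!assigned_det)) {
      tr <- list(id = next_id, pos = P[j, ], vel = c(0, 0, 0), last_frame = f, miss = 0L)
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <- tr
      rows[[length(rows) + 1L]] <- data.frame(track_id = tr$id, frame = f,
                                              z = P[j, 1], y = P[j, 2], x = P[j, 3])
    }
  }

  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- list(max_displacement = max_displacement, max_gap = max_gap)
  class(out) <- c("track_set", "data.frame")
  out
}

default_gate <- function(d, frames) {
  steps <- c()
  for (k in seq_len(length(frames) - 1)) {
    A <- as.matrix(d[d$frame == frames[k], c("z", "y", "x"), drop = FALSE])
    B <- as.matrix(d[d$frame == frames[k + 1], c("z", "y", "x"), drop = FALSE])
    if (!nrow(A) || !nrow(B)) next
    for (i in seq_len(nrow(A)))
      steps <- c(steps, min(row_norms(sweep(B, 2, A[i, ]))))
  }
  if (!length(steps)) stop("cannot infer max_displacement from a single frame")
  3 * median(steps)
}

#' Remove short trajectories
#'
#' Drops tracks whose frame span (last - first + 1) is below a duration
#' threshold, the standard guard against spurious single-detection tracks.
#'
#' @param tracks a `track_set`.
#' @param min_duration minimum span in frames.
#' @return The filtered `track_set`.
#' @export
filter_tracks <- function(tracks, min_duration = 5L) {
  if (!nrow(tracks)) return(tracks)
  span <- tapply(tracks$frame, tracks$track_id, function(f) max(f) - min(f) + 1L)
  keep <- names(span)[span >= min_duration]
  out <- tracks[tracks$track_id %in% as.integer(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- attr(tracks, "params")
  class(out) <- class(tracks)
  out
}

#' Per-step track velocities
#'
#' For every consecutive pair of localizations within a track, the velocity
#' `delta position / (delta frames * frame interval)` is stored on the
#' earlier frame; the last localization of each track has `NA` velocity.
#'
#' @param tracks a `track_set`.
#' @param frame_interval_s frame interval in seconds (> 0).
#' @return The `track_set` with `vz`, `vy`, `vx` columns in micrometers
#'   per second.
#' @export
track_velocities <- function(tracks, frame_interval_s) {
  if (frame_interval_s <= 0) stop("frame interval must be positive")
  tr <- as.data.frame(tracks)
  tr <- tr[order(tr$track_id, tr$frame), , drop = FALSE]
  n <- nrow(tr)
  v <- matrix(NA_real_, n, 3)
  if (n > 1) {
    same <- tr$track_id[-1] == tr$track_id[-n]
    dt <- (tr$frame[-1] - tr$frame[-n]) * frame_interval_s
    dp <- as.matrix(tr[-1, c("z", "y", "x")]) - as.matrix(tr[-n, c("z", "y", "x")])
    idx <- which(same)
    v[idx, ] <- dp[idx, , drop = FALSE] / dt[idx]
  }
  tr$vz <- v[, 1]; tr$vy <- v[, 2]; tr$vx <- v[, 3]
  rownames(tr) <- NULL
  attr(tr, "params") <- attr(tracks, "params")
  attr(tr, "frame_interval") <- frame_interval_s
  class(tr) <- c("track_set", "data.frame")
  tr
}
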