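#' Estimate the cardiac period of an image time sequence
#'
#' Computes the temporal autocorrelation of the mean-subtracted,
#' frame-vectorized sequence (summed over pixels, evaluated by FFT) and
#' returns the lag of its first prominent peak, refined by parabolic
#' interpolation. The peak prominence (peak height minus the deepest valley
#' preceding it, on the normalized autocorrelation) is returned as a
#' confidence score.
#'
#' @param seq numeric `(T, Y, X)` array covering at least two cardiac cycles.
#' @param min_lag smallest lag (frames) considered a plausible period.
#' @param prominence_threshold minimum peak prominence; below it the input
#'   is declared aperiodic.
#' @return A list with `period` (frames, real-valued), `confidence`
#'   (prominence) and `acf` (the normalized autocorrelation by lag).
#' @export
estimate_period <- function(seq, min_lag = 4L, prominence_threshold = 0.2) {
  d <- dim(seq)
  if (length(d) != 3) stop("seq must be a (t, y, x) array")
  T <- d[1]
  M <- matrix(seq, nrow = T)
  M <- sweep(M, 2, colMeans(M))
  if (sum(M^2) < 1e-12 * length(M))
    stop("aperiodic input: sequence has (near) zero temporal variance")
  # summed per-pixel linear autocovariance: lag-tau mean of the frame Gram
  # matrix superdiagonals (one BLAS product, cheap diagonals)
  G <- tcrossprod(M)
  r <- vapply(seq_len(T) - 1L, function(tau) {
    i <- seq_len(T - tau)
    mean(G[cbind(i, i + tau)])
  }, numeric(1))
  rho <- r / r[1]

  lags <- seq_len(T) - 1L
  lo <- max(min_lag, 2L)
  peak <- NA_integer_
  prom <- 0
  for (tau in lo:(T - 2L)) {
    i <- tau + 1L
    if (rho[i] >= rho[i - 1] && rho[i] > rho[i + 1]) {
      p <- rho[i] - min(rho[2:i])
      if (p >= prominence_threshold) { peak <- tau; prom <- p; break }
    }
  }
  if (is.na(peak))
    stop("aperiodic input: no autocorrelation peak above the prominence threshold")
  i <- peak + 1L
  denom <- rho[i - 1] - 2 * rho[i] + rho[i + 1]
  delta <- if (abs(denom) > 1e-12) 0.5 * (rho[i - 1] - rho[i + 1]) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  list(period = peak + delta, confidence = prom, acf = rho)
}

normalize_seq <- function(s) {
  m <- mean(s)
  if (m > 1e-12) s / m else s
}

# frame-pair distance matrix over one period: G[t, u] = ||A_t - B_u||_2
frame_distance_matrix <- function(A, B, L) {
  MA <- matrix(A[seq_len(L), , ], nrow = L)
  MB <- matrix(B[seq_len(L), , ], nrow = L)
  a2 <- rowSums(MA^2)
  b2 <- rowSums(MB^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(MA, MB)
  sqrt(pmax(d2, 0))
}

#' Pixel-wise Euclidean distance between two sequences at a circular shift
#'
#' `D(s) = sum_t ||A_t - B_((t+s) mod L)||_2` over a window of one rounded
#' period `L`, with `B` indexed circularly within its first `L` frames. Both
#' sequences are divided by their mean intensity first (disable with
#' `normalize = FALSE`), which removes per-slice illumination differences.
#'
#' @param seqA,seqB numeric `(T, Y, X)` arrays with equal in-plane shape and
#'   at least `round(period)` frames.
#' @param shift circular shift in frames; reduced modulo `L`.
#' @param period cardiac period in frames (real); the window is `round(period)`.
#' @param normalize divide each sequence by its mean intensity first.
#' @return Nonnegative distance value.
#' @export
sequence_distance <- function(seqA, seqB, shift, period, normalize = TRUE) {
  L <- as.integer(round(period))
  if (!identical(dim(seqA)[2:3], dim(seqB)[2:3]))
    stop("sequences must share the in-plane shape")
  if (dim(seqA)[1] < L || dim(seqB)[1] < L)
    stop("sequences must cover at least one period")
  if (normalize) { seqA <- normalize_seq(seqA); seqB <- normalize_seq(seqB) }
  s <- ((shift %% L) + L) %% L
  ia <- seq_len(L)
  ib <- ((ia - 1 + s) %% L) + 1
  MA <- matrix(seqA[ia, , ], nrow = L)
  MB <- matrix(seqB[ib, , ], nrow = L)
  sum(sqrt(pmax(rowSums((MA - MB)^2), 0)))
}

#' Estimate the relative cardiac-phase shift between two sequences
#'
#' Minimizes the one-period circular distance profile `D(s)` over all
#' integer shifts `s` in `[0, round(period))`; ties break toward the
#' smallest shift. The full profile is attached for diagnostics.
#'
#' @inheritParams sequence_distance
#' @param tol relative flatness tolerance: if
#'   `max(D) - min(D) <= tol * max(D)` the phases are indistinguishable.
#' @return A list with `shift` (integer frames), `profile` (distance per
#'   shift) and `distance` (the minimized value).
#' @export
estimate_relative_shift <- function(seqA, seqB, period, normalize = TRUE, tol = 1e-8) {
  L <- as.integer(round(period))
  if (!identical(dim(seqA)[2:3], dim(seqB)[2:3]))
    stop("sequences must share the in-plane shape")
  if (dim(seqA)[1] < L || dim(seqB)[1] < L)
    stop("sequences must cover at least one period")
  if (normalize) { seqA <- normalize_seq(seqA); seqB <- normalize_seq(seqB) }
  G <- frame_distance_matrix(seqA, seqB, L)
  prof <- vapply(seq_len(L) - 1L, function(s) {
    sum(G[cbind(seq_len(L), ((seq_len(L) - 1 + s) %% L) + 1)])
  }, numeric(1))
  if (max(prof) - min(prof) <= tol * max(max(prof), 1e-300))
    stop("indistinguishable phases: flat distance profile")
  s <- which.min(prof) - 1L   # which.min returns the first (smallest) minimum
  list(shift = s, profile = prof, distance = prof[s + 1L])
}

#' Retrospectively synchronize a slice scan into a 4-D volume series
#'
#' Estimates the cardiac period per slice (pooled by median), then the
#' relative phase shift between each pair of adjacent z slices, accumulates
#' the pairwise shifts (modulo the period) so every slice is aligned to the
#' phase of slice 1, circularly rolls each sequence by its accumulated
#' shift, crops to one period and stacks the result into `(time, z, y, x)`.
#'
#' @param scan a [slice_scan()] with at least two slices.
#' @param prominence_threshold forwarded to [estimate_period()].
#' @return A list with `volume` (a [volume4d()]) and `sync` (a
#'   `sync_result`: pooled `period`, `period_per_slice`, per-slice
#'   accumulated `shifts`, adjacent `pair_shifts`, distance `profiles` and
#'   period `confidence` scores).
#' @export
synchronize_scan <- function(scan, prominence_threshold = 0.2) {
  stopifnot(inherits(scan, "slice_scan"))
  K <- length(scan$sequences)
  if (K < 2) stop("at least two slices are required")

  # per-slice period estimates; weak-signal slices may fail and are excluded
  # from the median pool (that is what the median is for)
  per <- vapply(scan$sequences, function(s) {
    est <- tryCatch(estimate_period(s, prominence_threshold = prominence_threshold),
                    error = function(e) list(period = NA_real_, confidence = NA_real_))
    c(est$period, est$confidence)
  }, numeric(2))
  if (all(is.na(per[1, ])))
    stop("aperiodic input: period estimation failed on every slice")
  period <- median(per[1, ], na.rm = TRUE)
  L <- as.integer(round(period))

  pair_shifts <- integer(K - 1)
  profiles <- vector("list", K - 1)
  for (k in 2:K) {
    est <- tryCatch(
      estimate_relative_shift(scan$sequences[[k - 1]], scan$sequences[[k]], period),
      error = function(e) stop(sprintf("slices %d-%d: %s", k - 1, k, conditionMessage(e)),
                               call. = FALSE))
    pair_shifts[k - 1] <- est$shift
    profiles[[k - 1]] <- est$profile
  }
  shifts <- c(0L, cumsum(pair_shifts) %% L)

  d2 <- dim(scan$sequences[[1]])[2:3]
  out <- array(0, dim = c(L, K, d2))
  for (k in seq_len(K)) out[, k, , ] <- roll_frames(scan$sequences[[k]], shifts[k], L)

  zs <- diff(scan$z_um)
  spacing <- c(if (length(zs)) median(zs) else scan$pixel_um, scan$pixel_um, scan$pixel_um)
  sync <- structure(list(period = period, period_per_slice = per[1, ],
                         confidence = per[2, ], shifts = shifts,
                         pair_shifts = pair_shifts, profiles = profiles),
                    class = "sync_result")
  list(volume = volume4d(out, spacing, 1 / scan$fps, phase_origin = 0L), sync = sync)
}

#' Assign cardiac phases to concurrently acquired frames via time stamps
#'
#' Maps each target frame time to a cardiac phase in `[0, 1)` using the
#' synchronized reference sequence's phase origin and the common acquisition
#' clock: frames of a second modality recorded simultaneously with the
#' reference slice inherit its phase indirectly through the time stamps.
#'
#' @param reference_seq the synchronized reference `(T, Y, X)` sequence
#'   (defines the admissible time span).
#' @param target_frame_times times of the target frames in seconds, on the
#'   same clock that starts at the reference sequence's first frame.
#' @param sync a `sync_result` from [synchronize_scan()].
#' @param fps shared frame rate in Hz.
#' @param phase_origin frame index (0-based) of the reference sequence at
#'   cardiac phase 0.
#' @return Numeric vector of phases in `[0, 1)`.
#' @export
assign_phases_by_timestamp <- function(reference_seq, target_frame_times, sync, fps,
                                       phase_origin = 0L) {
  T <- dim(reference_seq)[1]
  span <- (T - 1) / fps
  if (any(target_frame_times < 0 | target_frame_times > span))
    stop("target times fall outside the reference sequence span")
  period_s <- sync$period / fps
  ph <- ((target_frame_times - phase_origin / fps) / period_s) %% 1
  ph %% 1
}
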