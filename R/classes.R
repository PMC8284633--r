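#' Phase-synchronized 4-D image series
#'
#' Container for an intensity series indexed `(time, z, y, x)` with physical
#' voxel spacing and frame timing. This is the common currency between the
#' gating, registration and tracking stages.
#'
#' @param data numeric 4-D array with dim `(T, Z, Y, X)`.
#' @param spacing_um voxel spacing in micrometers, length-3 `(z, y, x)`.
#' @param frame_interval_s time between consecutive frames in seconds.
#' @param phase_origin frame index (0-based) defining cardiac phase 0.
#' @return An object of class `volume4d` with fields `data`, `spacing`,
#'   `frame_interval` and `phase_origin`.
#' @export
volume4d <- function(data, spacing_um, frame_interval_s, phase_origin = 0L) {
  if (length(dim(data)) != 4) stop("data must be a 4-D (t, z, y, x) array")
  spacing_um <- rep_len(as.numeric(spacing_um), 3L)
  if (any(spacing_um <= 0)) stop("voxel spacing must be positive")
  if (frame_interval_s <= 0) stop("frame interval must be positive")
  structure(list(data = data, spacing = spacing_um,
                 frame_interval = frame_interval_s,
                 phase_origin = as.integer(phase_origin)),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume4d: %d frames of %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s um, frame interval %.4g s (%.4g fps)\n",
              paste(signif(x$spacing, 4), collapse = " x "),
              x$frame_interval, 1 / x$frame_interval))
  invisible(x)
}

n_frames <- function(v) dim(v$data)[1]

get_frame <- function(v, t) {
  d <- dim(v$data)
  array(v$data[t, , , ], dim = d[2:4])
}

#' Per-slice image time sequences awaiting synchronization
#'
#' One image time sequence per z position, acquired slice by slice so that
#' the cardiac phase of each sequence is unknown. Input to
#' [synchronize_scan()].
#'
#' @param sequences list of numeric `(T_i, Y, X)` arrays, ordered by z.
#' @param z_um strictly increasing z positions in micrometers.
#' @param fps acquisition frame rate in Hz.
#' @param pixel_um in-plane pixel size in micrometers.
#' @return An object of class `slice_scan`.
#' @export
slice_scan <- function(sequences, z_um, fps, pixel_um) {
  if (length(sequences) != length(z_um)) stop("one z position per sequence required")
  if (length(sequences) && is.unsorted(z_um, strictly = TRUE))
    stop("z positions must be strictly increasing")
  shp <- lapply(sequences, function(s) dim(s)[2:3])
  if (length(shp) > 1 && !all(vapply(shp, identical, logical(1), shp[[1]])))
    stop("all sequences must share the in-plane shape")
  if (fps <= 0 || pixel_um <= 0) stop("fps and pixel size must be positive")
  structure(list(sequences = sequences, z_um = as.numeric(z_um),
                 fps = fps, pixel_um = pixel_um),
            class = "slice_scan")
}

#' @export
print.slice_scan <- function(x, ...) {
  cat(sprintf("slice_scan: %d slices, %s frames each, %.4g fps, pixel %.3g um\n",
              length(x$sequences),
              paste(range(vapply(x$sequences, function(s) dim(s)[1], 1L)), collapse = "-"),
              x$fps, x$pixel_um))
  invisible(x)
}

#' Voxel-wise velocity field time series
#'
#' Per-voxel 3-component myocardial velocity in micrometers per second,
#' masked to the ventricular region. Produced by
#' [displacement_to_velocity()].
#'
#' @param v numeric 5-D array `(T, Z, Y, X, 3)`; the last axis holds the
#'   `(vz, vy, vx)` components.
#' @param mask logical `(Z, Y, X)` array or `NULL` for all voxels.
#' @param spacing_um voxel spacing `(z, y, x)` in micrometers.
#' @param frame_interval_s frame interval in seconds.
#' @return An object of class `vector_field4d`.
#' @export
vector_field4d <- function(v, mask = NULL, spacing_um, frame_interval_s) {
  if (length(dim(v)) != 5 || dim(v)[5] != 3)
    stop("v must be a (t, z, y, x, 3) array")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(v)[2:4])) stop("mask shape must match the field")
    for (k in 1:3) v[, , , , k] <- v[, , , , k] * rep(as.numeric(mask), each = dim(v)[1])
  }
  structure(list(v = v, mask = mask, spacing = rep_len(as.numeric(spacing_um), 3L),
                 frame_interval = frame_interval_s),
            class = "vector_field4d")
}

#' @export
print.vector_field4d <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("vector_field4d: %d frames, %d x %d x %d voxels, %s masked\n",
              d[1], d[2], d[3], d[4],
              if (is.null(x$mask)) "not" else sprintf("%d voxels", sum(x$mask))))
  invisible(x)
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("sync_result: period %.2f frames (median of %d slices), shifts 0-%d\n",
              x$period, length(x$period_per_slice), max(x$shifts)))
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth (%s): period %d frames", x$type, x$config$period))
  if (!is.null(x$offsets)) cat(sprintf(", %d slice offsets", length(x$offsets)))
  if (!is.null(x$trajectories))
    cat(sprintf(", %d tracer passages", length(unique(x$trajectories$id))))
  cat("\n")
  invisible(x)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks, %d localizations, frames %d-%d\n",
              length(unique(x$track_id)), nrow(x), min(x$frame), max(x$frame)))
  NextMethod()
}
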