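REQUIRED_SIDECAR_KEYS <- c("axes", "shape", "spacing_um", "frame_interval_s")

#' Write / read a 4-D volume as multi-page TIFF with a JSON sidecar
#'
#' Volumes are stored as 32-bit float multi-page TIFF, pages ordered
#' time-major (`page = t * Z + z`), with a JSON sidecar (`<path>.json`)
#' recording the axes convention, shape, voxel spacing, frame interval,
#' phase origin and the intensity range used to normalize the pages into
#' `[0, 1]` (TIFF stores values in that range). The round trip restores
#' intensities at 32-bit float precision.
#'
#' @param v a [volume4d()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `write_volume4d` returns `path` invisibly; `read_volume4d`
#'   returns a [volume4d()].
#' @export
write_volume4d <- function(v, path) {
  stopifnot(inherits(v, "volume4d"))
  d <- dim(v$data)
  lo <- min(v$data); hi <- max(v$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[1] * d[2])
  for (t in seq_len(d[1]))
    for (z in seq_len(d[2]))
      pages[[(t - 1) * d[2] + z]] <- (matrix(v$data[t, z, , ], d[3], d[4]) - lo) / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(axes = "tzyx", shape = as.integer(d), spacing_um = v$spacing,
               frame_interval_s = v$frame_interval, phase_origin = v$phase_origin,
               intensity_range = c(lo, hi))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume4d
#' @export
read_volume4d <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar %s (required keys: %s)", sidecar,
                 paste(REQUIRED_SIDECAR_KEYS, collapse = ", ")))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(REQUIRED_SIDECAR_KEYS, names(meta))
  if (length(missing))
    stop(sprintf("sidecar %s lacks required keys: %s", sidecar,
                 paste(missing, collapse = ", ")))
  if (!identical(meta$axes, "tzyx"))
    stop(sprintf("unsupported axes order '%s' (expected 'tzyx')", meta$axes))
  d <- as.integer(meta$shape)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != d[1] * d[2])
    stop(sprintf("page count %d does not match declared shape t=%d, z=%d",
                 length(pages), d[1], d[2]))
  rg <- meta$intensity_range %||% c(0, 1)
  scale <- if (rg[2] > rg[1]) rg[2] - rg[1] else 1
  arr <- array(0, dim = d)
  for (t in seq_len(d[1]))
    for (z in seq_len(d[2]))
      arr[t, z, , ] <- pages[[(t - 1) * d[2] + z]] * scale + rg[1]
  volume4d(arr, meta$spacing_um, meta$frame_interval_s,
           meta$phase_origin %||% 0L)
}

#' Write / read tracks as CSV
#'
#' Columns: `track_id, frame, t_seconds, z_um, y_um, x_um, vz, vy, vx`
#' (velocities in um/s, `NA` on each track's last localization).
#'
#' @param tracks a `track_set` (velocities optional).
#' @param path CSV path.
#' @param frame_interval_s frame interval used for the `t_seconds` column;
#'   taken from the track attributes when `NULL`.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a
#'   `track_set`.
#' @export
write_tracks <- function(tracks, path, frame_interval_s = NULL) {
  dt <- frame_interval_s %||% attr(tracks, "frame_interval") %||% NA_real_
  df <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                   t_seconds = tracks$frame * dt,
                   z_um = tracks$z, y_um = tracks$y, x_um = tracks$x,
                   vz = tracks$vz %||% NA_real_, vy = tracks$vy %||% NA_real_,
                   vx = tracks$vx %||% NA_real_)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- read.csv(path)
  out <- data.frame(track_id = df$track_id, frame = df$frame,
                    z = df$z_um, y = df$y_um, x = df$x_um,
                    vz = df$vz, vy = df$vy, vx = df$vx)
  if (nrow(df) > 1 && any(diff(df$t_seconds) != 0)) {
    dts <- unique(round(diff(df$t_seconds) / pmax(diff(df$frame), 1), 12))
    dts <- dts[is.finite(dts) & dts > 0]
    if (length(dts)) attr(out, "frame_interval") <- dts[1]
  }
  class(out) <- c("track_set", "data.frame")
  out
}

#' Write a synchronization report as JSON
#'
#' Records the pooled period, per-slice period estimates and confidences,
#' accumulated per-slice shifts, adjacent pairwise shifts and the full
#' distance profiles.
#'
#' @param sync a `sync_result` from [synchronize_scan()].
#' @param path JSON path.
#' @export
write_sync <- function(sync, path) {
  jsonlite::write_json(unclass(sync), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a fitted centerline as JSON (plus optional CSV of dense samples)
#'
#' @param cl a [fit_centerline()] object.
#' @param path JSON path for center, plane basis, polynomial coefficients,
#'   theta domain and orientation.
#' @param samples_csv optional CSV path for the dense samples
#'   (`s, z, y, x, tz, ty, tx`).
#' @export
write_centerline <- function(cl, path, samples_csv = NULL) {
  meta <- list(center = cl$center,
               e1 = cl$plane$e1, e2 = cl$plane$e2, normal = cl$plane$normal,
               coefficients = cl$coefficients, order = cl$order,
               theta_range = cl$theta_range, av_end = cl$av_end)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(samples_csv)) {
    df <- data.frame(s = cl$arc_length,
                     z = cl$samples[, 1], y = cl$samples[, 2], x = cl$samples[, 3],
                     tz = cl$tangents[, 1], ty = cl$tangents[, 2], tx = cl$tangents[, 3])
    write.csv(df, samples_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Write a velocity field as per-component TIFFs with a JSON sidecar
#'
#' Each component (`vz`, `vy`, `vx`) is written as one multi-page float
#' TIFF (time-major pages) through the same normalized encoding as
#' [write_volume4d()]; `<prefix>.json` lists the component files, spacing
#' and frame interval.
#'
#' @param vf a [vector_field4d()].
#' @param prefix output path prefix.
#' @return The sidecar path, invisibly.
#' @export
write_vector_field <- function(vf, prefix) {
  d <- dim(vf$v)
  comp <- c("vz", "vy", "vx")
  files <- character(3)
  for (k in 1:3) {
    files[k] <- paste0(prefix, "_", comp[k], ".tif")
    vk <- volume4d(array(vf$v[, , , , k], dim = d[1:4]), vf$spacing, vf$frame_interval)
    write_volume4d(vk, files[k])
  }
  meta <- list(components = basename(files), spacing_um = vf$spacing,
               frame_interval_s = vf$frame_interval)
  out <- paste0(prefix, ".json")
  jsonlite::write_json(meta, out, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @rdname write_vector_field
#' @export
read_vector_field <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dirn <- dirname(prefix)
  vols <- lapply(file.path(dirn, meta$components), read_volume4d)
  d <- dim(vols[[1]]$data)
  v <- array(0, dim = c(d, 3))
  for (k in 1:3) v[, , , , k] <- vols[[k]]$data
  vector_field4d(v, NULL, meta$spacing_um, meta$frame_interval_s)
}

#' Export one frame of a velocity field as a legacy VTK file
#'
#' ASCII legacy-VTK STRUCTURED_POINTS with a VECTORS attribute, for
#' visualization in ParaView and friends. Vector components are written in
#' `(x, y, z)` order as VTK expects.
#'
#' @param vf a [vector_field4d()].
#' @param t frame index (1-based).
#' @param path output `.vtk` path.
#' @export
write_vtk_vector_field <- function(vf, t, path) {
  d <- dim(vf$v)[2:4]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cardio4d velocity field (um/s)", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[3], d[2], d[1]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", vf$spacing[3], vf$spacing[2], vf$spacing[1]),
               sprintf("POINT_DATA %d", prod(d)),
               "VECTORS velocity float"), con)
  vz <- vf$v[t, , , , 1]; vy <- vf$v[t, , , , 2]; vx <- vf$v[t, , , , 3]
  # VTK iterates x fastest, then y, then z
  lines <- character(prod(d))
  i <- 1L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) {
    xs <- sprintf("%g %g %g", vx[z, y, ], vy[z, y, ], vz[z, y, ])
    lines[i:(i + d[3] - 1L)] <- xs
    i <- i + d[3]
  }
  writeLines(lines, con)
  invisible(path)
}
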