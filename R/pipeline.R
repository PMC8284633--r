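#' Pipeline configuration
#'
#' Collects every tunable of the staged analysis: gating, registration,
#' tracking and flow-geometry options, with the defaults used throughout
#' the standard workflow (200 Hz acquisition, 2 um working resolution,
#' demons pyramid 100/50/25, 7-frame temporal window, 30 um ventricle mask
#' radius, 4 segments, 1000 um/s reversal threshold). All numeric options
#' are validated here, before any computation runs.
#'
#' @param out_dir output directory for all intermediates.
#' @param phantom a [phantom_config()] used to generate inputs when no
#'   recorded data are supplied; its seed drives all pipeline randomness.
#' @param scan optional [slice_scan()] (recorded data) instead of the
#'   phantom heart channel.
#' @param particles optional [volume4d()] tracer series instead of the
#'   phantom flow channel.
#' @param period_prominence prominence threshold for [estimate_period()].
#' @param iterations demons pyramid iterations, coarsest first.
#' @param smoothing_sigma demons field regularization sigma (voxels).
#' @param temporal_window circular smoothing window (odd, frames).
#' @param mask_radius ventricle mask radius around the centerline (um).
#' @param intensity_threshold background threshold for the myocardial
#'   channel (`NULL` = Otsu).
#' @param particle_sigma preprocessing blur sigma (voxels).
#' @param detect_threshold_rel detection threshold as a fraction of the
#'   preprocessed maximum intensity.
#' @param min_separation minimum detection separation (um).
#' @param max_displacement linking gate (um; `NULL` = data-driven).
#' @param max_gap linking gap tolerance (frames).
#' @param min_duration track duration filter (frames).
#' @param n_segments number of myocardial segments (even).
#' @param reversal_threshold flow-reversal magnitude threshold (um/s).
#' @param av_point optional AV-canal position (um) to orient the centerline.
#' @param systole,diastole optional 0-based frame windows; derived from the
#'   projected-flow sign by [phase_windows()] when `NULL`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("cardio4d_"),
                            phantom = phantom_config(),
                            scan = NULL, particles = NULL,
                            period_prominence = 0.2,
                            iterations = c(100, 50, 25),
                            smoothing_sigma = 1.5,
                            temporal_window = 7L,
                            mask_radius = 30,
                            intensity_threshold = NULL,
                            particle_sigma = 1,
                            detect_threshold_rel = 0.3,
                            min_separation = 6,
                            max_displacement = NULL,
                            max_gap = 1L,
                            min_duration = 5L,
                            n_segments = 4L,
                            reversal_threshold = 1000,
                            av_point = NULL,
                            systole = NULL, diastole = NULL) {
  if (temporal_window %% 2 == 0) stop("temporal_window must be odd")
  if (n_segments %% 2 != 0 || n_segments < 2) stop("n_segments must be even")
  if (any(iterations <= 0)) stop("iterations must be positive")
  if (mask_radius <= 0 || min_separation <= 0) stop("radii must be positive")
  if (detect_threshold_rel <= 0 || detect_threshold_rel >= 1)
    stop("detect_threshold_rel must be in (0, 1)")
  if (max_gap < 0 || min_duration < 1) stop("invalid tracking thresholds")
  structure(list(out_dir = out_dir, phantom = phantom, scan = scan,
                 particles = particles, period_prominence = period_prominence,
                 iterations = iterations, smoothing_sigma = smoothing_sigma,
                 temporal_window = as.integer(temporal_window),
                 mask_radius = mask_radius, intensity_threshold = intensity_threshold,
                 particle_sigma = particle_sigma,
                 detect_threshold_rel = detect_threshold_rel,
                 min_separation = min_separation, max_displacement = max_displacement,
                 max_gap = as.integer(max_gap), min_duration = as.integer(min_duration),
                 n_segments = as.integer(n_segments),
                 reversal_threshold = reversal_threshold, av_point = av_point,
                 systole = systole, diastole = diastole),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[cardio4d] %-12s %6.1f s", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full staged analysis
#'
#' Executes gating, then the two parallel branches (demons registration of
#' the myocardial channel; particle tracking of the tracer channel), fits
#' the flow centerline from the pooled tracks, masks and partitions the
#' ventricle around it, and computes the projected flow profile, reversal
#' intervals and segmental wall-motion statistics. Every intermediate is
#' written under `config$out_dir`; a stage failure halts with the stage
#' name while earlier outputs remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return A result bundle (invisible list): gated `volume`, `sync`,
#'   `tracks`, `centerline`, `mask`, `labels`, velocity field `vf`,
#'   `flow_profile`, `reversals`, `windows`, `stats`, `relative` and the
#'   output `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  ph <- config$phantom

  # inputs: recorded data or the synthetic phantom
  scan <- config$scan
  particles <- config$particles
  if (is.null(scan)) {
    heart <- stage("phantom", {
      hb <- make_beating_heart(ph)
      simulate_slice_scan(hb, ph)
    })
    scan <- heart$scan
  }
  if (is.null(particles)) {
    flow <- stage("phantom-flow", make_particle_flow(ph))
    particles <- flow$volume
  }

  gated <- stage("gate", synchronize_scan(scan, config$period_prominence))
  write_volume4d(gated$volume, out("volume4d.tif"))
  write_sync(gated$sync, out("sync.json"))

  tracks <- stage("track", {
    pv <- preprocess_particles(particles, sigma = config$particle_sigma)
    det <- detect_particles(pv, config$detect_threshold_rel * max(pv$data),
                            config$min_separation)
    tr <- link_tracks(det, config$max_displacement, config$max_gap)
    tr <- filter_tracks(tr, config$min_duration)
    track_velocities(tr, particles$frame_interval)
  })
  write_tracks(tracks, out("tracks.csv"))

  cl <- stage("centerline", {
    fit_centerline(as.matrix(tracks[, c("z", "y", "x")]), av_point = config$av_point)
  })
  write_centerline(cl, out("centerline.json"), out("centerline_samples.csv"))

  reg <- stage("register", {
    vol <- preprocess_volume(gated$volume, config$intensity_threshold)
    T <- n_frames(vol)
    fields <- vector("list", T)
    for (t in seq_len(T)) {
      t2 <- if (t == T) 1L else t + 1L
      fields[[t]] <- demons_register(get_frame(vol, t), get_frame(vol, t2),
                                     config$iterations, config$smoothing_sigma,
                                     vol$spacing[1], from = t - 1L, to = t2 - 1L)
    }
    mask <- centerline_mask(cl, dim(vol$data)[2:4], vol$spacing, config$mask_radius)
    vf <- displacement_to_velocity(fields, vol$frame_interval, mask)
    w <- min(config$temporal_window, T)
    if (w %% 2 == 0) w <- w - 1L
    list(vf = smooth_temporal(vf, w), mask = mask)
  })
  write_vector_field(reg$vf, out("velocity"))

  res <- stage("flow-profile", {
    profile <- project_flow_velocity(tracks, cl)
    reversals <- detect_reversal(profile, config$reversal_threshold)
    windows <- if (is.null(config$systole) || is.null(config$diastole)) {
      w <- phase_windows(profile)
      list(systole = profile$frame[w$systole], diastole = profile$frame[w$diastole])
    } else list(systole = config$systole, diastole = config$diastole)
    list(profile = profile, reversals = reversals, windows = windows)
  })
  write.csv(res$profile, out("flow_profile.csv"), row.names = FALSE)
  write.csv(res$reversals, out("reversals.csv"), row.names = FALSE)

  seg <- stage("segments", {
    labels <- partition_segments(reg$mask, cl, config$n_segments,
                                 spacing_um = reg$vf$spacing)
    stats <- segment_statistics(reg$vf, labels)
    rel <- relative_velocity_by_phase(stats, res$windows$systole, res$windows$diastole)
    list(labels = labels, stats = stats, rel = rel)
  })
  write.csv(seg$stats, out("segment_stats.csv"), row.names = FALSE)
  write.csv(seg$rel, out("relative_velocity.csv"), row.names = FALSE)

  invisible(list(volume = gated$volume, sync = gated$sync, tracks = tracks,
                 centerline = cl, mask = reg$mask, labels = seg$labels,
                 vf = reg$vf, flow_profile = res$profile, reversals = res$reversals,
                 windows = res$windows, stats = seg$stats, relative = seg$rel,
                 files = list.files(config$out_dir, full.names = TRUE)))
}
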