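#' Configuration for the synthetic beating-heart phantom
#'
#' Defines a periodically contracting ellipsoidal myocardial shell imaged on a
#' voxel grid, and a set of point tracers ("blood cells") advected along a
#' curved path with a pulsatile, sign-changing speed profile. The phantom
#' provides exhaustive ground truth (per-slice phase offsets, an analytic
#' displacement-field sampler, true trajectories and the true flow path) so
#' every downstream stage can be validated without microscope data.
#'
#' The shell contracts as `r(t, u) = r0(u) * (1 + a * sin(2*pi*t/P - k*u))`
#' where `u` is the apex-base arc coordinate (micrometers), `a` the
#' contraction amplitude and `k` the phase-propagation rate, so contraction
#' propagates from the apex as observed in the embryonic ventricle.
#'
#' The tracer speed profile is a raised-cosine forward lobe followed by a
#' raised-cosine retrograde notch: over one cycle of phase `p in [0, 1)`,
#' `v(p) = v_peak * sin(pi * p / (1 - f))^2` for `p < 1 - f` and
#' `v(p) = -d * sin(pi * (p - 1 + f) / f)^2` otherwise, with `f` the
#' reversal fraction, `d` the reversal depth and `v_peak` set so the cycle
#' mean equals `flow_mean`. This reproduces a brief end-of-cycle
#' regurgitation through the valves rather than a symmetric oscillation.
#'
#' @param grid voxel counts `(z, y, x)`.
#' @param voxel_um isotropic voxel size in micrometers.
#' @param period cardiac period in frames (>= 8).
#' @param n_cycles number of cardiac cycles to render.
#' @param fps frame rate in Hz.
#' @param shell_center shell center in micrometers `(z, y, x)`; default grid center.
#' @param shell_radii ellipsoid semi-axes `(z, y, x)` in micrometers.
#' @param wall_thickness myocardial wall thickness (intensity FWHM) in micrometers.
#' @param contraction_amplitude fractional radius oscillation, in `[0, 0.5)`.
#' @param phase_rate contraction phase propagation, radians per micrometer
#'   from apex to base.
#' @param n_particles number of tracer particles (>= 0).
#' @param flow_mean cycle-averaged tracer speed, micrometers per second.
#' @param flow_reversal_depth peak retrograde speed (positive number), um/s.
#' @param flow_reversal_fraction fraction of the cycle with retrograde flow,
#'   in `[0, 0.5)`.
#' @param flow_path `"arc"` (planar arc, the default) or `"line"`.
#' @param path_radius arc radius in micrometers.
#' @param path_span angular span of the arc in radians.
#' @param spot_sigma rendered tracer spot sigma in micrometers.
#' @param noise_sigma additive Gaussian noise sigma, in intensity units
#'   (the rendered signal peak is 1, so SNR = 1 / noise_sigma).
#' @param background constant background intensity.
#' @param seed integer seed; all phantom randomness flows from it.
#' @return An object of class `phantom_config`.
#' @seealso [make_beating_heart()], [simulate_slice_scan()], [make_particle_flow()]
#' @export
phantom_config <- function(grid = c(32, 64, 64),
                           voxel_um = 2,
                           period = 40L,
                           n_cycles = 4L,
                           fps = 200,
                           shell_center = NULL,
                           shell_radii = c(40, 32, 32),
                           wall_thickness = 8,
                           contraction_amplitude = 0.1,
                           phase_rate = 0.015,
                           n_particles = 20L,
                           flow_mean = 400,
                           flow_reversal_depth = 1500,
                           flow_reversal_fraction = 0.15,
                           flow_path = c("arc", "line"),
                           path_radius = 40,
                           path_span = 4,
                           spot_sigma = 3,
                           noise_sigma = 0.1,
                           background = 0,
                           seed = 1L) {
  flow_path <- match.arg(flow_path)
  grid <- as.integer(rep_len(grid, 3L))
  if (period < 8) stop("period must be at least 8 frames")
  if (contraction_amplitude < 0 || contraction_amplitude >= 0.5)
    stop("contraction amplitude must be in [0, 0.5)")
  if (n_particles < 0) stop("particle count must be nonnegative")
  if (voxel_um <= 0 || wall_thickness <= 0 || any(shell_radii <= 0) ||
      path_radius <= 0 || spot_sigma <= 0)
    stop("all lengths must be positive")
  if (flow_reversal_fraction < 0 || flow_reversal_fraction >= 0.5)
    stop("flow reversal fraction must be in [0, 0.5)")
  if (fps <= 0) stop("frame rate must be positive")
  center <- shell_center %||% ((grid - 1) * voxel_um / 2)
  structure(list(grid = grid, voxel_um = voxel_um, period = as.integer(period),
                 n_cycles = as.integer(n_cycles), fps = fps,
                 shell_center = as.numeric(center), shell_radii = as.numeric(shell_radii),
                 wall_thickness = wall_thickness,
                 contraction_amplitude = contraction_amplitude,
                 phase_rate = phase_rate, n_particles = as.integer(n_particles),
                 flow_mean = flow_mean, flow_reversal_depth = flow_reversal_depth,
                 flow_reversal_fraction = flow_reversal_fraction,
                 flow_path = flow_path, path_radius = path_radius,
                 path_span = path_span, spot_sigma = spot_sigma,
                 noise_sigma = noise_sigma, background = background,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("phantom_config: %s voxels at %.3g um, period %d frames at %g fps, %d cycles\n",
              paste(x$grid, collapse = " x "), x$voxel_um, x$period, x$fps, x$n_cycles))
  cat(sprintf("  shell radii %s um, amplitude %.3g, phase rate %.3g rad/um\n",
              paste(x$shell_radii, collapse = "/"), x$contraction_amplitude, x$phase_rate))
  cat(sprintf("  %d tracers on %s path, mean flow %g um/s, reversal %g um/s over %.0f%% of cycle\n",
              x$n_particles, x$flow_path, x$flow_mean, x$flow_reversal_depth,
              100 * x$flow_reversal_fraction))
  invisible(x)
}

# per-voxel geometry shared by rendering and the analytic displacement sampler:
# w    = position normalized by the semi-axes, rho = |w|
# u    = apex-base arc coordinate (invariant under the radial scaling motion)
# Lloc = physical radius along the voxel's direction, per unit rho
shell_geometry <- function(points_um, config) {
  ctr <- config$shell_center
  rad <- config$shell_radii
  w <- sweep(points_um, 2, ctr)
  wn <- sweep(w, 2, rad, "/")
  rho <- row_norms(wn)
  safe <- pmax(rho, 1e-12)
  dhat <- wn / safe
  rbar <- mean(rad)
  u <- acos(pmin(1, pmax(-1, -dhat[, 1]))) * rbar  # apex at low z
  Lloc <- sqrt((rad[1] * dhat[, 1])^2 + (rad[2] * dhat[, 2])^2 + (rad[3] * dhat[, 3])^2)
  list(offset = w, rho = rho, u = u, Lloc = Lloc)
}

shell_scale <- function(t, u, config) {
  1 + config$contraction_amplitude *
    sin(2 * pi * t / config$period - config$phase_rate * u)
}

#' Render the beating-heart phantom
#'
#' Renders a closed ellipsoidal shell whose local radius oscillates with the
#' cardiac period and whose contraction phase propagates from the apex. The
#' wall is drawn as a Gaussian intensity profile across the material
#' mid-surface so that the image is exactly advected by the analytic motion
#' (registration stays well-posed, no aperture problem from binary edges).
#'
#' @param config a [phantom_config()].
#' @param n_frames number of frames to render; default `period * n_cycles`.
#' @param add_noise add Gaussian noise of sigma `config$noise_sigma`
#'   (seeded); default `FALSE` so the returned volume is the clean truth.
#' @return A list with `volume` (a [volume4d()]) and `truth`, a
#'   `phantom_truth` carrying `scale(t, u)`, the analytic
#'   `displacement(points_um, t_from, t_to)` sampler (micrometers) and
#'   `boundary_points(n, t)` sampling the material mid-surface.
#' @export
make_beating_heart <- function(config, n_frames = NULL, add_noise = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$grid
  h <- config$voxel_um
  extent <- (g - 1) * h
  amax <- 1 + config$contraction_amplitude
  reach <- config$shell_radii * amax + config$wall_thickness
  # the scan may crop the shell along z (the slice axis covers the central
  # portion of the heart), but laterally the shell must fit the field of view
  if (any(config$shell_center[2:3] - reach[2:3] < 0) ||
      any(config$shell_center[2:3] + reach[2:3] > extent[2:3]) ||
      config$shell_center[1] < 0 || config$shell_center[1] > extent[1])
    stop("shell radii exceed the voxel grid")
  n_frames <- as.integer(n_frames %||% (config$period * config$n_cycles))

  zc <- (seq_len(g[1]) - 1) * h
  yc <- (seq_len(g[2]) - 1) * h
  xc <- (seq_len(g[3]) - 1) * h
  pts <- as.matrix(expand.grid(z = zc, y = yc, x = xc))
  geo <- shell_geometry(pts, config)
  sigw <- config$wall_thickness / (2 * sqrt(2 * log(2)))  # FWHM -> sigma

  vol <- array(0, dim = c(n_frames, g))
  P <- config$period
  for (t in seq_len(min(n_frames, P)) - 1L) {
    s <- shell_scale(t, geo$u, config)
    m <- (geo$rho / s - 1) * geo$Lloc
    vol[t + 1L, , , ] <- config$background + exp(-0.5 * (m / sigw)^2)
  }
  if (n_frames > P)  # the motion is exactly periodic: tile the first cycle
    for (t in (P + 1L):n_frames) vol[t, , , ] <- vol[((t - 1L) %% P) + 1L, , , ]
  if (add_noise && config$noise_sigma > 0) {
    vol <- vol + with_seed(config$seed,
                           array(rnorm(length(vol), sd = config$noise_sigma), dim = dim(vol)))
  }

  cfg <- config
  truth <- structure(list(
    type = "heart", config = cfg,
    scale = function(t, u) shell_scale(t, u, cfg),
    displacement = function(points_um, t_from, t_to) {
      pm <- matrix(as.numeric(points_um), ncol = 3)
      geo <- shell_geometry(pm, cfg)
      s1 <- shell_scale(t_from, geo$u, cfg)
      s2 <- shell_scale(t_to, geo$u, cfg)
      geo$offset * (s2 / s1 - 1)
    },
    boundary_points = function(n = 200, t = 0) {
      i <- seq_len(n)
      # deterministic golden-spiral directions on the unit sphere
      cz <- 1 - 2 * (i - 0.5) / n
      az <- pi * (1 + sqrt(5)) * i
      sz <- sqrt(pmax(0, 1 - cz^2))
      dir <- cbind(cz, sz * sin(az), sz * cos(az))
      rbar <- mean(cfg$shell_radii)
      u <- acos(pmin(1, pmax(-1, -dir[, 1]))) * rbar
      s <- shell_scale(t, u, cfg)
      sweep(dir * s, 2, cfg$shell_radii, "*") +
        matrix(cfg$shell_center, n, 3, byrow = TRUE)
    },
    offsets = NULL), class = "phantom_truth")

  list(volume = volume4d(vol, rep(h, 3), 1 / config$fps),
       truth = truth)
}

#' Simulate a slice-by-slice acquisition of the beating heart
#'
#' Converts a rendered phantom volume into per-slice time sequences, each
#' circularly offset by a random (recorded) cardiac phase, emulating an
#' acquisition that scans the heart one z plane at a time over several
#' cycles. Additive Gaussian noise is applied per slice.
#'
#' @param heart output of [make_beating_heart()] (or a list with `volume`
#'   and `truth`).
#' @param config the same [phantom_config()].
#' @param offsets optional integer vector of per-slice phase offsets in
#'   `[0, period)`; drawn uniformly when `NULL`.
#' @return A list with `scan` (a [slice_scan()]) and `truth` (the input
#'   truth with `$offsets` recorded).
#' @export
simulate_slice_scan <- function(heart, config, offsets = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  vol <- heart$volume
  P <- config$period
  if (n_frames(vol) < 2 * P) stop("truth volume must cover at least 2 periods")
  d <- dim(vol$data)
  K <- d[2]
  n_seq <- max(4L, config$n_cycles) * P

  if (is.null(offsets)) {
    offsets <- with_seed(config$seed + 1L, sample.int(P, K, replace = TRUE) - 1L)
  } else {
    offsets <- as.integer(offsets)
    if (length(offsets) != K || any(offsets < 0 | offsets >= P))
      stop("offsets must give one value in [0, period) per slice")
  }

  sequences <- vector("list", K)
  noise <- config$noise_sigma
  with_seed(config$seed + 2L, {
    for (k in seq_len(K)) {
      idx <- ((seq_len(n_seq) - 1 + offsets[k]) %% P) + 1
      sk <- array(vol$data[idx, k, , ], dim = c(n_seq, d[3], d[4]))
      if (noise > 0) sk <- sk + array(rnorm(length(sk), sd = noise), dim = dim(sk))
      sequences[[k]] <- sk
    }
  })

  truth <- heart$truth
  truth$offsets <- offsets
  list(scan = slice_scan(sequences, (seq_len(K) - 1) * config$voxel_um,
                         config$fps, config$voxel_um),
       truth = truth)
}

# discrete per-frame speed profile (um/s) over one cycle, frames 0..P-1
flow_speed_profile <- function(config) {
  P <- config$period
  f <- config$flow_reversal_fraction
  d <- config$flow_reversal_depth
  m <- config$flow_mean
  p <- (seq_len(P) - 1) / P
  if (f <= 0) {
    vpk <- 2 * m
    return(vpk * sin(pi * p)^2)
  }
  vpk <- (2 * m + d * f) / (1 - f)
  ifelse(p < 1 - f,
         vpk * sin(pi * p / (1 - f))^2,
         -d * sin(pi * (p - (1 - f)) / f)^2)
}

#' Render the tracer-flow phantom
#'
#' Advects point tracers along a parametric path (planar arc by default)
#' with the pulsatile, sign-changing speed profile of the configuration, and
#' renders them as Gaussian spots. Tracers are seeded evenly along the path
#' with fixed radial/axial jitter and move as a rigid rotation of the
#' constellation that wraps at the end of the arc: a tracer leaving at the
#' outflow end re-enters at the inflow end as a new "passage" with a fresh
#' trajectory id, emulating cells transiting the ventricle. Spots whose
#' center leaves the grid are dropped from the images but kept in the truth.
#'
#' @param config a [phantom_config()].
#' @param n_frames frames to render; default `period * n_cycles`.
#' @return A list with `volume` (a [volume4d()]) and `truth`, carrying the
#'   true `trajectories` (id, frame, position um, velocity um/s, in_grid),
#'   the generating `profile` (per-frame nominal and mean projected speed),
#'   the `path` (plane basis, radius, dense `samples`, `av_point`) and the
#'   `reversal_window` of frames with retrograde flow.
#' @export
make_particle_flow <- function(config, n_frames = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$grid
  h <- config$voxel_um
  n_frames <- as.integer(n_frames %||% (config$period * config$n_cycles))
  P <- config$period
  dt <- 1 / config$fps
  n <- config$n_particles
  ctr <- (g - 1) * h / 2

  vprof <- flow_speed_profile(config)             # one cycle
  vt <- vprof[((seq_len(n_frames) - 1) %% P) + 1] # per frame 0..n_frames-1

  # basis in (z, y, x) coordinates: the arc lives in the y-x plane
  e1 <- c(0, 0, 1); e2 <- c(0, 1, 0); nrm <- c(1, 0, 0)
  r0 <- config$path_radius
  span <- config$path_span
  th0 <- -span / 2

  with_seed(config$seed + 3L, {
    rj <- r0 + runif(n, -5, 5)
    zj <- ctr[1] + rep_len(c(-6, 6), n) + runif(n, -2, 2)
  })

  if (config$flow_path == "arc") {
    pos_of <- function(a, j) {
      th <- th0 + (a %% span)
      cbind(zj[j], ctr[2] + rj[j] * sin(th), ctr[3] + rj[j] * cos(th))
    }
    # unwrapped path coordinate advances by v * dt / r0 radians per frame
    step <- vt * dt / r0
    wrap_span <- span
  } else {
    L <- (g[3] - 1) * h * 0.8
    pos_of <- function(a, j) {
      x <- ctr[3] - L / 2 + (a %% L)
      cbind(zj[j], ctr[2] + (rj[j] - r0), x)
    }
    step <- vt * dt
    wrap_span <- (g[3] - 1) * h * 0.8
  }

  # rigid advance of the constellation; per-particle unwrapped coordinate
  adv <- c(0, cumsum(step))[seq_len(n_frames)]
  traj <- vector("list", n)
  for (j in seq_len(n)) {
    a0 <- (j - 0.5) * wrap_span / max(n, 1)
    a <- a0 + adv
    passage <- floor(a / wrap_span)
    pos <- pos_of(a, j)
    in_grid <- pos[, 1] >= 0 & pos[, 1] <= (g[1] - 1) * h &
      pos[, 2] >= 0 & pos[, 2] <= (g[2] - 1) * h &
      pos[, 3] >= 0 & pos[, 3] <= (g[3] - 1) * h
    vel <- rbind((pos[-1, , drop = FALSE] - pos[-n_frames, , drop = FALSE]) / dt,
                 c(NA, NA, NA))
    same <- c(passage[-1] == passage[-n_frames], FALSE)
    vel[!same, ] <- NA
    traj[[j]] <- data.frame(id = j * 10000L + as.integer(passage - min(passage)),
                            frame = seq_len(n_frames) - 1L,
                            z = pos[, 1], y = pos[, 2], x = pos[, 3],
                            vz = vel[, 1], vy = vel[, 2], vx = vel[, 3],
                            in_grid = in_grid)
  }
  trajectories <- do.call(rbind, traj)
  rownames(trajectories) <- NULL

  # render
  sig <- config$spot_sigma / h
  rad <- ceiling(4 * sig)
  vol <- array(config$background, dim = c(n_frames, g))
  for (t in seq_len(n_frames)) {
    img <- array(0, dim = g)
    rows <- trajectories[trajectories$frame == t - 1L & trajectories$in_grid, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      cv <- c(rows$z[i], rows$y[i], rows$x[i]) / h  # 0-based voxel coords
      lo <- pmax(0L, floor(cv - rad)); hi <- pmin(g - 1L, ceiling(cv + rad))
      iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
      ez <- exp(-0.5 * ((iz - cv[1]) / sig)^2)
      ey <- exp(-0.5 * ((iy - cv[2]) / sig)^2)
      ex <- exp(-0.5 * ((ix - cv[3]) / sig)^2)
      img[iz + 1, iy + 1, ix + 1] <- img[iz + 1, iy + 1, ix + 1] +
        outer(outer(ez, ey), ex)
    }
    vol[t, , , ] <- img
  }
  if (config$noise_sigma > 0) {
    vol <- vol + with_seed(config$seed + 4L,
                           array(rnorm(length(vol), sd = config$noise_sigma), dim = dim(vol)))
  }

  # truth profile: nominal speed and mean signed projection of true velocities
  proj <- rep(NA_real_, n_frames)
  if (config$flow_path == "arc") {
    for (t in seq_len(n_frames)) {
      rows <- trajectories[trajectories$frame == t - 1L & trajectories$in_grid &
                             !is.na(trajectories$vz), , drop = FALSE]
      if (!nrow(rows)) next
      th <- atan2(rows$y - ctr[2], rows$x - ctr[3])
      # unit tangent toward increasing theta is (0, cos(th), -sin(th)) in (z, y, x)
      proj[t] <- mean(rows$vy * cos(th) - rows$vx * sin(th))
    }
  } else {
    for (t in seq_len(n_frames)) {
      rows <- trajectories[trajectories$frame == t - 1L & trajectories$in_grid &
                             !is.na(trajectories$vz), , drop = FALSE]
      if (nrow(rows)) proj[t] <- mean(rows$vx)
    }
  }

  ths <- seq(th0, th0 + span, length.out = 256)
  samples <- cbind(ctr[1], ctr[2] + r0 * sin(ths), ctr[3] + r0 * cos(ths))
  truth <- structure(list(
    type = "flow", config = config,
    trajectories = trajectories,
    profile = data.frame(frame = seq_len(n_frames) - 1L, v_nominal = vt,
                         v_projected = proj),
    path = list(center = ctr, e1 = e1, e2 = e2, normal = nrm, radius = r0,
                theta_range = c(th0, th0 + span), samples = samples,
                av_point = samples[1, ]),
    reversal_window = which(vprof < 0) - 1L,
    offsets = NULL), class = "phantom_truth")

  list(volume = volume4d(vol, rep(h, 3), dt), truth = truth)
}
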