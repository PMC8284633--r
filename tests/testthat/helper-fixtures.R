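# Shared fixtures, built once per session and cached. Sizes are chosen so
# unit tests stay fast; the acceptance tests build their own full-size
# phantoms.

.fix <- new.env(parent = emptyenv())

cache <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, expr, envir = .fix)
  get(key, envir = .fix)
}

cfg_with <- function(defaults, ...) {
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

small_heart_cfg <- function(...) {
  cfg_with(list(grid = c(16, 32, 32), period = 12L, n_cycles = 2L,
                shell_radii = c(20, 16, 16), wall_thickness = 6,
                noise_sigma = 0, seed = 1L), ...)
}

small_heart <- function() cache("small_heart", make_beating_heart(small_heart_cfg()))

small_flow_cfg <- function(...) {
  cfg_with(list(grid = c(24, 64, 64), period = 20L, n_cycles = 1L,
                n_particles = 8L, path_radius = 36, path_span = 3,
                noise_sigma = 0, seed = 2L), ...)
}

# the acceptance registration phantom and its full-cycle demons fields are
# expensive; several acceptance blocks share them
reg_cycle <- function() cache("reg_cycle", {
  cfg <- phantom_config(grid = c(64, 64, 64), period = 20L, n_cycles = 1L,
                        contraction_amplitude = 0.05, noise_sigma = 0, seed = 2L)
  hb <- make_beating_heart(cfg)
  P <- cfg$period
  fields <- vector("list", P)
  for (t in seq_len(P)) {
    t2 <- if (t == P) 1L else t + 1L
    fields[[t]] <- demons_register(array(hb$volume$data[t, , , ], cfg$grid),
                                   array(hb$volume$data[t2, , , ], cfg$grid),
                                   spacing_um = cfg$voxel_um,
                                   from = t - 1L, to = t2 %% P)
  }
  list(cfg = cfg, heart = hb, fields = fields)
})

# reference arc centerline used by the flow-geometry tests
arc_centerline <- function() cache("arc_centerline", {
  th <- seq(-1.5, 1.5, length.out = 60)
  pts <- cbind(30 + 0 * th, 60 + 40 * sin(th), 60 + 40 * cos(th))
  list(points = pts, theta = th, center = c(30, 60, 60),
       cl = fit_centerline(pts, center = c(30, 60, 60)))
})

rotation_matrix <- function(ax, ay, az) {
  Rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
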