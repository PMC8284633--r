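# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian blur of a 3-D array (clamped borders, separable kernel).
blur3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  array(cpp_gaussian_blur3(as.double(vol), as.integer(d), sigma), dim = d)
}

# Trilinear sampling of a 3-D array at 0-based voxel coordinates (clamped).
trilinear <- function(vol, z, y, x) {
  cpp_trilinear(as.double(vol), as.integer(dim(vol)), as.double(z), as.double(y), as.double(x))
}

# Resample a 3-D array from spacing `from_um` (per axis) to isotropic `to_um`.
resample_iso <- function(vol, from_um, to_um) {
  d <- dim(vol)
  if (any(from_um <= 0) || to_um <= 0) stop("voxel spacing must be positive")
  nd <- pmax(1L, as.integer(round(d * from_um / to_um)))
  if (all(nd == d) && all(abs(from_um - to_um) < 1e-12)) return(vol)
  zq <- (seq_len(nd[1]) - 1) * to_um / from_um[1]
  yq <- (seq_len(nd[2]) - 1) * to_um / from_um[2]
  xq <- (seq_len(nd[3]) - 1) * to_um / from_um[3]
  g <- expand.grid(z = zq, y = yq, x = xq)
  array(trilinear(vol, g$z, g$y, g$x), dim = nd)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

row_norms <- function(m) sqrt(rowSums(m^2))

# Circular roll of the first `L` frames of a (T, Y, X) sequence by `shift`.
roll_frames <- function(seq, shift, L) {
  idx <- ((seq_len(L) - 1 + shift) %% L) + 1
  seq[idx, , , drop = FALSE]
}

stopifnot_odd <- function(w, what = "window") {
  if (w %% 2 == 0) stop(sprintf("%s must be odd, got %d", what, w))
}
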