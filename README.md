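# cardio4d

Post-imaging computation for hybrid light-sheet / light-field recordings
of the beating embryonic heart (zebrafish, 3–5 days post fertilization):
retrospective gating of slice-scanned cardiac image sequences, demons
deformable-registration myocardial velocimetry, particle tracking
velocimetry (PTV) of blood-cell tracers, and centerline-referenced flow
and segmental wall-motion analysis.

At heart rates of 120–180 bpm a light-sheet microscope cannot scan a
volume per beat; it records one 2-D time sequence per z plane, each with
an unknown cardiac phase. Blood cells move aperiodically and are captured
volumetrically on the same 200 Hz clock by a light-field camera.
`cardio4d` turns those raw sequences into synchronized 4-D data and
quantitative motion:

* **Gating** — the cardiac period is the first prominent peak of the
  summed temporal autocorrelation of each slice sequence (median-pooled
  across slices); relative phase shifts between adjacent slices minimize
  the one-period circular pixel-wise Euclidean distance
  `D(s) = Σ_t ‖A_t − B_(t+s mod L)‖₂`, are chained modulo the period, and
  the rolled sequences are stacked into a `(t, z, y, x)` cycle.
* **Myocardial velocimetry** — classic (Thirion) demons registration
  between consecutive frames on a 3-level pyramid (100/50/25 iterations)
  yields voxel displacement fields; division by the frame interval gives
  velocity (µm/s), circularly smoothed over 7 frames, with spatial
  velocity gradients (1/s) and speed heatmaps.
* **PTV** — tracers are detected as local maxima with sub-voxel centroid
  refinement and linked by an order-1 autoregressive (constant-velocity)
  prediction with min-cost bipartite assignment, gap tolerance 1 frame.
* **Flow geometry** — a principal-plane angle θ parameterizes the pooled
  tracer cloud and each coordinate is fit as a 4th-order polynomial in θ
  (the flow centerline, an S3 model with `coef`/`predict`/`plot`
  methods); cell velocities project onto the local tangent (AV canal →
  outflow tract positive) giving the collective flow profile; retrograde
  intervals with |V| > 1000 µm/s mark trans-valvular reversal; the
  ventricle splits into left/right × proximal/distal segments around the
  centerline, with per-segment mean and magnitude-weighted mean velocity
  vectors and relative (segment/global) velocities.

No raw microscope data are required anywhere: the package ships a
synthetic beating-heart phantom (contracting ellipsoidal shell with
apex-led phase propagation, slice scan with hidden offsets, tracers on a
curved path with pulsatile reversing flow) whose ground truth — per-slice
offsets, an analytic displacement-field sampler, true trajectories and
the true flow path — drives every test.

## Worked example

```r
library(cardio4d)

cfg   <- phantom_config(seed = 42)      # 200 Hz, 40-frame cycle, 20 tracers
heart <- make_beating_heart(cfg)
scan  <- simulate_slice_scan(heart, cfg)

gated <- synchronize_scan(scan$scan)
gated$sync
#> sync_result: period 40.06 frames (median of 32 slices), shifts 0-38
gated$volume
#> volume4d: 40 frames of 32 x 64 x 64 voxels (z, y, x)
#>   spacing 2 x 2 x 2 um, frame interval 0.005 s (200 fps)

err <- (gated$sync$shifts + scan$truth$offsets - scan$truth$offsets[1]) %% cfg$period
mean(pmin(err, cfg$period - err))       # recovered vs true phase offsets
#> [1] 0
```

The estimated period (40.06 frames at 200 Hz ≈ 200 ms, i.e. 300 bpm for
this phantom's default cycle) is within 0.06 frames of the generating
value, and every one of the 32 hidden per-slice phase offsets is
recovered exactly.

```r
flow <- make_particle_flow(cfg, n_frames = cfg$period)
pv   <- preprocess_particles(flow$volume, sigma = 1)
det  <- detect_particles(pv, 0.3 * max(pv$data), min_separation = 6)
tk   <- track_velocities(filter_tracks(link_tracks(det, max_gap = 1), 3),
                         flow$volume$frame_interval)
tk
#> track_set: 34 tracks, 797 localizations, frames 0-39

cl <- fit_centerline(as.matrix(tk[, c("z", "y", "x")]),
                     center = flow$truth$path$center,
                     av_point = flow$truth$path$av_point)
cl
#> centerline: order-4 polynomial in theta over [-0.447, 3.552] rad
#>   797 points, arc length 156.7 um, AV canal at the theta_max end
#>   RMS residual 3.62 um per coordinate

profile <- project_flow_velocity(tk, cl)
range(profile$velocity, na.rm = TRUE)
#> [1] -1445.302  1193.277
detect_reversal(profile, magnitude_threshold = 1000)
#>   start end
#> 1    36  38
```

The 34 tracks are the 20 tracers split where they exit at the outflow
tract and re-enter; the 3.6 µm RMS centerline residual is the radius of
the simulated cell stream, not fit error. The projected flow profile
swings between ≈ +1.2 mm/s forward and −1.4 mm/s retrograde, and the
detected reversal interval (frames 36–38) sits inside the phantom's
generating reversal window (frames 35–39) — the end-of-cycle
trans-valvular backflow the |V| > 1000 µm/s criterion is designed to
flag.

From here, `demons_register`/`displacement_to_velocity` produce the
myocardial velocity field, `partition_segments` +
`segment_statistics` the segmental wall-motion table, and
`run_pipeline(pipeline_config(...))` chains every stage and writes all
intermediates (TIFF + JSON sidecars, CSV tables) to an output directory.
A thin command-line wrapper with `simulate`, `gate` and `pipeline`
subcommands lives in `inst/cli/cardio4d.R`.

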