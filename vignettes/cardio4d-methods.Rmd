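---
title: "Methods: retrospective gating, demons velocimetry and centerline-referenced flow analysis"
author: "cardio4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrospective gating, demons velocimetry and centerline-referenced flow analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Volumetric fluorescence imaging of the embryonic heart at 3–5 days post
fertilization must resolve events at heart rates of 120–180 beats per
minute. Light-sheet microscopes image one z plane at a time, so a 3-D
movie of the beating ventricle is assembled from per-slice 2-D time
sequences acquired minutes apart — each with an unknown cardiac phase.
Blood cells, in contrast, move aperiodically and must be captured
volumetrically in a single exposure (here, volumes reconstructed from a
light-field camera operating at the same 200 Hz clock).

`cardio4d` implements the post-imaging computation for such hybrid
recordings:

1. **Retrospective gating** — estimate the cardiac period and the relative
   phase shift of every slice sequence, then merge them into one
   `(time, z, y, x)` cycle.
2. **Deformable-registration velocimetry** — demons registration between
   consecutive frames gives a voxel-wise myocardial displacement field;
   division by the frame interval gives velocity in µm/s.
3. **Particle tracking velocimetry (PTV)** — detect blood-cell tracers and
   link them with a constant-velocity motion model into trajectories.
4. **Flow geometry** — fit a polynomial centerline through the pooled
   tracer positions, project cell velocities onto its tangent to get a
   collective flow profile, detect retrograde (reversal) intervals, and
   partition the ventricle into centerline-referenced segments for
   wall-motion statistics.

Because no raw recordings ship with the package, a synthetic beating-heart
phantom with exhaustive ground truth drives all tests: a contracting
ellipsoidal shell imaged slice by slice with hidden phase offsets, and
point tracers advected along a curved path with a pulsatile, sign-changing
speed.

# Retrospective gating

## Period estimation

For one slice sequence the frames are vectorized and the per-pixel
temporal autocovariance is summed over pixels (computed as the
superdiagonal means of the frame Gram matrix). The period is the lag of
the first local maximum of the normalized autocorrelation whose
prominence — peak height minus the deepest preceding valley — exceeds a
threshold (default 0.2), refined by parabolic interpolation of the three
samples around the peak. Constant or noise-only sequences fail the
prominence test and raise an "aperiodic input" error.

Per-slice estimates are pooled by the **median**; slices whose estimate
fails (e.g. planes grazing the edge of the heart) are simply excluded from
the pool. This is the standard robustness argument for median pooling and
is why the phantom's default shell deliberately spans the full slice range
the way a cropped field of view does in practice.

## Shift estimation

The distance between two sequences at circular shift $s$ is

$$D(s) = \sum_{t=0}^{L-1}\ \lVert A_t - B_{(t+s) \bmod L}\rVert_2,\qquad
L = \mathrm{round}(\text{period}),$$

after dividing each sequence by its mean intensity (this removes per-slice
illumination differences; `normalize = FALSE` restores the raw distance).
The window is exactly one rounded period, which makes $D$ strictly
circular and gives the swap symmetry $D(A,B,s) = D(B,A,(L-s) \bmod L)$.
The shift is the exhaustive integer argmin over $[0, L)$, ties toward the
smaller shift; a flat profile (relative range below $10^{-8}$) raises an
"indistinguishable phases" error rather than returning an arbitrary value.

Shifts are estimated between **adjacent** slices and accumulated modulo
$L$, aligning every slice to the phase of slice 1. Adjacent slices are the
most similar pair available; the cost is that one bad link offsets all
deeper slices, which is acceptable because the phantom study shows
per-pair recovery is exact at SNR 10 and the aperiodic-slice guard removes
the weak planes that could break a link. Sub-frame interpolation is
deliberately not attempted: at 200 Hz one frame is about 0.5 % of a cycle
at 150 bpm.

Frames of the concurrently recorded tracer channel inherit phases through
the shared clock (`assign_phases_by_timestamp`): the synchronized
reference sequence defines phase zero and the common frame rate maps any
time stamp to a phase in $[0, 1)$.

# Demons velocimetry

Volumes are first resampled to isotropic 2 µm (linear interpolation) and
background is removed by thresholding (Otsu's method on the pooled
histogram when no threshold is given).

Registration uses classic (Thirion) demons: with fixed image $F$ (frame
$t$), moving image $M$ (frame $t+1$) and current displacement $u$, the
per-voxel update is

$$\delta = \frac{(F - M\circ(\mathrm{id}+u))\,\nabla F}
{\lVert\nabla F\rVert^2 + (F - M\circ(\mathrm{id}+u))^2},$$

capped at 2 voxels per iteration, accumulated, and the **field** is
smoothed with a Gaussian (default σ = 1.5 voxels) after every iteration.
The solver runs coarse→fine over a 3-level image pyramid (factor 2 per
level, images pre-blurred with σ = 1 before decimation) with 100, 50 and
25 iterations. The field maps reference voxels to their moving-frame
positions and is reported in µm; with frame $t$ as the reference it reads
as the motion of material located at frame $t$. The last→first pair closes
the cycle so every frame carries a velocity.

Velocity is displacement over the frame interval, masked to the
ventricular region — by default all voxels within 30 µm of the flow
centerline. A circular 7-frame moving average (30 ms at 200 Hz) smooths
the maps over the cycle; circular averaging conserves the per-voxel cycle
mean exactly. Spatial velocity gradients (units 1/s) use central
differences that fall back to one-sided at mask borders so masked and
unmasked voxels never mix.

On the phantom, demons recovers 2-voxel translations and the analytic
shell displacement with mean endpoint error below half a voxel, and the
composition of all per-frame fields over one cycle returns material points
to their start within one voxel (the numbers are recomputed by
`scripts/acceptance.R` and the test suite).

## Kymograph cross-check

`kymograph_deformation_rate` samples intensity along a fixed line per
frame, finds the two outer wall boundaries by threshold crossing (default
half the kymograph maximum, sub-sample refined), and differentiates the
boundary distance — the classical 1-D deformation-rate readout. The same
two boundary points are used to sample the registration velocity field,
whose projected difference is the 3-D estimate. On the phantom the two
series correlate at r ≈ 1 for a line through the shell center, while a
line meeting the wall at 60° inflates the kymograph rate by ≈ 1/cos 60° =
2 and leaves the projected vector-field rate unaffected — the
angle-dependence that makes 1-D kymograph analysis fragile. Note that the
relevant incidence angle is at the **detected** boundary surface (the
outer half-maximum isosurface, i.e. mid-wall radius plus half the wall
thickness); measuring the tilt against the mid-surface predicts a smaller
factor.

# Particle tracking

Tracer volumes are resampled to 2 µm and blurred (σ = 1 voxel) to suppress
reconstruction artifacts. Detections are 26-connected local maxima above
an intensity threshold, with non-maximum suppression at a minimum
separation (default 6 µm) keeping the brighter of two close peaks, and
sub-voxel refinement by the intensity-weighted centroid of the 3×3×3
neighborhood. At SNR 10 this localizes isolated spots to ≈ 0.4 voxel; the
centroid window is small relative to the spot, so individual per-step
velocities carry a noise floor of roughly √2 × 0.4 voxel / Δt. Collective
(per-frame ensemble mean) speeds average this away and track the true
ensemble mean within a few percent, which is the quantity the flow profile
consumes.

Linking realizes the "autoregressive motion" model as order-1 constant
velocity: each active track predicts its next position as last position
plus last inter-frame step (zero for new tracks), candidates farther than
`max_displacement` from the prediction are forbidden, and the per-frame
assignment minimizes the summed squared prediction error by the Hungarian
algorithm. Unmatched tracks coast for `max_gap` frames (default 1) with
the prediction carried forward, then terminate. `max_displacement`
defaults to 3× the median inter-frame nearest-neighbor step measured on
the detections. Tracks shorter than `min_duration` frames are dropped, and
per-step velocities are Δposition / (Δframes × frame interval), stored on
the earlier frame.

A sampling constraint worth knowing: for a single-file stream of similar
tracers, frame-to-frame tracking is only unambiguous when the per-frame
step stays below about half the inter-particle spacing. The phantom's
default speeds respect this; data violating it need a higher volume rate,
not a cleverer linker.

# Flow geometry

## Centerline

Pooled tracer positions are reduced by PCA: the two leading eigenvectors
of the position covariance span the principal plane. Each point gets an
angle θ about a center point after projection onto the plane; the branch
cut is placed in the largest angular gap of the data so θ is continuous
along the occupied arc. Each spatial coordinate is then regressed on
$[1, \theta, \theta^2, \theta^3, \theta^4]$ by ordinary least squares.
The curve is evaluated at 200 θ samples; tangents come from the analytic
derivative of the polynomials and are globally oriented so the curve runs
from the atrioventricular canal to the outflow tract.

Choices a user should know:

* **Center point.** Default is the centroid of the pooled positions. For
  strongly curved (≳ 180°) paths the centroid sits far from the center of
  curvature and distorts the angular parameterization; supplying the
  anatomical center (as the original analyses do, by inspection) keeps the
  quartic model exact. The fit object is a classed model with `print`,
  `coef`, `predict`, `fitted`, `residuals` and `plot` methods.
* **AV-canal end.** `av_end = "theta_min"` by default; pass
  `av_point = <position>` to designate the start geometrically — the only
  rotation-safe option, since eigenvector signs (and with them the θ axis)
  are arbitrary.
* **Residual scale.** Under isotropic point noise σ the per-coordinate
  residual sd settles slightly **below** σ (≈ 0.8 σ): the noise component
  tangent to the curve is absorbed into each point's angle, not into the
  residual. This is a property of angular parameterizations, not a bug.
* Fit preconditions: at least `order + 1` points (≥ 15 recommended) and a
  θ span above π/4; smaller spans make the Vandermonde system
  ill-conditioned and are rejected.

## Projection, reversal, coordinates

Per-cell velocities are projected onto the unit tangent of the nearest
point of the dense centerline polyline and averaged per frame; positive
means AV canal → OFT. Frames without tracked cells are `NA`, never zero.
Reversal intervals are maximal runs with projected velocity below
−1000 µm/s (the threshold used for valve regurgitation at 3 dpf;
configurable).

`to_centerline_coords` maps points to (arc length, two signed cross-
section offsets). Cross-section frames are built by parallel transport of
`tangent × plane-normal` along the curve — this avoids the frame flips a
naive per-sample construction produces — and points are projected onto the
polyline segments so the round trip back to world coordinates is exact to
well under a micrometer for points near the curve. Points beyond the
curve's ends have no recoverable tangential coordinate (the projection
clamps to the end), which is inherent to any finite curve.

## Segments and statistics

For the standard four-segment analysis, each masked voxel is classified
proximal/distal by whether its nearest arc length falls in the first or
last half of the centerline, and left/right by the sign of its lateral
offset (labels 1–4 ordered from the AV canal, odd = left). General even
segment counts split the arc into n/2 equal bins. Odd counts are rejected
because segments pair left/right.

Two segmental velocity estimators are in circulation: the plain **mean
vector** and the **magnitude-weighted mean vector**
$\sum |v| v / \sum |v|$. Both are computed and returned side by side;
the magnitude-weighted vector is the default reported "segmental
velocity", matching the figure-level convention of the source analyses,
while the plain mean matches their text. The global velocity is the mean
speed over the whole mask, and the relative velocity of a segment is its
mean speed over the global mean — by construction the voxel-count-weighted
mean of segment speeds equals the global speed. Cycle-level relative
velocities are averaged within systole/diastole windows; when no windows
are declared the cycle is split at the sign changes of the projected flow
(longest positive run = systole), an operational default the user should
override with physiological annotations when available.

A geometric caveat: around a curved centerline, equal-width left and right
bands contain genuinely different voxel counts (the volume element is
$(1-\kappa u)\,du\,dw\,ds$), so count symmetry should only be expected for
nearly straight flow paths.

# The phantom

The myocardium is an ellipsoidal shell whose radius follows

$$r(t, u) = r_0(u)\,\bigl(1 + a\,\sin(2\pi t/P - k\,u)\bigr),$$

with $u$ the apex–base arc coordinate, amplitude $a$ (default 0.1) and
phase propagation $k$ (default 0.015 rad/µm) so contraction travels from
the apex as in the embryonic ventricle. The wall is rendered as a Gaussian
intensity profile across the material mid-surface (FWHM = wall thickness,
default 8 µm): because the profile is a function of the material
coordinate, the image is advected **exactly** by the analytic motion and
registration is well-posed (a binary shell would create aperture
problems). The default geometry (semi-axes 40/32/32 µm, prolate along the
scan axis, poles cropped by the 64 µm field of view) keeps signal in every
slice, as a real acquisition framed on the heart does. The analytic
displacement sampler, exact periodicity and cycle closure follow in closed
form from the radius law.

The slice-scan simulator tiles the periodic truth to ≥ 4 cycles per slice,
applies one uniform random integer phase offset per slice (recorded in the
truth; the offset distribution in real acquisitions is unknown, uniform is
assumed) and adds Gaussian noise (default σ = 0.1 of the unit signal peak,
i.e. SNR 10).

Tracers sit on a planar arc (radius 40 µm, span 4 rad) at evenly spaced
angles with fixed radial (±5 µm) and axial (alternating ±6 µm) jitter, and
advect as a rigid rotation of the constellation that wraps at the arc end
— a cell exiting at the outflow end re-enters at the inflow end as a new
trajectory, the way real cells transit the ventricle. Even spacing is
preserved across wraps, so the "well-separated spots" premise of the
detection tests is maintained at all times. The speed profile is a
raised-cosine forward lobe plus a raised-cosine retrograde notch
parameterized by (cycle-mean speed, reversal depth, reversal fraction),
defaults 400 µm/s, 1500 µm/s and 0.15: peak forward speed ≈ 1.2 mm/s and a
brief end-of-cycle regurgitation beyond the 1000 µm/s reversal threshold,
which reproduces the short trans-valvular backflow reported in early
valvulogenesis rather than the symmetric oscillation a pure sinusoid would
force. Spots are Gaussian (σ = 3 µm), rendered only while their centers
are inside the grid but always kept in the truth.

What the phantom does **not** emulate: optical point-spread functions,
depth-dependent attenuation and scattering, photobleaching, heart-rate
variability between cycles, deviations of the wall from an ellipsoid, and
out-of-plane tracer dispersion beyond the jittered tube. Passing tests
therefore demonstrate correctness of the computation under periodic,
geometrically clean conditions — not robustness to arrhythmia or imaging
artifacts, which the error paths (aperiodic input, indistinguishable
phases, missing boundaries) merely surface rather than repair.

# Numerical choices and problem sizes

* Volumes are stored `(t, z, y, x)` with positions in µm in `(z, y, x)`
  order; the TIFF sidecar records the convention. TIFF pages are 32-bit
  float, range-normalized into [0, 1] with the range in the sidecar, so
  round trips are exact at float32 precision (~1e-7 relative).
* Demons: update cap 2 voxels/iteration, field regularization σ = 1.5
  voxels, clamp-to-edge sampling; non-finite updates abort with the
  pyramid level and iteration named.
* Gaussian kernels are truncated at 3σ and renormalized; borders replicate.
* Assignment uses an exact Hungarian solver on the squared prediction
  error; forbidden links carry an effectively infinite cost and dummy
  rows/columns absorb unmatched items.
* Nearest-centerline queries use the dense 200-sample polyline (no
  quartic root-finding); coordinate transforms project onto its segments.
* Test and verification sizes: gating uses 32 slices of 64×64 at period
  40 over 20 random acquisitions; registration phantoms are 64³ voxels
  with a 20-frame cycle for the closure and kymograph studies; tracking
  uses 20 tracers over one 40-frame cycle. These sizes make every stage's
  error measurable against closed-form truth while the whole verification
  suite completes in a few minutes.

# Limitations

* Gating assumes strict periodicity; arrhythmic data should fail loudly
  (low autocorrelation prominence), not be corrected.
* Adjacent-pair shift chaining can propagate a single bad link; inspect
  the recorded distance profiles when a reconstruction looks torn.
* Classic demons is not diffeomorphic and makes no inverse-consistency
  guarantee; large inter-frame motion (> ~3 voxels) needs more pyramid
  levels or a higher frame rate.
* The linker neither merges nor splits tracks and carries no Kalman
  smoothing; it is intentionally the simplest model consistent with the
  "autoregressive motion, gap 1" description.
* The quartic-in-θ centerline is a single-branch model: paths that loop
  past ~300° or cross themselves need a different parameterization.
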