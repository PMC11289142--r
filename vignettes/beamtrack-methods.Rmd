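---
title: "Methods: marker tracking and closed-loop laser targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker tracking and closed-loop laser targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beamtrack` models the software of a camera-guided illumination rig: an
overhead camera watches a mouse in a 20 × 20 cm cage, a vision pipeline
tracks a coloured pen mark on its back, and a two-axis gimbal points a
blue laser at the tracked site on a programmed light schedule. This
vignette describes the models and procedures the package implements, the
parameters that matter, and the choices made where the design was open.

## The tracking pipeline

Detection is colour-based. Each 8-bit RGB frame passes through three
stages:

1. **Colour mask.** A pixel is foreground iff its colour lies in a
   configured range (`color_spec()`). The default works in HSV with two
   hue windows, `[0°, 25°]` and `[335°, 360°]`, so that red — which
   straddles the hue wrap-around — is captured in one spec; saturation
   ≥ 0.35 and value ≥ 0.15 floors reject the grey body, the dark floor,
   and black/white impulse noise. HSV is used because a hue window is far
   more robust to brightness variation than an RGB box; the conversion
   follows the standard hexcone formulas and matches
   `grDevices::rgb2hsv` exactly (a unit test asserts this).

2. **Morphological opening.** Erosion then dilation with a disk
   structuring element (`{(dx, dy) : dx² + dy² ≤ r²}`, default radius 2)
   removes speckle smaller than the element while approximately
   preserving the marker disk. A disk is used because pen marks are
   roughly rotationally symmetric. Pixels beyond the image border count
   as background in both passes; opening is anti-extensive and
   idempotent, which the tests check against a brute-force sliding-window
   oracle.

3. **Blobs and centroid.** 8-connected components are extracted; each
   blob's centroid is the arithmetic mean of its member pixel
   coordinates. Pixel centres sit at integer coordinates, 0-based, origin
   top-left, `u` rightward, `v` downward. Blobs are ordered by size with
   `(centroid_v, centroid_u)` tie-breaks so every run is reproducible.

Target selection discards blobs below `min_blob_px` (default 10), then
takes the nearest blob within `max_jump_px` (default 50) of the previous
centroid, falling back to the largest survivor. The centroid is smoothed
by an exponential moving average with `ema_alpha = 0.5`; when detection
fails the last smoothed position is held for `hold_frames = 15` frames
(0.75 s at 20 fps — about the longest occlusion we would still call the
same sighting) before the target is reported absent. The smoothing level
trades jitter against lag: at 0.05 m/s the EMA contributes roughly one
frame of lag, ~2.5 mm, half the marker radius.

## Geometry

The overhead camera views a planar floor, so a 3 × 3 homography `H` fully
describes the pixel→floor map; no intrinsic/extrinsic decomposition or
lens-distortion model is attempted. Calibration uses the normalised
direct linear transform: both point sets are translated/scaled
(Hartley normalisation), the 2n × 9 system is solved by SVD (exact for 4
correspondences, least squares beyond), and the result is denormalised
and scaled so `H[3,3] = 1`. A rank check rejects degenerate (e.g.
collinear) configurations.

The gimbal mount sits at `(mount_x, mount_y)` at height `mount_z`
(default: arena centre, 0.33 m — the height of the aluminium gantry).
With horizontal offset `d` to the target,

* `tilt = atan(d / mount_z)`, measured from nadir (straight down), and
* `pan` = planar bearing of the target from a frame-parallel reference
  axis, counter-clockwise from above, reported in (−180°, 180°].

Directly beneath the mount the bearing is undefined; the previous pan is
kept, so trajectories through nadir cause no pan discontinuity. The
laser spot is the ray–floor intersection,
`spot = mount + mount_z · tan(tilt) · (cos pan, sin pan)`; `laser_spot()`
and `arena_to_gimbal()` are exact inverses (tested to 1e-9 m).
Out-of-limit targets are clamped and flagged rather than rejected — a
moving animal may transiently leave the reachable cone and the loop must
keep running. The marked site is treated as lying on the floor plane; the
animal's back height adds a small constant offset that is well below the
illuminated spot size, and is a documented approximation.

## Control loop

The device's PID-stabilised brushless gimbal is abstracted to a
slew-rate-limited servo (default 300°/s per axis): per frame each axis
moves toward its target by at most `slew × dt`, pan along the shorter
wrapped direction. This preserves the property that matters for pointing
— bounded angular velocity — without modelling unpublished controller
gains. The loop acts on the centroid of the current frame, i.e. on
one-frame-old information by the time the spot lands, and applies no
predictive lead; this is deliberately conservative.

The scheduler supports continuous, off, and light/dark cycles (e.g. the
12 h/12 h regime used for multi-day induction), with half-open light
intervals. Doses are computed by exact interval arithmetic — whole cycles
contribute exactly `n × cycle_on` seconds — so 100 µW cm⁻² continuous
over 48 h is 17.28 J cm⁻² in closed form. The laser is gated off whenever
the schedule says off **or** the tracker reports the target absent; this
safety invariant is asserted over every frame of every simulated run in
the tests. For desk-scale tests of multi-day schedules the simulated
clock can be compressed via `time_scale`.

## The synthetic scene

The simulator stands in for the camera feed: a dark floor
(grey level 20), a grey elliptical body (semi-axes 110 × 55 px at the
default 640 px — a 7 × 3.5 cm mouse), and a red marker disk
(RGB 200/30/30, radius 16 px = 5 mm — a realistic pen circle) drawn at a
sub-pixel position, plus Gaussian sensor noise (σ = 2 grey levels) and
scripted occlusion intervals. Rasterisation is pixel-centre-in-shape
membership, and the exact sub-pixel marker position is emitted as ground
truth, so tracking error can be measured to a fraction of a pixel. The
marker is drawn after the body, so it is hidden only through explicit
occlusions — occlusion handling stays a controlled variable.

Motion is a reflected Ornstein–Uhlenbeck process: the velocity relaxes
toward zero with time constant 1 s while driven by white noise scaled so
the stationary RMS speed equals `speed_scale_m_per_s` (default 0.05 m/s,
an unhurried exploring mouse); the position integrates the velocity and
reflects off the walls at a 2 cm margin (the marker cannot reach the wall
because the body is in the way). The exact OU discretisation is used, so
trajectories are valid for any frame interval, and everything is
deterministic given the scene seed.

What the simulator does **not** emulate: fur texture and specularity,
lighting gradients, shadows, perspective and lens distortion, body pose
(the mark is always face-on), or multiple animals. Passing tests
therefore demonstrate the pipeline's correctness and its robustness to
impulse and Gaussian sensor noise — not performance on real video, where
the colour windows and morphology radius would need tuning to the actual
marker and illumination.

## Numerical choices and degenerate inputs

* Homographies are stored normalised to `H[3,3] = 1`; points mapping to
  `w ≈ 0` (the plane at infinity) raise an error rather than returning
  infinities.
* The nadir tie-break (`d = 0`) keeps the previous pan; tilt is exactly 0
  there.
* Blob and selection tie-breaks are total orders (size, then position,
  then proximity), so identical inputs always give identical tracks.
* Opening with radius 0 is the identity; an empty mask yields an empty
  blob table and a `found = FALSE` track state, not an error.
* All CSV/JSON outputs are written atomically (temp file + rename) and
  contain no timestamps, so reruns are byte-identical; timestamps go to
  the run log only.

## Problem sizes

The shipped tests and the acceptance script run the full loop on
320 × 320 px scenes (16 px/cm — the same physical geometry as the 640 px
default at half resolution): 1200 frames (60 s at 20 fps) for the
closed-loop metrics, 200 frames for tracking accuracy, 20 × 1000 points
for homography round trips, and 100 random masks for the morphology and
centroid properties. At these sizes the tracker's sub-pixel accuracy and
the ≥ 0.95 on-target fraction at 0.05 m/s are stable across seeds.

## Known limitations

* Colour segmentation assumes one marked animal per cage; multi-animal
  scenes and identity maintenance are out of scope (the four-cage rig is
  modelled as independent loops).
* The flat-floor assumption ignores the animal's height; for tall
  animals or low mounts the constant offset would need a correction.
* The servo abstraction does not model overshoot or vibration, only the
  angular-velocity bound.
* No learning-based detection: a marker colour that collides with the
  background (or severe colour casts) will defeat a pure colour mask.
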