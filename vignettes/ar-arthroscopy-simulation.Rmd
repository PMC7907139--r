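---
title: "Simulating marker-based AR navigation for elbow arthroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating marker-based AR navigation for elbow arthroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scopesight)
```

## The system being simulated

Elbow arthroscopy is performed through small portals with an
oblique-viewing rod-lens scope, in a joint where every major nerve of the
arm runs within millimetres of the instruments. Marker-based augmented
reality (AR) navigation addresses this by superimposing preoperative organ
models — bones and, critically, nerves — on the arthroscopic video. The
hardware stack behind such a system is: an optical stereo tracker watching
fiducial markers on the organ-model base plate and on the scope; a
calibration of the scope camera including its strong barrel distortion; and
a chain of rigid transforms that carries every organ mesh from the
preoperative model frame into the camera-sight frame for rendering.

`scopesight` rebuilds that stack as a desk-scale, fully deterministic
simulation. Every hardware component is replaced by a model with explicit,
seedable noise: the tracker by a stereo pinhole pair plus Gaussian pixel
noise, the scope by a Brown–Conrady camera, the printed phantom by
generated meshes. The point of the exercise is the *geometry*: with all
noise at zero the whole pipeline must be exact to numerical precision, and
with noise on, accuracy must degrade in the ways geometry predicts.

## Frames and the transform chain

Six coordinate frames matter (all units millimetres, all angles degrees at
the interfaces):

* `S` — the tracker sensor frame,
* `M` — the model base frame (the phantom's base plate marker),
* `A` — the scope-head marker frame,
* `T` — the scope tip frame,
* `C` — the camera-sight frame of the virtual camera,
* one frame per organ, placed by a static `T_MO`.

The tracker measures the poses `T_sM` (M→S) and `T_sA` (A→S). A per-session
calibration fixes `T_AT` (A→T), the rigid offset from the scope-head marker
to the tip. The model-to-camera transform is

```
M → C  =  V(θ) ∘ T_AT ∘ invert(T_sA) ∘ T_sM
```

where `V(θ)` places the virtual camera at the tip origin with its optical
axis tilted from the shaft axis by the lens-offset angle (30° by default)
at azimuth `θ`, the lens-cylinder rotation angle. Transforms are stored as
rotation + translation pairs (equivalently 4×4 homogeneous matrices),
column-vector convention, pre-multiplication; `compose()` refuses to chain
transforms whose frame labels do not match, which catches ordering bugs at
the source.

`θ` is not commanded but *estimated*, as in the real system: a second
marker on the lens cylinder is tracked, the relative transform head→cylinder
is compared against a reference pair captured once at `θ = 0`, and the
rotation angle about the shaft axis is extracted. If the relative rotation
axis deviates from the shaft axis by more than 5° *and* the off-axis
rotation component exceeds 2°, the estimate is flagged as misaligned. The
second condition matters: the axis of a near-identity rotation is dominated
by noise, so raw axis deviation alone would flag spuriously at small
cylinder rotations, whereas a genuine mount misalignment produces an
off-axis component that grows with the rotation and is reliably caught at
larger angles.

## The simulated tracker

The tracker is a stereo pair of pinhole cameras (defaults: f = 1000 px,
1280×960, 120 mm baseline, 10° total vergence) in the sensor frame.
Marker "Xpoints" are projected into both cameras, perturbed by i.i.d.
Gaussian pixel noise of standard deviation `noise_sigma_px`, and
triangulated back (midpoint of the common perpendicular of the two rays).
Poses are then estimated by the closed-form SVD solution of the absolute
orientation problem with a reflection guard. Image-level Xpoint *detection*
is deliberately not simulated — it is detector firmware, and no algorithm
for it is published for the hardware class — so pixel noise is the
simulation's single free noise parameter.

Two consequences of this geometry are worth keeping in mind when reading
numbers produced by the package. First, at ~820 mm range the depth error of
triangulation is amplified by roughly range/baseline ≈ 7 relative to the
lateral error, so 0.05 px of pixel noise already corresponds to ~0.3–0.5 mm
of 3D jitter — which is why 0.05 px is the default: it places the simulated
tracker in the sub-millimetre accuracy class of real optical trackers.
Second, the scope's camera centre sits ~180 mm from the scope-head marker
(`T_AT`), so marker *rotation* noise is levered into camera-centre
translation error. Both effects are physical, not artefacts.

## The arthroscope camera

The scope camera is a pinhole with Brown–Conrady distortion (three radial,
two tangential coefficients); the default model (f = 420 px, 640×480,
k1 = −0.22, k2 = 0.05) has the pronounced barrel distortion of a fisheye-like
arthroscope. Reverse correction uses a damped fixed-point iteration with a
monotone radial bracketing initialiser, converging below 1e-12 in normalised
coordinates inside the field of view (far outside it the r⁵/r⁷ polynomial
terms limit attainable residuals to their floating-point cancellation level,
and the tolerance scales accordingly).

Calibration follows the planar-checkerboard workflow: per-view DLT
homographies, closed-form intrinsics from the homography constraints, then
joint Levenberg–Marquardt refinement of intrinsics, distortion and per-view
poses. Corner detection is out of scope; `synthesize_calibration_views()`
renders exact corner correspondences (9×7 inner corners, 2 mm squares by
default) with optional pixel noise. On noise-free views the refinement
recovers focal lengths to ~1e-7 % and k1 to ~1e-8; at 0.2 px noise the rms
reprojection error sits at the noise floor.

```{r}
intr <- camera_intrinsics(420, 420, (640 - 1) / 2, (480 - 1) / 2, 640, 480)
dist <- distortion_model(k1 = -0.22, k2 = 0.05)
views <- synthesize_calibration_views(intr, dist, n_views = 5, seed = 1)
calibrate_camera(views, 640, 480)
```

## The synthetic phantom

`generate_phantom()` builds what the physical training phantom provides: a
mounting frame block, three bone cylinders (humerus, radius, ulna) meeting
near a joint point, a skin cylinder, and four thin nerve tubes
(radial, ulnar, median, musculocutaneous; 2 mm radius — nerves at the elbow
are of roughly this calibre) swept along smooth spline curves passing the
joint, plus the three marker templates (base plate, scope head, lens
cylinder). The arrangement is static, as in a printed model. A small seeded
jitter on the nerve control points makes each phantom individual while
keeping generation byte-deterministic: the same seed yields byte-identical
STL files.

What the phantom does *not* emulate: segmentation error in the preoperative
models, soft-tissue deformation, joint flexion, occlusion, and the optical
appearance of tissue. Tests passing on this phantom therefore validate the
navigation *geometry* — transform chain, calibration, angle estimation,
error propagation — not the image-processing or clinical end of a real
system.

## The TRE protocol

Accuracy is measured the way navigation accuracy is measured on hardware: a
2 mm-diameter circular model is registered so that its centre coincides
with a checkerboard intersection on the object; the scope views the
intersection at a 20 mm working distance; the lens cylinder is rotated from
−40° to +40° in 10° steps (9 angles, endpoints included); and the target
registration error (TRE) is the distance between where the overlay says the
circle centre is and where the intersection actually is.

One reading of `tre_at_angle()` runs the full estimated pipeline — noisy
marker observation, pose estimation, cylinder-angle estimation, transform
chain, distorted projection of the circle centre — and then back-projects
the resulting pixel through the *true* camera onto the checkerboard plane,
reporting the error in millimetres on the object plane. This object-plane
definition is declared, not inferred: it is the only hardware-free reading
of a superimposed-display error that has physical units. With zero noise
the error is numerically zero (< 1e-9 mm) at every grid angle, which is the
end-to-end consistency check of the whole package.

```{r}
res <- run_tre_protocol(tre_protocol(noise_sigma_px = 0, repetitions = 1))
summary(res)
```

The default protocol runs 100 repetitions per angle for stable statistics
(the physical measurement is one sweep; `paper_sweep: true` in a YAML
config, or `repetitions = 1`, reproduces that). Per-(angle, repetition)
seeds are derived from the protocol seed, so results are independent of
evaluation order. The summary uses the sample standard deviation (n−1),
flagged in the output because reporting conventions vary.

Two noise models are available. `"pixel"` (default) is the end-to-end
tracker noise path. `"rotation"` perturbs the estimated camera orientation
about the camera centre by a random small rotation and nothing else; it
isolates the angular error component, under which object-plane error is
working-distance × tan(error) — doubling the working distance from 20 to
40 mm doubles the median TRE, a scaling the pixel-noise path obscures
because marker translation errors do not scale with working distance.

At extreme commanded noise (≳ 0.5 px) an estimated chain can place the
target behind the camera; `tre_at_angle()` raises a visibility error rather
than fabricating a reading, and Monte-Carlo summaries should censor such
trials as unbounded errors.

## Numerical choices and degenerate inputs

* Absolute orientation: SVD (Kabsch) with a determinant guard against
  reflections; degenerate inputs (< 3 points, collinear source) are classed
  errors. Planar sets are not degenerate.
* Triangulation rejects ray pairs subtending < 0.1°.
* Template identification is by minimal pose-fit rms residual over the
  database, ties broken lexicographically, with a configurable acceptance
  threshold (default 1 mm).
* STL vertices are welded by exact float equality only — deterministic and
  reversible; ASCII output prints float32-rounded coordinates with 9
  significant digits so both dialects decode to identical meshes; binary
  output is byte-deterministic with the attribute count written as 0.
* Rendering clips overlay segments to the near plane and then to the image
  rectangle (Liang–Barsky); organs behind the camera yield empty primitive
  lists, never errors; skipped frames are logged, never dropped silently.
  No hidden-surface removal is performed — the clinical display deliberately
  shows structures behind the joint capsule.

## Problem sizes used by the test suite

The shipped tests and the acceptance script use 1000 random pose sets for
the chain-oracle comparison, 20 random distortion models on a 100×100 grid,
10 calibration views of 63 corners, 500 Monte-Carlo seeds per noise level
for pose/angle ordering, and the default 9 angles × 100 repetitions for the
TRE summary. These sizes give stable medians while keeping a full run in
the low minutes on one core.

## Known limitations

The simulation's noise model is white and isotropic in pixel space; real
trackers show distance- and angle-dependent, temporally correlated error.
The manual registration step of a clinical workflow is replaced by a
landmark-based rigid fit (`refine_registration()`), which is a testable
surrogate, not a reconstruction of how a surgeon adjusts an overlay. And
the headline accuracy of any real AR-arthroscopy system depends on hardware
characteristics (tracker jitter spectrum, lens stability, mount stiffness)
that no desk-scale simulation can supply; the package's claims are about
the correctness and scaling of the geometry, not about clinical accuracy.
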