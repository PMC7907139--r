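# scopesight

Desk-scale simulation of a marker-based augmented-reality (AR) navigation
system for elbow arthroscopy.

Elbow arthroscopy carries an unusually high risk of nerve injury: every
major nerve of the arm passes within millimetres of the portals. AR
navigation mitigates this by superimposing preoperative bone and nerve
models on the arthroscopic video. Behind such a system sits a chain of
geometry: an optical stereo tracker estimating the poses of fiducial
markers on the organ-model base plate and on the scope; a calibrated camera
model of an oblique-viewing (30° angled-lens) arthroscope with strong
barrel distortion; and rigid transforms carrying every organ mesh from the
preoperative model frame into the camera-sight frame.

`scopesight` rebuilds that stack in software, end to end and fully
deterministic, for people who develop or study surgical navigation
pipelines: simulated tracker, synthetic elbow phantom, calibration,
overlay rendering, and the accuracy protocol that sweeps the lens-cylinder
rotation angle.

## The core geometry

With frames `S` (tracker sensor), `M` (model base), `A` (scope-head
marker), `T` (scope tip) and `C` (camera sight), the tracker measures
`T_sM : M→S` and `T_sA : A→S`, a per-session calibration fixes
`T_AT : A→T`, and the overlay is rendered through

```
M → C  =  V(θ) ∘ T_AT ∘ T_sA⁻¹ ∘ T_sM
```

where `V(θ)` tilts the virtual camera's optical axis away from the shaft
axis by the 30° lens offset at azimuth `θ`, the lens-cylinder rotation
angle. `θ` is itself estimated from a second marker on the lens cylinder,
relative to a reference pair captured at `θ = 0`. Pose estimation is the
closed-form SVD (Kabsch) solution of the absolute orientation problem;
lens distortion is Brown–Conrady, calibrated from planar checkerboard
correspondences by homography initialisation plus Levenberg–Marquardt
refinement. The target registration error (TRE) of the overlay is measured
in millimetres on the object plane at a 20 mm working distance across
θ ∈ {−40°, …, +40°} in 10° steps.

## Worked example

```r
library(scopesight)

# simulated AR session: phantom -> tracking -> theta estimation -> overlay
s <- run_session(session_config(noise_sigma_px = 0.05), seed = 1)
print(s)
#> <ar_session: 9 frames rendered, 0 skipped, noise 0.05 px>
#>   cylinder-angle error: mean 0.3210 deg, max 0.5848 deg

# accuracy protocol: 9 cylinder angles x 100 repetitions at 20 mm
res <- run_tre_protocol(tre_protocol(seed = 1))
summary(res)
#> Target registration error: 1.32 ± 0.70 mm (range 0.0098–3.8 mm)
#>   n = 900, sd convention: sample (n-1)
#>   per-angle mean error (mm):
#>  angle_deg mean_error_mm   n
#>        -40      1.035570 100
#>        -30      1.249413 100
#>        ...
```

The session report says that across a −40°…+40° cylinder sweep, tracking
three markers at 0.05 px pixel noise, the estimated rotation angle stayed
within 0.6° of the commanded one and all nine overlay frames rendered. The
TRE summary is the simulated counterpart of a hardware accuracy report:
mean ± sd over the full angle grid, in millimetres on the object plane.
With `noise_sigma_px = 0`, both the overlay error and the TRE are
numerically zero — the consistency check that the transform chain,
lens-offset handling and distortion correction agree exactly.

Session and protocol runs can also be driven from YAML configs and written
to disk (numbered PGM frames, `poses.csv`, `tre_raw.csv`,
`tre_summary.txt`); see `inst/cli/scopesight.R` for a small command-line
front end:

```sh
Rscript inst/cli/scopesight.R tre --out out/
```

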