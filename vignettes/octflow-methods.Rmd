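---
title: "Depth-resolved OCT particle tracking velocimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved OCT particle tracking velocimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`octflow` measures depth-resolved lateral velocity — and from it the shear
rate — of a fluid sheared between microparallel plates, from time series of
OCT B-mode images of embedded tracer microspheres. This vignette explains
the physical model, the image-analysis procedure, every tunable parameter
that matters, the synthetic-data generator used for validation, and the
numerical choices and limitations a user should know about.

## Flow model and assumptions

The chamber holds the fluid between a stationary top plate and a bottom
plate driven laterally with either a triangle waveform (constant speed
`±V₀`, reversing each half period) or a sinusoid (velocity amplitude
`U₀ = π f Δpp`, peak-to-peak displacement `Δpp`). Depth `z` is measured
downward from the top plate (`z = 0`) to the driven plate (`z = H`).

Assumptions inherited from the experimental design:

* **No-slip tracers.** The ~2 µm polystyrene microspheres follow the fluid;
  Brownian motion is negligible on frame timescales in the viscous
  (hundreds of mPa·s) working fluids.
* **Low Reynolds number and fast viscous transients.** The viscous
  diffusion time `τ = H²ρ/μ` (exposed as `transient_time()`) is below a
  millisecond for the target fluids, so the linear Couette profile holds
  quasi-statically at every frame: `v(z, t) = (z/H) · v_plate(t)`. For a
  sinusoidal drive this is the finite-depth oscillating-plate solution in
  the gap-loading limit: amplitude linear in depth, no phase lag. Even
  non-Newtonian fluids show this profile within the gap-loading limit,
  which is what makes the chamber useful for biofluids such as mucus.
* **Parallel plates.** Plates are treated as parallel when their detected
  angles agree within 1° (`parallel_tol`), otherwise the stack is rejected.
* **Pure lateral motion.** Axial (depth) displacements are expected to be
  zero; the tracker searches only ±2 px axially as a sanity check.

The shear rate is the depth gradient of the velocity (amplitude):
`γ̇ = V₀/H` for the triangle drive, `γ̇max = U₀/H` for the sinusoid, both
constant in depth. The pipeline recovers them as the slope of a weighted
regression of measured row velocity (amplitude) on depth.

## The analysis chain

```{r}
library(octflow)
p <- preset_sinusoid(frequency = 10, scene = scene_config(seed = 3))
stack <- generate_stack(p$scene, p$acq, p$waveform, p$geom)
result <- track_stack(stack)   # runs the full chain below
```

1. **Start-up discard** (`discard_time = 30 ms`): removes stage transients;
   the waveform model carries the measured 9 ms mechanical start delay, so
   all later timestamps stay referenced to the actual plate motion.
2. **Lateral upsampling** (`upsample = 4`, cubic Catmull-Rom by default,
   linear available): integer displacements on the upsampled grid resolve
   ¼ native pixel.
3. **Plate detection and flattening**: per-column ridge maxima of the
   time-averaged image, residual-trimmed line fits, integer column shifts
   (no axial interpolation) to level the top plate. Depth is calibrated
   with the axial distortion factor `D_axial = √(n² − sin²α)/n²` — the form
   is fixed by its normal-incidence limit `1/n`, since OCT measures optical
   path length — and lateral distances with `D_transverse = 1/cos α`. The
   plate separation `H` is measured at the center column.
4. **ROI grid**: rows of 12 native axial px when `H > 200 µm`, 18 px below
   (15–18 µm physical), 100 native px wide (~150 µm, one to a few tracers
   per ROI); half-ROI safety margins from both plates; partial ROIs
   discarded.
5. **Thresholding and validity**: one threshold per ROI row — mean + 1.5 SD
   of that row's pixels pooled over columns and frames, which adapts to the
   depth sensitivity roll-off; pixels at or below it are zeroed. An ROI is
   non-empty only if, in every frame, it keeps more than one non-zero pixel
   and passes the diagonal-autocorrelation cluster check
   (`Σ I(x,z)·I(x−1,z−1) > 0`). Every row must keep at least one non-empty
   ROI or the stack is rejected as invalid (with the offending row in the
   error).
6. **Frame decimation**: displacements between frames `k` and `k + Δk`
   rather than adjacent frames, so slow regions accumulate measurable
   motion (see below).
7. **NCC displacement**: normalized cross-correlation of thresholded ROI
   pairs over integer shifts, zero-padded extension (out-of-window content
   cannot fabricate correlation), ties broken toward the smallest then
   most negative shift. Zero-variance ROIs raise an error and the
   measurement is marked missing.
8. **Velocities**: `v = xshift / Δk` converted to µm/s via the upsampled
   pixel size, `D_transverse` and the frame interval. Constant mode
   averages within each half sweep and pools `|v|` over columns and sweeps
   per row; turnaround frames (±2 frame intervals around each triangle
   peak/valley) are omitted. Sinusoidal mode assigns each sample to the
   middle of its pair interval, averages over columns (retaining the
   spread), and fits `A·cos(2πft + φ)` per row by weighted non-linear
   least squares initialized at the driving frequency.
9. **Shear-rate regression**: weighted least squares of row velocity
   (amplitude) on row depth; the slope ± SE is the shear rate, the
   intercept is left free (a no-slip zero intercept is available via
   `through_origin`), and the weighted r² measures profile linearity.

## Decimation rules

The published description of this method states the intent of decimation —
exaggerate motion where it is slow, using a linear velocity extrapolation
from the bottom row — but not the exact rule, so the rule here is this
package's own design, isolated behind the `decimation_plan` interface:

* **Bottom-row estimate.** Sub-pixel per-frame motion cannot be measured at
  `Δk = 1`, so the estimator doubles `Δk` until the mean measured bottom-row
  displacement reaches 2 px, then divides back.
* **Target displacement** `p_target` = 2 native pixels (8 upsampled px) per
  pair. Integer peak localization carries an irreducible ±0.5 px error;
  at 8 px accumulated displacement this bounds the per-measurement speed
  error at ~6%, which row and cycle averaging reduces further. (At the
  1-native-px target the bound would be ~12%, visibly degrading the
  linearity of recovered profiles.)
* **Caps.** Constant mode: `Δk` cannot exceed the largest lag realizable
  inside a padded half sweep. Sinusoidal mode: `Δk(k)_i ≤ T/(4·Δt)`. A pair
  spanning `Δk` frames measures the average velocity of its interval, which
  for a sinusoid equals the midpoint velocity times `sinc(ω·Δk·Δt/2)`;
  `velocities_sinusoidal()` divides this factor out exactly, so the cap
  only needs to keep `sinc` well-conditioned (> 0.9 at a quarter period)
  while letting slow rows accumulate several pixels.
* **Instantaneous speed model.** Sinusoidal `Δk(k)_i` follows
  `V̂_N · (z_i/z_N) · |cos(ωt + φ)|`, floored at `0.05·V̂_N`, with `V̂_N`
  the 0.9 quantile of coarse-decimation bottom-row displacements.
* **Measurability.** Rows whose pairs cannot accumulate at least 2
  upsampled px within the cap are quantization-dominated; they are excluded
  from tracking (the three deepest rows are always kept so the regression
  is possible). This mirrors the experimental observation that slow drives
  and high frequencies strain the method's frame-rate budget.

## Error model and weighting

Fitted standard errors alone understate the error of integer-quantized
displacements, which is systematic across identical pairs and does not
average out. Both modes therefore floor measurement spreads with the
quantization standard deviation `0.289 px / Δk` (±0.5 px uniform): constant
mode combines it with the across-(column, sweep) SD of row speeds;
sinusoidal mode floors the per-sample spreads entering the waveform fit and
combines it with the amplitude SE entering the depth regression. Rows with
no usable spread receive the median weight. "Weights from standard
deviations" is implemented as inverse variance, the standard convention.

Because an ROI's displacement is that of the tracers it actually contains —
anywhere within its 15–18 µm axial extent, not at its geometric center —
each row is assigned the intensity-weighted centroid depth of its
thresholded pixels (`effective_depths()`). With only a few tracers per ROI
this materially reduces depth-assignment bias in the regression.

## The synthetic generator

`generate_stack()` renders what the analysis needs to see, with exact
ground truth:

* two bright plate interfaces with configurable tilt (the same tilt the
  preprocessing must undo), the bottom plate at the refraction-scaled pixel
  offset `H / (pz · D_axial)` — the exact inverse of the depth calibration,
  so geometry recovery is testable as a round trip;
* sparse Gaussian tracer blobs (PSF 12 µm lateral × 3 µm axial in air,
  broadened by the 2.07 µm sphere diameter) advected by the closed-form
  Couette solutions, including the 9 ms mechanical delay; positions
  wrap at the extended lateral domain so tracer density is conserved;
* per-column A-line timing (column `c` rendered at
  `t_frame + c / line rate`), modelling lateral beam scanning of moving
  particles; a flag disables it for idealized tests;
* depth sensitivity roll-off `exp(−depth/600 µm)` and additive zero-mean
  Gaussian noise (default SD 0.02 on a [0, 1] intensity scale) clipped at
  zero, quantized to 16-bit levels so TIFF round trips are exact;
* an optional static-streak injector that emulates an autocorrelation
  artifact near the top plate, for exercising the rejection logic.

Tracer placement is stratified — two tracers per (ROI-height × ROI-width)
cell, within the central 70% of each lateral band — so that every ROI row
is trackable in every frame, which the validity rules require. The two
presets mirror the validation experiments: `preset_constant()` (0.5 Hz
triangle, plate speeds 5–60 µm/s, `H = 292 µm`, 250 A-lines at 10 kHz + 2 ms
dead time → 37 Hz frames, 1.5 mm field) and `preset_sinusoid()` (1–10 Hz,
24 µm peak-to-peak, `H = 150 µm`, 208 A-lines at 69 kHz → 199 Hz frames,
1.2 mm field). Stacks cover at least two driving cycles, capped at 200
frames (the experiments recorded three and six cycles; the cap keeps test
stacks tractable, and recovery quality at two cycles is already limited by
quantization, not cycle count).

What the generator does **not** emulate: OCT speckle (tracers dominate the
images for this particle-based method), Brownian motion, tracer
sedimentation or migration, spectral-domain reconstruction artifacts, and
detector saturation. Passing tests therefore validate the analysis chain
and its geometry/kinematics handling, not robustness to every instrumental
nuisance of real data.

## Numerical choices and degenerate inputs

* NCC means and normalizations are computed over the original window; the
  mean-subtracted second image is zero-padded, so padding contributes
  nothing to the sums.
* Tie-breaks at equal correlation go to the smallest `|u|`, then smallest
  `|v|`, then the negative candidate — deterministic and
  motion-conservative.
* The sinusoid fit is initialized by a linear cos/sin regression at the
  driving frequency; if that initialization already fits exactly, it is
  returned directly (the non-linear refiner has a singular Jacobian at an
  exact solution). Negative amplitudes are folded into the phase; phases
  are wrapped to (−180°, 180°] and reported relative to the drive after
  delay correction.
* Constant images, all-zero ROIs, empty rows, non-parallel plates, frames
  exhausted by the discard window, and drives faster than a quarter of the
  frame rate all raise classed errors (`octflow_error_*`) rather than
  propagating nonsense.

## Known limitations

* **Peak locking.** With a lateral PSF of ~2 native pixels FWHM, integer
  correlation peaks on the 4× upsampled grid are slightly biased toward
  zero for sub-native-pixel displacements. Rows that cannot accumulate
  about a native pixel of displacement within the decimation caps (shallow
  rows at high driving frequency) are underestimated by up to ~15% before
  the measurability rule excludes the worst of them; recovered shear rates
  can carry a few percent of residual bias from this effect. The
  experimental analogue is the reported difficulty at low shear rates and
  at ≥8 Hz driving.
* **ROI depth heterogeneity.** Tracers at different depths within one ROI
  move at different speeds; the correlation peak follows a
  brightness-weighted compromise. Effective-depth assignment corrects the
  first-order effect; the residual row-level scatter is visible in the
  regression spreads.
* **Newtonian validation only.** The synthetic flow is the linear Couette
  solution; shear-thinning or viscoelastic profiles (outside the
  gap-loading limit) are out of scope for the generator, though the
  tracker itself makes no Newtonian assumption beyond expecting motion
  along x.

## Problem sizes

The test suite and the acceptance script run the full pipeline on stacks of
130–200 frames of roughly 250 × 150–250 px (well under a minute per stack
on one CPU), six end-to-end experiments for the agreement sweep, 400
NCC-versus-brute-force oracle pairs, and an 8-configuration geometry
round-trip grid.
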