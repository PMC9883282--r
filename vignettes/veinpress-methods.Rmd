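---
title: "veinpress: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{veinpress: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Central venous pressure (CVP) guides fluid management in decompensated
heart failure, but the gold standard is an invasive catheter. The
internal jugular vein (IJV) offers a noninvasive window: it is valveless
between the neck base and the right atrium, so its lumen pressure tracks
right-atrial pressure, and it is softer and at lower pressure than every
structure around it, so it is the first thing to collapse under probe
pressure. `veinpress` implements the software side of a *force-coupled
ultrasound* measurement: B-mode short-axis cine of the IJV acquired while
the force on the probe face is recorded. The **collapse force** — the
probe force at which the segmented lumen area first falls below
0.5 mm² — serves as a Korotkoff-like surrogate for venous pressure. A
calibration line maps collapse force to the clinical jugular venous
pulsation height (JVP), and an inverse mechanical model turns a
constant-force area waveform into a venous pressure waveform.

The package covers: a synthetic phantom generator with known ground
truth, force/image synchronization, staged lumen segmentation, collapse
force estimation with two uncertainty components, JVP calibration with
Bland-Altman agreement and tilt/Valsalva perturbation summaries, and
waveform inversion by downhill simplex against a pluggable forward
model.

## The forward model: a collapsible-tube law

The 3-D finite-element simulation used in the original measurement
workflow is external solver territory; what the inverse machinery needs
is any smooth, strictly monotone pressure-area relation. We use the
standard collapsible-tube law

$$P_{tm} \;=\; K_p\!\left[\left(\frac{A}{A_0}\right)^{n_1} -
\left(\frac{A}{A_0}\right)^{-n_2}\right],$$

with a stiff expansion branch ($n_1 = 10$) and a soft collapse branch
($n_2 = 1.5$), inverted numerically by bisection (`tube_law_area()`).
The effective external pressure applied by the probe is a single lumped
transfer coefficient times force, $P_{ext} = c\,F$: within the narrow
healthy pressure range, the proportion of probe force lost to
surrounding tissue is treated as constant. `forward_area(P, F)` is then
the law evaluated at transmural pressure $P - cF$.

### Why the phantom's unloaded area is small

The exponents pin a scale relation: between the law's compliance scale
$K_p$ and full collapse at 0.5 mm², the collapse branch spans a pressure
factor of $(A_0/0.5\,\mathrm{mm^2})^{n_2}$. If $A_0$ were a typical
*distended* IJV area (~50-100 mm²), no $K_p$ could give both
physiological compliance near zero transmural pressure and collapse
forces in the observed 2-20 N range. The resolution is physiological:
the IJV is nearly collapsed at zero transmural pressure, so the
*unloaded* area is small. The phantom defaults are

| parameter | default | meaning |
|---|---|---|
| `unloaded_area` | 8 mm² | area at zero transmural pressure |
| `tube_stiffness` | 0.06 mmHg | compliance scale $K_p$ |
| `baseline_pressure` | 5 mmHg | mean venous pressure |
| `cardiac_amplitude` | 1 mmHg | cardiac pressure oscillation |
| `cardiac_period` | 1 s | heart rate 60 bpm |
| `force_transfer_coeff` | 0.9 mmHg/N | probe force to external pressure |
| `pixel_pitch` | 0.1 mm/px | high-resolution linear array |
| `frame_rate` | 20 Hz | B-mode cine rate |
| `speckle_level` | 0.15 | multiplicative speckle SD |

These give a supine lumen of ≈12.4 mm², collapse at ≈9.8 N from a 5 mmHg
baseline (inside the observed 3.5-10.5 N supine range), and a sub-5 mm²
descent spanning ≈2.4 cardiac cycles on the default 8 s, 14 N ramp — the
regime the collapse estimator actually works in. They were chosen once,
from this physical argument, and not revisited.

### What the phantom emulates, and what it does not

`generate_sequence()` renders the acquisition maneuver: three quick
triangular force spikes (0.3 s wide), a slow linear ramp past full
collapse, one post-ramp spike. Per frame the truth is
$P_{tm} = \text{baseline} + \text{cardiac}(t) - cF(t)$, the truth area
follows the tube law, and the force-trace clock is shifted by
`sync_offset` so the synchronization stage has something to recover.
Bulk tissue translation proportional to force makes the compressions
visible to optical flow. The rendered lumen is the *count-matched disk*:
exactly `round(area/pitch²)` pixels nearest the centroid, so the
dark-pixel count equals the truth area to half a pixel — the generator
contract the segmentation tests lean on. Speckle is multiplicative
Gaussian on the background field, translated coherently with the tissue.

Not emulated: acoustic point-spread functions, shadowing, wall
anisotropy, out-of-plane motion, the carotid artery, respiratory
variation. A green phantom test therefore establishes algorithmic
correctness against known truth, not clinical performance.

## Synchronization

The force trace and the cine come from unsynchronized clocks. Both carry
five events: three pre-ramp spikes, the ramp maximum, one post-ramp
spike. `compute_flow_signal()` reduces each frame pair to row-mean
intensity profiles and takes the vertical shift maximizing their
normalized cross-correlation (a one-block block matching; compression is
axial, so only the vertical component is informative); the cumulative
sum is a position signal that tracks force. `detect_events()` finds
strict prominence-filtered peaks (minimum separation 0.5 s, plateaus
carried through so the ramp staircase contributes none); the ramp
maximum is the global maximum of the lightly smoothed signal, the three
pre-events are the last three peaks before it, the post-event the first
peak after it. `align_events()` sets the offset from the first and last
pairs (least squares) and validates the three middle pairs against a
0.7 s summed-disagreement budget; `assign_force()` then interpolates the
shifted trace at frame times, flagging frames outside the trace span
rather than extrapolating. Probe pitch/yaw are carried as metadata only;
no orientation correction of force is applied.

## Segmentation

Four stages per frame (`segment_frame()`):

1. **Region growing** from a seed: the 4-connected component of pixels
   at or below an adaptive threshold. The threshold rule (not fixed by
   the measurement procedure, therefore a documented interpretation) is the
   3×3 seed-neighborhood mean plus 0.25 of its contrast against the
   image median, which adapts to gain. Leakage (border contact or
   oversize) is an error, not a silent result.
2. **Radial refinement**: 32 equally spaced rays from the mask centroid;
   on each, the radius maximizing the outward intensity difference
   $I(r{+}1) - I(r{-}1)$ within a window of ±max(3 px, 25%) around the
   region-growing boundary radius. Plateaus of the difference profile
   resolve to their midpoint. Rays exiting the image fall back to the
   mask radius, flagged.
3. **Shape optimization** (the least-specified stage, implemented as a
   penalized per-ray adjustment): coordinate-ascent sweeps maximizing
   gradient minus $\lambda\,(r - m)^2$ with $m$ the mean of the two
   angular neighbors, $\lambda = 0.5$ by default, at most 50 sweeps.
   $\lambda = 0$ reproduces stage 2 exactly.
4. **Contour interpolation**: a periodic cubic spline through the 32
   points sampled at 2000 parameter values; a self-intersecting spline
   falls back to linear interpolation with a flag.

Area is always *interior pixel count × pitch²* — the binary-image
counting a clinical pipeline reports — not the continuous polygon area.
When the previous frame's area is below 5 mm² (near collapse), only
region growing runs: wall pixels brighten near collapse and contain the
region on their own. A seed neighborhood no darker than 60% of the image
median marks a fully collapsed lumen (area 0). The seed for the next
frame is the current mask centroid.

The **boundary band** — pixels adjacent to the final boundary whose
intensity lies within ±10% of the growing threshold — is reported in mm²
as the segmentation ambiguity at the wall.

### The resolution floor of a 32-ray contour

Two lattice effects bound what pixel-counting accuracy can be claimed.
First, even a perfect analytic circle rasterized by pixel-center
counting fluctuates around $\pi r^2$ with mean absolute error ≈1.4 px.
Second, 32 rays subsample the pixelated edge, leaving a per-frame mean
radius uncertainty of ±0.1-0.2 px, i.e. an area error of
$2\pi r \cdot 0.15 \approx$ 8-15 px² for open lumens — ≈1% relative,
measured empirically across 30 lumen sizes and insensitive to the
sampling interpolation and the value of $\lambda$. Near-collapse frames
(region growing + counting) are exact to the rendering quantum of half
a pixel, and those frames are the ones that determine the collapse
force. Tests assert exactly these two contracts; a blanket sub-2-pixel
claim for the full four-stage pipeline would not survive this floor.

## Collapse force and its uncertainty

`estimate_collapse_force()` returns the force at the first (time-order)
area sample below 0.5 mm², linearly interpolated between the bracketing
samples — the sweep is slow, so interpolation adds sub-sample precision
without changing the first-crossing semantics.

Two uncertainty components:

* **Cardiac cycle** (`cardiac_envelope_uncertainty()`): collapse can
  happen at any cardiac phase. Local minima and maxima of the raw area
  series (plateau-aware sign changes) with areas between 0.5 and 5 mm²
  are each fit with a least-squares line in (force, area); the two
  0.5 mm² crossings bound the collapse force. Extrema on the flat
  fully-collapsed tail are excluded — envelope lines extrapolate the
  oscillating descent, and the tail would flatten them. With no
  oscillation the bounds degenerate to the collapse force, flagged.
  Because the tube law approaches the threshold tangentially
  (dA/dF ≈ 0.08 mm²/N at the peak-phase crossing), the upper envelope
  line systematically stops ≈0.5 N short of the true peak-phase
  crossing; the truth there is decided by area differences of ≈0.2 px,
  below what any pixel-counting segmentation resolves. The interval
  should be read as a lower-bounded, slightly conservative band.
* **Segmentation** (`segmentation_force_uncertainty()`): the boundary
  band area (default 0.25 mm² at the collapse threshold when no
  per-frame band is available) divided by the local |dA/dF| from a line
  fit near the crossing — the force it takes to compress the ambiguous
  pixels.

The total is the cardiac half-interval plus the segmentation term.
Collapse forces under 2 N are flagged: below the minimum contact force,
image quality precludes measurement.

## Calibration and perturbations

`fit_collapse_jvp()` regresses JVP (mmHg) on supine collapse force (N)
by ordinary least squares over complete pairs — the regression direction
matches its use (predicting venous pressure from force), and
errors-in-variables are deliberately ignored. `jvp_from_tilt_angle()`
converts the recline angle at which pulsations appear into pressure via
a 10 cm water column from right atrium to neck base and
0.7356 mmHg/cmH₂O. `agreement()` reports Bland-Altman statistics of
predicted minus measured JVP. `perturbation_summary()` computes the
per-subject hydrostatic (supine − 16° tilt) and Valsalva
(Valsalva − supine) collapse-force differences over pairwise-complete
subjects, plus the ordering check Valsalva > supine > tilt.
`hydrostatic_expected_difference()` gives the tilt effect a perfect
hydrostatic model would predict, flooring venous pressure at 0 mmHg: the
IJV is exposed to atmospheric pressure transmurally and collapses rather
than sustaining negative lumen pressure.

On the bundled 27-subject table the fit gives $r^2 = 0.886$ and a mean
absolute prediction difference of 0.229 mmHg over 26 complete pairs, and
the mean Valsalva − supine difference over its 20 complete pairs is
9.34 N (a value often rounded up to "about 9.5 N" when eyeballed from a
plot; computed from the table itself it is 9.3 at one decimal).

## Waveform inversion

Over a near-constant-force window, each frame's venous pressure is the
minimizer of the squared area mismatch
$\mathrm{Cost}(P) = \lVert A_{seg} - A_{mod}(P)\rVert_2^2$
(`invert_frame()`), found by Nelder-Mead downhill simplex (relative
tolerance 1e-12, cost tolerance (0.01 mm²)², at most 200 iterations,
pressure clamped to [−200, 500] mmHg with bound hits flagged as
non-convergence). The model is monotone in $P$, so the 1-D simplex is
reliable; a property test checks it against a bisection oracle to
1e-3 mmHg on random draws.

`invert_sequence()` anchors the scale: the frame whose area is nearest
the window mean (earliest on ties) is assigned the
calibration-predicted CVP, and `calibrate_forward_model()` rescales
$A_0$ — closed-form, since the law is scale-invariant in $A_0$ — so the
model reproduces that area at that pressure. Frames are then processed
in time order, each warm-started from the previous converged pressure.
Anchoring is exact at the anchor frame by construction; the *mean* of
the waveform shifts by ≈1.15 δ when the anchor moves by δ, because the
stiff $n_1 = 10$ branch makes the pressure offset induced by an $A_0$
rescaling grow with $(A/A_0)^{10}$, which varies ≈2× across a 1 mmHg
cardiac swing. A uniform δ-shift would require a log-linear law; the
excess is a property of the model family, not of the optimizer.

`label_waveform_landmarks()` is purely descriptive: per cardiac cycle,
after pruning low-prominence flicker (<5% of range), the three tallest
maxima are labeled a, c, v and the two deepest minima x, y in temporal
order. A pure sinusoid (two extrema per cycle) is flagged unlabeled.

## Numerical and degenerate-input choices

* Tube-law bisection: 200 iterations, relative tolerance 1e-12; the
  inverse composed with the closed form is identity to 1e-8.
* Coordinates are row/col, 0-based, pixel centers at integers; polygon
  interiors count centers strictly inside (even-odd scanline).
* Single-pixel masks degenerate radial refinement to zero radii with a
  flag; duplicate contour points are deduplicated with a flag; fewer
  than 4 distinct points is an error.
* Peak detection carries slope signs through plateaus so monotone
  staircases produce no candidates; tied correlation lags resolve to
  the smallest shift so featureless frames report zero motion.
* Determinism: all randomness flows from `rng_seed` via a scoped RNG
  that restores the caller's stream; repeated generation is
  bit-identical.

## Known limitations

* The forward model is a lumped 1-D tube law, not tissue mechanics; the
  inverse loop is faithful, but absolute waveform amplitudes inherit
  the model family.
* The force-to-pressure transfer coefficient is constant; in tissue it
  varies with anatomy and probe placement.
* Segmentation accuracy for open lumens is bounded by the 32-ray
  contour resolution (~1%); claims below that are not made.
* Calibration is against JVP, itself an estimate; the package
  reproduces the published agreement, it does not validate against
  catheterization.
* DICOM input is not supported; cine I/O is uncompressed grayscale
  multi-frame TIFF with a JSON sidecar for pixel pitch and frame times.
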