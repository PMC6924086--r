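---
title: "spinetrack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spinetrack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinetrack)
```

spinetrack is the offline software core of a biomechanical spine-testing
rig. A vertebral specimen is loaded stepwise in seven modes — flexion,
extension, left/right lateral bending, left/right axial torsion and axial
compression — while four strain gauges record the applied force and two
orthogonal cameras watch markers attached to the vertebrae. The package
covers everything downstream of the hardware: synthetic test inputs, the
marker-disc detection pipeline, displacement estimation from
pseudo-speckle targets, voltage-to-force calibration, and the
instant-rigidity bookkeeping, plus a JSON-configured batch driver and a
small CLI.

This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open, so that a maintainer can tell which
behavior is physics, which is convention, and which is a calibrated
choice.

## Instant rigidity

The stiffness measure is the *instant rigidity* of a single load step:
the ratio of the applied load to the deformation it produces, not the
slope of a fitted load–deflection curve. For axial compression

$$R_c = \frac{F}{\Delta l} \quad [\mathrm{N/mm}],$$

for axial torsion through a lever arm $r$ either the angle form or, when
the camera measures the arm-tip shift $d$ instead of the angle, the shift
form

$$R_{t_1} = \frac{F\,r}{\varphi}\ [\mathrm{Nm/rad}], \qquad
  R_{t_2} = \frac{F\,r}{d}\ [\mathrm{Nm/mm}],$$

and likewise for bending with arm $l$ and angle $\alpha$
($R_{f_1} = F l / \alpha$, $R_{f_2} = F l / d$). Forces are Newton,
shifts millimetres, angles radians and arms metres, which produces
exactly the units above. Both variants are implemented
(`rigidity_torsion()`, `rigidity_bending()`, `variant = "angle"/"shift"`)
because the camera-based rig measures shifts in practice; the variant is
explicit in configuration and in the result units, and mixing variants in
a comparison is rejected.

The lever arms are laboratory geometry. They are **required
configuration with no default**: any default would silently scale every
moment-based rigidity.

A protocol run (`run_protocol()`) repeats the load sequence (ten repeats
in the reference protocol), averages the per-step rigidities within each
repeat and summarizes each mode as mean ± sample SD over repeats. A
stiffness comparison between an intact and a treated (implant-stabilized)
specimen is reported as `normalize_to_intact()`: 100 × treated mean /
intact mean, so the intact specimen reads exactly 100 %.

Degenerate inputs are errors, not numbers: zero displacement or angle,
non-positive arm, unknown mode, and unit/mode mismatches all stop with a
message.

## Strain-gauge calibration

Each gauge is calibrated by ordinary least squares on a table of
(voltage, known force) pairs, $F = a + bV$, using the closed-form
normal-equation summations

$$b = \frac{n\sum x_i y_i - \sum x_i \sum y_i}
           {n\sum x_i^2 - (\sum x_i)^2}, \qquad
  a = \frac{1}{n}\Bigl(\sum y_i - b \sum x_i\Bigr),$$

returned as a classed fit (`gauge_cal`) with `print`, `coef`, `predict`,
`summary`, `residuals` and `plot` methods. The implementation is the
summation formulas themselves; `lm()` serves only as an independent
cross-check in the test suite. A near-singular design (all voltages
equal) is refused.

`calibration_error()` audits a fit against noise-free truth as the
maximum relative force error in percent. Relative error diverges as the
true force approaches zero, so points below a force floor are excluded —
by default 5 % of the largest true force. One property of this audit is
worth stating because it is a property of least squares, not of the code:
the prediction SD at voltage $V$ is
$\sigma \sqrt{1/n + (V - \bar V)^2 / S_{xx}}$, so the *relative* error is
largest at the floor itself, and a worst-case audit over many replicates
is dominated by the behavior at the smallest admitted force. The test
suite exercises exactly this configuration.

## Marker-disc detection

Large vertebra motions are tracked through circular marker discs. The
pipeline is a fixed composition:

1. **Convolution** — Gaussian pre-smoothing (`smooth_sigma`, default
   1 px, truncated at 3σ) followed by the standard 3×3 Sobel pair;
   `edge_map()` returns the gradient magnitude
   $\sqrt{g_x^2 + g_y^2}$. Convolution uses reflective (edge-inclusive
   mirror) border padding so constants stay constant. The smoothing step
   matters: without it the edge annulus of a small disc is only ~2–3 px
   wide and breaks into arcs under any workable threshold, biasing
   centroids by 1–3 px; with σ = 1 the annulus is a closed band and
   sub-half-pixel recovery holds down to radius 4 px.
2. **Band threshold** — `threshold_band(e, t_min, t_max)` keeps pixels
   with $t_{\min} \le e \le t_{\max}$, inclusive at both ends. By default
   $t_{\min}$ adapts to 0.35 × the 99.9th percentile of the edge map (an
   absolute band can be configured); a fixed absolute default cannot
   serve scenes of different contrast.
3. **Morphological opening** — erosion then dilation by a digital disc of
   radius 1 (the 4-connected cross), with outside-frame pixels treated as
   background. Opening removes speckle-sized noise responses that the
   threshold lets through. Radius 1 rather than a larger element is
   deliberate: the object being cleaned is the thin edge annulus itself,
   and a radius-2 disc erodes it away entirely.
4. **Centroid search** — 8-connected components of at least `min_pixels`
   (default 20) pixels; each center is the unweighted mean of member
   pixel coordinates. The annulus is symmetric about the disc center, so
   its centroid is an unbiased center estimate. Components are ordered by
   descending pixel count with ties broken by center (y, x). Per-component
   averaging generalizes a global row/column average, which cannot
   separate multiple discs in one frame.

Coordinates everywhere are zero-based, x = column rightward,
y = row downward; sub-pixel centers are real-valued, and
integer-translating a mask translates every centroid exactly.

Frame-to-frame correspondence (`assemble_tracks()`) is greedy
nearest-neighbour: closest (track, detection) pairs link first, within a
maximum jump radius (default 15 px/frame); leftover detections open new
tracks. A missed detection leaves a gap rather than merging neighbours,
and a track can resume after a gap if it reappears within the jump
radius. Nothing more elaborate (Kalman filtering, global assignment) is
warranted for slow, well-separated markers.

## Pseudo-speckle displacement by Fourier fringes

Motions too small for the disc tracker are measured on pseudo-speckle
targets. If $f_2(\mathbf{x}) = f_1(\mathbf{x} - \mathbf{d})$, the DFT of
the mean-subtracted sum $s = f_1 + f_2$ is
$S(\mathbf{u}) = F(\mathbf{u})\,(1 + e^{-2\pi i\,\mathbf{u}\cdot\mathbf{d}/N})$,
so the power spectrum

$$|S|^2 = 2\,|F|^2\bigl(1 + \cos(2\pi\,\mathbf{u}\cdot\mathbf{d}/N)\bigr)$$

is modulated by cosine *interference strips* perpendicular to
$\mathbf{d}$ with a spacing of $N/|\mathbf{d}|$ frequency bins: the strip
density encodes the shift magnitude and the strip pitch the direction.
`measure_displacement()` runs the chain `sum_frames` → `power_spectrum` →
`estimate_fringes` → `displacement_from_fringes` → `resolve_sign`.

`power_spectrum()` mean-subtracts, applies a Hann window by default
(leakage control for non-periodic real footage), and zeroes the DC bin
plus a 2-bin neighbourhood.

Fringe extraction is cepstral: the 2D FFT of the log power spectrum turns
the $\cos(2\pi\,\mathbf{u}\cdot\mathbf{d}/N)$ modulation into a peak at
offset $(d_x, d_y)$, read off directly. Three measures make this robust,
each of which was added against a concrete failure mode observed on
synthetic sweeps:

* **Radial whitening.** The texture's own power spectrum has a smooth,
  radially symmetric envelope (the speckle correlation length), whose
  logarithm dominates the low-quefrency cepstrum and produces false
  peaks near the exclusion boundary even for unshifted pairs. The
  annulus-mean of the log-spectrum is subtracted first; fringes depend on
  the projection $\mathbf{u}\cdot\mathbf{d}$, not on $|\mathbf{u}|$, and
  survive.
* **3×3 peak ranking and recentering.** $\log(2 + 2\cos\theta)$ has
  harmonics at $k\,\mathbf{d}$ with amplitude $2/k$. A fundamental at a
  half-integer offset is split across bins by leakage while its second
  harmonic can land near-integer and concentrated, so single-bin ranking
  sometimes picks $2\mathbf{d}$. Candidates are therefore ranked by
  3×3-summed power (restoring the 4:1 fundamental/harmonic ratio), a
  subharmonic check steps down to $\mathbf{d}$ if a harmonic still wins,
  and the winning bin is recentered on the strongest single bin (the 3×3
  sums tie across neighbours of a concentrated peak, and an argmax tie
  otherwise lands one bin off).
* **Bounded DTFT refinement.** Sub-bin position is found by maximizing
  $|\sum L(\mathbf{u}) e^{-2\pi i \mathbf{u}\cdot\mathbf{d}/N}|^2$ over
  continuous $\mathbf{d}$ within ±0.75 bin of the winning bin, by
  alternating 1D golden-section passes with precomputed partial sums
  (each evaluation is O(N)). Unbounded simplex refinement from an
  off-by-one start can converge onto a Dirichlet sidelobe ~1.4 bins away;
  the bounded search cannot.

The no-fringe decision uses the fringe **contrast** — 3×3 peak power over
total non-DC cepstral power. The floor `eps = 0.06` was calibrated on
60-trial sweeps of 256² σ = 50 speckle: unshifted pairs measured at most
0.027 and genuine fringes at least 0.127, so 0.06 separates the two
distributions with a factor-of-two margin on both sides. The minimum
detectable shift is 2 px (one full fringe across the spectrum); smaller
shifts report zero displacement through the no-fringe path, and the
upper end is bounded by the shift generator's |d| < N/4 precondition.

Summing the frames destroys the shift sign, so the fringe direction is
known only modulo 180°. `resolve_sign()` shifts the first frame by the
two candidate vectors and keeps the sign whose copy correlates better
with the second frame; scores within 1 % of each other leave the vector
unresolved with a warning rather than guessing.

## Synthetic data: what it emulates, and what it does not

All test inputs are generated in code, seeded, and pure functions of
their parameters (`gen_speckle()`, `shift_image()`, `gen_disc_scene()`,
`gen_gauge_data()`, `simulate_load_steps()`).

* Pseudo-speckle targets are white Gaussian noise low-pass filtered with
  a Gaussian of correlation length 2 px, rescaled to the requested
  brightness SD (default σ = 50 on the 0–255 scale, the rig's target
  parameter) around mean 128 and clipped. Only σ is a rig-level
  parameter; the filtered-noise recipe is this package's stand-in for an
  unspecified texture-generation method, and results that depend only on
  σ and the shift should transfer to other textures with similar
  bandwidth.
* Rigid shifts use the spectral phase ramp with periodic boundaries
  (integer shifts are an exact grid roll; the Nyquist bin gets the real
  factor $\cos(\pi d)$ so real images stay exactly real). Real cameras
  crop at the frame edge instead of wrapping — acceptable for fixtures,
  and the reason shift-composition tests are stated over the periodic
  grid.
* Disc scenes render anti-aliased discs by linear edge coverage on a flat
  background with optional Gaussian pixel noise; the returned truth is
  the requested centers, exactly.
* Gauge records are a linear law plus Gaussian force noise; load-step
  tables apply displacement noise of 2 % of full scale by default.

Not emulated: lens distortion, perspective, illumination gradients,
sensor fixed-pattern noise, camera crop at frame edges, specimen
viscoelasticity or hysteresis, and any cadaver-specific stiffness values.
Passing the recovery sweeps therefore demonstrates that the *algorithms*
invert the *modelled* image formation and noise at the stated operating
envelope (disc radius ≥ 4 px, contrast ≥ 50, noise SD ≤ 10; shifts of
3–N/8 px on σ = 50 speckle) — not that the rig as a whole meets those
numbers on real footage.

## Numerical conventions and problem sizes

* Brightness is real-valued on [0, 255]; 8-bit quantization is an
  explicit optional step (`quantize_8bit()`).
* Reflective padding for convolution; outside-frame = background for
  morphology; inclusive threshold band; 8-connectivity for components.
* Ties: component ordering by (−count, y, x); `which.max` ties inside the
  cepstrum are neutralized by the recentering step.
* The test suite sizes were chosen to cover the operating envelope while
  keeping a full run around half a minute: 100-trial displacement sweeps
  at 256², 50 disc scenes at 96², 200 random ≤16×16 masks against
  brute-force morphology oracles, and 20-replicate calibration audits.

## Known limitations

* Displacement is planar and per camera; the two orthogonal views are
  not fused into 3D motion.
* The fringe method reports a single rigid shift per target — no
  rotation, strain, or dense displacement fields.
* Sub-2 px shifts are reported as zero rather than estimated.
* Track assembly is greedy and local; crossing markers closer than the
  jump radius can swap identities.
* The BMP reader covers uncompressed 8/24/32-bit files only, which is
  what the rig's cameras export.
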