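---
title: "vogkit: models, parameters and numerical choices"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
pipeline computes, why the defaults are what they are, what the synthetic
generator does and does not emulate, and where the design was genuinely
open.

## Image and coordinate conventions

Images are 8-bit grayscale integer matrices indexed `image[y + 1, x + 1]`.
Pixel coordinates are 0-based, origin top-left, x rightward, y downward,
and pixel `(i, j)` is centred exactly at `(i, j)` — sub-pixel results are
real-valued in this frame. Gaze sign conventions are horizontal positive
rightward (image +x) and vertical positive upward (image −y); they are
written into every data-file and calibration-file header so a silent flip
cannot survive a round-trip.

## Dark-pupil detection

Thresholding uses strict `<` (so threshold 0 selects nothing), followed by
one iteration of 3×3 morphological opening to remove salt noise, and a 7×7
closing. The closing exists because a corneal reflection that overlaps the
pupil boundary cuts a bright notch into the dark mask; closing bridges
gaps up to ~6 px (a glint of σ ≈ 1.5 px cuts ~5 px) while being the
identity on convex shapes, so an unoccluded pupil is untouched. An eyelid
cut leaves the mask convex too, so the occlusion experiments are
unaffected. Interior holes (a glint fully inside the pupil) are filled
before the boundary is extracted, so only the outer contour is fitted.

Component analysis is 8-connected; the pupil candidate is the largest
component with area in `[min_size_px2, max_size_px2]`, ties broken toward
the image centre (both choices are conventions; the underlying framework
leaves them open). The three localization methods:

* **centroid** — the arithmetic mean of member pixels. The reported shape
  degenerates to the equivalent-area circle (radius `sqrt(area / pi)`),
  a convention this package fixes since "centroid" alone defines no shape.
* **convex_hull** — ellipse fitted to the hull, with hull edges resampled
  every ~2 px so that the long chord spanning an occluded sector does not
  carry more weight than its vertex count warrants.
* **ellipse_fit** — the numerically stable split form of the direct
  least-squares conic fit (scatter matrices partitioned into quadratic and
  linear blocks; the ellipse constraint `4ac − b² = 1` enforced through a
  3×3 eigenproblem), after centring/scaling the points for conditioning.
  Axes are reported as **semi-axes**; the major-axis angle lies in
  [0, 180°), measured from +x toward +y.

On analytic boundary points the fit recovers parameters to 1e-6; on
rendered frames the limiting factor is boundary-pixel quantization, giving
~0.1 px centre error and ~1.5 % axis bias (boundary pixel centres sit up
to half a pixel inside the true contour).

## Glints and pupil–CR

Glint centres are background-subtracted intensity-weighted centroids
(weights `value − threshold + 1`): plain binary centroids waste the
sub-pixel information in a 2–3 px spot, and weighting by raw value drags
the centroid toward the background. Pupil pixels are excluded from glint
components so a glint touching the pupil boundary cannot merge with it.
The pupil−glint vector cancels global translation exactly in the model
and to < 0.05 px on rendered translation tests.

## Torsion

The iris annulus is re-derived from the tracked pupil every frame
(`r_inner = semi-major + 2 px`, width `iris_width_px`, default 40 px), so
pupil dilation changes which pixels are sampled but not the angular
indexing. Defaults `n_angles = 720` (0.5°/sample) and `n_radii = 20`
balance angular resolution against per-frame cost; bilinear interpolation
is used throughout. The angular profile is the per-angle mean over valid
radii, with an angle masked when fewer than half its radial samples are
valid (image edge, occlusion), then mean-subtracted.

Torsion is the argmax over integer-sample shifts within ±`max_shift_deg`
(default 15°) of the normalized circular cross-correlation computed over
jointly valid angles, refined by parabolic interpolation of the three
points around the peak. The measurement is declared invalid when the peak
correlation is below `correlation_threshold` (default 0.5), when fewer
than 25 % of angles are jointly valid, or when the peak saturates at the
shift limit. Because the correlation at shift k between profiles (a, b)
equals the correlation at −k between (b, a), the estimate is antisymmetric
to machine precision.

With 0.5° sampling and parabolic refinement the recovery error on the
synthetic harmonic texture stays below 0.1° noise-free — adequate, but
the parabola is the accuracy bottleneck; halving the sample step would
halve it at double the cost.

Positive torsion is counter-clockwise rotation of the pattern in the
`atan2(y − cy, x − cx)` sense of image coordinates; the mapping to
clinical extorsion/intorsion depends on which eye and camera orientation
and is deliberately left to calibration metadata. No per-frame ellipse
shape correction is applied for the projective foreshortening of the iris
at eccentric gaze: torsion measured far from primary position inherits a
small systematic error. This is a documented limitation, not a bug.

## Dual-Purkinje

P1 is the brightest spot with peak ≥ `p1_threshold`; P4 the brightest
with peak in `[p4_threshold, p1_threshold)` within `p4_search_radius`
(default 40 px) of P1. Frames with two P1 candidates within 10 % peak
intensity are flagged ambiguous rather than guessed. The thresholds
assume Purkinje-style short exposures in which the globe is dim and the
reflections dominate; on a bright-iris image a P4 threshold of 90 would
merge the background into one component, which is why the DPI test scenes
are rendered dim. Degrees conversion for the P1−P4 signal goes through
the regression calibration route, as no geometric gain is assumed.

## Calibration

Two routes:

* **Geometric eye model** — pupil centre displaced along a sphere of
  radius `radius_px`: `h = asin(Δx / r)`, `v = −asin(Δy / r)`. The
  reference centre is the per-axis median of ≥ 10 fixation samples, gated
  on RMS dispersion ≤ 5 px ("fixation unstable" otherwise); the radius
  comes from a setting (default 259.1 px ≈ 4.5 px/°, matching the
  synthetic scene) or from a known-amplitude fixation pair via
  `r = Δpx / sin(Δθ)`.
* **Regression** — per-axis least squares from a 2-D raw feature (pupil
  centre, or pupil−CR when glints are enabled) to target degrees; degree 1
  fits `h = a0 + a1·fx + a2·fy` (cross-axis term included, so axis
  rotation is absorbed; no polynomial cross-terms), degree 2 adds `fx²,
  fy²` and stays identifiable with 9 targets. Rank-deficient designs
  (collinear targets) are refused. Behavioural calibration aggregates the
  middle 50 % of each target dwell by the median.

A degree-1 regression cannot absorb the asin() nonlinearity of the
projection: at ±10° the cubic term is ≈ 0.05°. The 9-target grid used for
regression validation therefore spans ±5°, where the residual is < 0.01°;
wider ranges belong to the eye-model route, which inverts the projection
exactly. Both agree within 0.1° inside ±5°.

## Sessions, buffering, determinism

The frame buffer is a fixed-capacity ring; when full, the **incoming**
frame is rejected (preserving the temporal continuity of frames already
queued) and still produces an output row flagged `dropped`, so the data
file always has one row per grabbed frame and
`grabbed = processed + dropped` holds exactly. Pipeline exceptions flag
their row `error` — a level added beyond the base quality set to keep
`dropped` strictly about buffer overflow — and the session continues.

R executes in a single OS thread, so the "worker pool" is a faithful
scheduling simulation: frames are dispatched round-robin to n logical
workers and their completions interleaved out of dispatch order, which
genuinely exercises the reorder stage keyed on `frame_number`; stateful
pipeline updates (the torsion reference) happen in frame order. The
payoff is the contract the framework cares about: identical (video,
settings, calibration) produce byte-identical data files for any worker
count and buffer capacity. A future native-threaded backend must preserve
exactly this contract.

## Synthetic scenes: what a green test establishes

The renderer emulates the features the pipelines key on: dark elliptical
pupil (centre displaced by `radius_px·(sin h, −sin v)`, minor axis scaled
by the cosine of the eccentricity along the gaze direction), an iris disk
textured with fixed angular harmonics (k = 5, 9, 13 — pairwise coprime so
no two harmonics alias onto each other at the sampling grid and the
correlation peak is unique), bright Gaussian glints fixed in the image
(rigid camera+illuminator), an optional dimmer P4 displaced at a fixed
px/° gain, a horizontal upper-eyelid cut, and seeded additive Gaussian
noise. Default levels (pupil 20, iris 130, sclera 200, glint amplitude
250, noise σ up to 5) keep 8-bit values in range; geometry defaults
(360×360 px per eye, pupil radius 30 px, iris 80 px, radius 259.1 px)
mirror a plausible 720×540 binocular rig after the left/right split.

Deliberately **not** emulated: corneal refraction, perspective, natural
iris texture (crypts), reflections of room lights, motion blur,
interlacing, pupillary light response. A green test therefore establishes
algorithmic correctness — geometry, sign conventions, invariances,
noise scaling — not performance on any particular camera or subject.
Edges are rendered with a 1.5 px linear ramp so that the default
threshold crosses close to the true boundary; that choice makes sub-pixel
accuracy assertions meaningful rather than generous.

## Numerical conventions and degenerate inputs

* `velocity` is the central difference (half the noise amplification of
  the forward difference — RMS of i.i.d. noise is `σ·fs/√2`, the closed
  form the noise-statistics test checks); endpoints are one-sided. A NaN
  position yields NaN velocity at itself *and* its neighbours: no
  velocity claim is made where position is missing.
* Data files are tab-separated text with `#` headers (schema version,
  sampling rate, an FNV-1a fingerprint of the settings, sign
  conventions); missing values are the literal token `NaN`; numbers are
  written at full precision (17 significant digits) so write→read→write
  is byte-stable.
* Raw video is uncompressed 8-bit AVI (RIFF `DIB `, bottom-up palettized
  rows) or a binary PGM (P5) sequence — PGM rather than PNG because the
  round-trip must be bit-exact with no compression dependency. Lossy
  codecs are rejected by fourcc with the codec named.
* Ellipse normalization: if a fit returns minor > major the axes are
  swapped and the angle rotated 90°; angles live in [0, 180°).
* Settings files are flat `section.key = value` text; unknown keys are
  errors (a typo must not silently become a default), missing keys take
  defaults, and every parse error names its key.

## Known limitations

* No iris foreshortening correction for torsion at eccentric gaze.
* No glint identity tracking across frames (multi-LED rigs get a sorted
  list per frame).
* The centroid method's reported "ellipse" is an area-equivalent circle.
* Blink handling is detection-only (flagged rows); no interpolation.
* The remote protocol is line-JSON over any connection; no TCP server is
  started by the test suite, and no authentication exists.
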