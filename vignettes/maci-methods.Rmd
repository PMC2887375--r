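---
title: "Modelling muscle movement in ultrasound loops with congruent wavelet images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling muscle movement in ultrasound loops with congruent wavelet images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maci)
```

## The problem

A B-mode ultrasound loop of a working muscle is a stack of grayscale
frames, each showing the same anatomy under a slightly different
deformation. Clinically one wants to read movement structure out of such a
loop: when the tissue reverses direction (turning phases of a
dorsal/plantar flexion), how dynamic each phase is, how repeatable
successive repetitions of an exercise are, and which image regions carry
the movement. Speckle tracking answers these questions locally by
following one patch at a time; the approach implemented here answers them
globally, by modelling the whole loop at once.

The chain is: make the frames *congruent* with a 2-D discrete wavelet
transform, compress by coefficient variance into a frames x variables
table, model the table with principal component analysis, and interpret
the time-ordered scores as a movement trajectory.

## Congruence and compression

Each frame $I(x, y)$ is decomposed with a separable, periodized,
orthogonal 2-D DWT (Symlet 8 by default, depth 4 or the deepest feasible
level). Because the transform is deterministic in the frame shape and
configuration, coefficient $j$ means the same thing -- the same subband,
scale and position -- in every frame: the transformed frames are
congruent, and stacking them row-wise gives an ordinary two-way table on
which any multivariate method works.

Compression keeps the `nKeep` coefficients (default 3000) with the
largest variance *across frames*: coefficients that do not change over
the loop describe static anatomy and carry no movement information.
Sample variance (denominator $n-1$) is used; ties are broken by
coefficient order so the selection is reproducible.

Numerical choices worth knowing:

* **Periodized boundaries.** The periodized DWT is non-expansive (every
  level halves both dimensions exactly, so the full coefficient count
  equals the pixel count) and exactly orthogonal, so the inverse
  transform is the transpose and reconstruction is accurate to machine
  precision. The cost is that both frame dimensions must be divisible by
  $2^{\text{levels}}$ -- `buildFeatureTable()` clamps the depth, and odd
  dimensions must be cropped. Symmetric padding would avoid the
  divisibility requirement but is expansive and makes the coefficient
  addressing depend on the filter length; for a method whose core idea is
  a fixed, shared coefficient addressing, the non-expansive transform is
  the cleaner choice.
* **Flattening order.** Deepest approximation band first, then per level
  (deepest to shallowest) the diagonal, vertical and horizontal detail
  bands, row-major within each band. The index map stores
  (level, subband, row, col) per retained column, so loading vectors can
  be mapped back to image space.

## The principal component model

The table $X$ ($n$ frames x $p$ coefficients) is column-mean-centred and
decomposed as $X = T P^{\top} + E$ with $k$ components (default 2, the
score-plot convention). Components are extracted sequentially by NIPALS
with deflation; the start vector is the largest-variance column and each
component's sign is fixed so its largest-magnitude loading entry is
positive, which makes runs reproducible across platforms. Convergence is
declared when the relative score change drops below $10^{-10}$ (cap 500
iterations). No unit-variance scaling is applied by default: wavelet
coefficients of one image share a physical scale, and scaling would
inflate near-constant coefficients; a `scale` flag exists for other uses.

**DModX.** The distance to the model of frame $i$ is its normalized
residual standard deviation
$s_i = \sqrt{\sum_j e_{ij}^2 / (p - k)}$ over the pooled
$s_0 = \sqrt{\sum_{ij} e_{ij}^2 / ((n-k-1)(p-k))}$, with the training-set
correction $\sqrt{n/(n-k-1)}$ (the $A_0 = 1$ convention for centred
models), under which the training mean of $\mathrm{DModX}^2$ is exactly
1. The critical limit at level $\alpha$ is
$\sqrt{F_{1-\alpha}(p-k,\,(n-k-1)(p-k))}$. This is the conventional
chemometric recipe; it is stated here explicitly because different
software packages differ in their degrees-of-freedom corrections.

**Loading images.** A loading vector is placed at its coefficient
addresses in an otherwise-zero coefficient structure and inverse
transformed. Coefficients that were not retained are zero by
construction -- the loading image shows what the *model* used, not
everything the sequence contains; interpretation of fine detail near the
patch borders should allow for the spatial support of the wavelet
filters (the localization measure in `energyFraction()` dilates the
region of interest by the filter support scaled by $2^{\text{levels}-1}$
for exactly this reason).

## Reading the score trajectory

The rows of $T$ in acquisition order trace the movement.

* **Adjacent distances** (`adjacentDistances`): Euclidean distances
  between consecutive score vectors. Dynamic phases show large
  distances, holds and turning phases small ones.
* **Turning points** (`detectTurningPoints`): two operational
  definitions. The *extremum* rule smooths one score (default window 5
  frames, about 64 ms at 78.6 fps) and reports strict local extrema,
  merged under a minimum separation -- appropriate whenever the chosen
  score follows the movement monotonically, as for the pure sinusoid it
  is tested against. The *dwell* rule, the pipeline default, works in
  the full score space: a turn is a run of low trajectory speed (below
  the 0.25 quantile) across which the direction of travel reverses,
  reported at the speed-weighted centre of the run. The dwell rule is
  the more faithful transcription of "the frames change direction in
  the score plot", and it is robust to a failure mode of the extremum
  rule: when peak tissue displacement is large enough that fine-scale
  wavelet coefficients decorrelate, the trajectory bends (a horseshoe)
  and no single component is monotone in the movement near its peak.
* **Repetition segmentation** (`segmentRepetitions`): the smoothed
  score is orientation-normalised using the fact that a repetition
  starts and ends at rest (the sequence endpoints define the baseline
  side), and the sequence is split at the $n_{\text{reps}}-1$ deepest
  interior valleys, which are the returns to baseline between
  repetitions. For scores shaped like concatenated $1-\cos$ cycles this
  coincides with splitting at the deepest return-to-baseline crossings.
  The pipeline segments with a wider smoothing window (15 frames,
  roughly 190 ms) than turning detection: a boundary is a single deep
  valley, so heavier smoothing suppresses frame-level noise without
  biasing the location; near the baseline the score-displacement
  relation does not fold, so the valley is sharp.
* **Repetition similarity** (`repetitionCorrelation`): each segment's
  score is linearly resampled to a common length (repetitions differ in
  duration) and all pairs are Pearson-correlated. Linear time
  normalisation was chosen over dynamic time warping deliberately:
  warping would hide exactly the timing differences the comparison is
  meant to expose.

## The speckle-tracking reference

The reference analysis follows patches by pyramidal Lucas--Kanade: for
each seeded point, the frame-to-frame displacement minimises the sum of
squared intensity differences over a patch (uniform weight), solved by
Gauss--Newton iterations coarse-to-fine over an image pyramid, with
bilinear subpixel sampling. Defaults: 21 x 21 px window, 3 pyramid
levels, at most 30 iterations per level, termination at 0.01 px. A track
is invalidated permanently when its patch leaves the image or when the
minimum eigenvalue of the spatial gradient matrix, normalised by patch
area, falls below $10^{-4}$ (intensities are in $[0,1]$): below that
there is too little texture to solve the 2 x 2 flow system reliably. The
inner loops are compiled (Rcpp), as is usual for per-pixel image code.

On top of the point tracker sit: segmented-ROI tracking (equal bands
along the ROI's long axis, transversal displacement per band, mm when a
pixel spacing is known), whole-image grids, PCA of the tracked
coordinates (frames x 2-coordinates table -- directly comparable with
the congruent-image trajectory via `crossMethodCorrelation`), and the
pennation angle of three tracked points (angle at the middle vertex from
the normalised dot product).

## What the simulator emulates -- and what it does not

`renderSequence()` builds speckle-like texture by scattering
exponentially distributed point scatterers on a padded canvas, blurring
with a Gaussian point-spread function (sigma 1.2 px), displacing the
scatterers per frame with subpixel bilinear splatting, adding Gaussian
pixel noise, and cropping the padding. Everything is driven by one seed:
identical specs render bit-identical sequences, and the exact
displacement of every material point is returned alongside.

The default study conditions, chosen once to emulate a functional
heel-raise recording: 3 repetitions x 150 frames at 128 x 128 px
(`heelRaisePreset`), a concentric / 3-frame hold / eccentric amplitude
profile per repetition, peak deep-layer displacement 6 px, three tissue
layers with depth gains 0.4 / 0.7 / 1.0 (superficial tissue moves least,
as in depth-graded shear over a sliding aponeurosis), per-repetition
amplitude jitter with sd 0.10, noise sd 0.02, scatterer density
0.08 px$^{-1}$, and 78.6 fps frame-rate metadata matching the intended
acquisition rate. The hold is kept short so that the true turning frame
(the plateau centre) is sharp to about one frame.

Limits of fidelity, hence of what green tests prove: the simulator is
not an acoustic model -- no ray physics, no depth-dependent attenuation
or focusing, no out-of-plane motion, no probe pressure artefacts, and
speckle decorrelates only through in-plane motion. Passing tests
demonstrate that the pipeline recovers known in-plane kinematics from
speckle-textured sequences; they cannot certify behaviour under
out-of-plane motion or real acoustic artefacts, which is exactly where
real recordings are harder.

## Problem sizes and runtime choices

The package's own test and acceptance runs use the preset above
(450-frame, 128 x 128 loops), 3000 retained coefficients, 2 components,
and a 20 x 20 tracking grid for the cross-method comparison -- sizes
chosen so a complete run stays comfortable on a single CPU while every
stage still operates at realistic dimensionality. A 100 x 100 grid (the
whole-image analysis density) is supported and simply takes 25 x longer
than the 20 x 20 grid.

## Known limitations

* Frame dimensions must be even down to the configured depth
  (periodized transform); crop odd-sized inputs first.
* Turning localization degrades gracefully but measurably when peak
  displacement decorrelates the features (the horseshoe above); the
  dwell rule recovers the turns, but score-1 magnitude is then no longer
  an amplitude proxy near the peaks.
* The segmentation orientation rule assumes the recording starts and
  ends near rest; a loop cut mid-repetition should be segmented with
  explicit boundaries (`repetitionSegments`).
* DICOM and proprietary loop formats are out of scope; inputs are
  multi-page TIFF or directories of PNG/TIFF frames.
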