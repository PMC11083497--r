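---
title: "Automated thoracic aorta quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated thoracic aorta quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`aortaq` implements an automated measurement chain for the thoracic aorta in
3D CT-like volumes: segmentation of the aortic region, detection of five
anatomical landmarks (aortic root, brachiocephalic artery, left common
carotid, left subclavian, celiac artery), extraction of an
arc-length-parameterized centerline with cross-sectional frames, partition
into ascending / arch / descending sections, measurement of the maximal
average diameter per section perpendicular to the centerline, and screening
for aortic dissection by classifying cross-sectional slices of the
straightened vessel. A seeded synthetic phantom generator with analytic
ground truth stands in for clinical CT: every measured quantity can be
compared against a closed-form answer.

This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

## The phantom: analytic geometry as oracle

The phantom is a "candy-cane" tube in a single plane: an ascending limb
(default 100 mm), a half-torus arch (default radius 35 mm) and a descending
limb. The outer vessel radius along arc length $s$ is

$$ r(s) = r_0 + A \exp\!\left(-\frac{(s - s_0)^2}{2\sigma_s^2}\right), $$

with base radius $r_0$ (default 15 mm), aneurysm amplitude $A$, apex $s_0$
and width $\sigma_s$. The lumen occupies radii up to $r(s) - w$ with wall
thickness $w$ (default 2 mm), so $2r(s)$ is the *external* vessel diameter:
the quantity recovered when measuring the segmented vessel envelope, and the
convention adopted because a contrast segmentation of lumen plus wall has
exactly this outer boundary. All ground-truth diameters, the acceptance
tolerances, and the bulge examples (30 mm base diameter, 40 mm apex for
$r_0 = 15, A = 5$) are stated in this convention.

Materials follow a simple Hounsfield model: contrast lumen 300 HU
(non-contrast 40 HU), wall 50 HU, dissection flap 60 HU, graft 500 HU,
background -50 HU, plus Gaussian noise (default SD 10 HU) under the spec
seed, which makes volumes bit-reproducible. The dissection flap is a planar
sheet of default thickness 2 mm through the centerline plane over a
configurable arc-length range, splitting the lumen into two channels — a
minimal true/false-lumen model. Voxels near material interfaces are
supersampled ($3^3$ subsamples) so partial-volume intensities resemble
band-limited CT and sub-voxel diameter recovery is actually testable;
because the tube geometry is closed-form (point-to-segment and
point-to-arc distances), this costs a band of voxels, not the whole volume.
The volume box is fitted to the tube extent plus an 8 mm margin (about
$130 \times 60 \times 195$ voxels at the default 1 mm spacing).

What the phantom does *not* emulate: thoracic anatomy around the aorta
(lungs, spine, heart), branch vessels, ECG-gated motion, scanner physics,
streak or beam-hardening artifacts, and anatomical variability beyond the
parameter ranges. Passing phantom benchmarks therefore demonstrates that
the measurement chain is *internally correct* (geometry, perpendicularity,
calibration); it does not certify performance on clinical scans.

## Segmentation

Two segmenters sit behind one interface:

* **`classical_segment()`** — a deterministic intensity-prior segmenter:
  HU band covering the vessel materials widened by $3\sigma$ of the assumed
  noise, morphological closing (radius 1 voxel, which seals the thin flap so
  both lumina end up in one object), largest 26-connected component, hole
  filling. On noiseless phantoms it recovers the truth mask to Dice
  $\ge 0.98$ and serves as the deterministic oracle path so the geometry and
  diameter stages can be tested without any training.
* **`train_segmenter()` / `segment()`** — a compact 3D U-Net:
  $3^3$ convolutions, batch normalization, ReLU, filters doubling with
  depth, $2^3$ max pooling, nearest-neighbour upsampling with skip
  concatenation, per-voxel softmax head. Trained with Adam (initial learning
  rate $10^{-4}$) on voxelwise cross entropy, with window-jitter
  (random $\pm 20\%$ linear intensity rescale) and additive-noise
  (SD drawn from 0–20 HU) augmentation, on cubic patches drawn with
  80% foreground bias from volumes resampled to a uniform 2 mm working
  resolution; 20% of cases are held out for validation. The clinical-scale
  recipe is depth 5; the restaged benchmark uses depth 3 with 8 base
  filters, 32-voxel patches and up to 20 epochs — at phantom complexity this
  saturates validation Dice above the 0.93 bar. The convolution kernels and
  their gradients are implemented in C++ (gathered-neighbourhood loops);
  backpropagation is verified against numerical differentiation in the test
  suite. Inference is a single fully-convolutional pass over the padded
  volume (the "sliding window" degenerates to one window), followed by
  probability cutoff (default 0.5, configurable — only the existence of a
  cutoff is prescribed), largest component and hole filling.

The validation Dice is reported at the 2 mm working resolution, where the
tube surface occupies a large voxel fraction; it is the stricter of the two
plausible conventions.

## Landmark detection

A Q-learning navigation agent per resolution (16, 8, 4 mm): state is the
normalized $9^3$ intensity patch at the agent position, actions are six
unit-voxel moves, reward is the decrease in Euclidean distance (mm) to the
target with a terminal bonus within one voxel. The Q-function is a small
MLP (729-64-6) trained from an experience replay (capacity $10^4$,
minibatch 32, discount 0.9, $\varepsilon$-greedy 1 → 0.1 linearly over up
to 300 episodes per scale) with double-DQN targets (the online network
selects the next action, a target network refreshed every 200 steps rates
it) and a Huber loss on the temporal-difference residual — both standard
stabilizations, adopted because plain max-target MSE Q-learning converged
erratically across seeds at this episode budget. Half of the training
episodes start uniformly at random; the other half start within four
voxels of the target. This curriculum is a deliberate addition: the
coarse-to-fine hand-off only ever queries the fine agents near the target,
and purely uniform starts spend most of a 300-episode budget far from it.

Detection runs the coarsest agent from several random starts; each finer
agent runs from the same number of starts jittered around the previous
estimate. Terminal positions at every scale are aggregated by geometric
median (Weiszfeld), which discards stray rollouts (how the clinical system
aggregates starts is unspecified; per-scale median aggregation is this
package's choice). Greedy rollouts terminate when the agent oscillates
between two adjacent voxels; the midpoint is returned, giving half-voxel
precision at the finest scale. Rollouts that exhaust the step limit are
flagged low-confidence rather than raised as errors.

Because phantoms have no branch vessels, the phantom landmark definitions
anchor the three arch landmarks at arch-angle fractions 0.25 / 0.50 / 0.75
and put the root and celiac landmarks at the centerline ends; the section
partition they induce follows the standard reading convention (ascending
ends at the brachiocephalic origin; descending starts at the left
subclavian). Two non-learned providers — the ground-truth pass-through and
a mask-topology provider (tube ends from the caudal slices, arch anchors
from tangent-to-vertical angle crossings at 45°) — are first-class, so the
downstream stages never depend on RL convergence.

## Centerline and frames

The centerline is the shortest path on the 26-neighbourhood voxel graph of
the mask between the root and celiac landmarks (snapped to the mask within
10 mm), with edge weight equal to the physical step length divided by the
medialness factor $1 + \mathrm{EDT}^2$ (exact Euclidean distance transform,
in mm — computed by the separable squared-distance algorithm). Dividing by
medialness keeps the path on the medial axis; multiplying by step length
(a deliberate refinement of the plain $1/(1+\mathrm{EDT}^2)$ cost) keeps
diagonal and axial moves metrically comparable. The voxel path is smoothed
by a moving average (window 5), resampled at a uniform 2 mm arc-length
step, and equipped with rotation-minimizing frames: tangents by central
differences, in-plane vectors by parallel transport (Rodrigues rotation
between consecutive tangents), seeded with an arbitrary vector orthogonal
to the first tangent. The test suite asserts orthonormality, absence of
frame flips (< 15° between consecutive in-plane vectors at 2 mm steps),
rotation equivariance, and arc-length recovery within 2%.

## Diameters

At each centerline sample the mask is resampled on the local cross-sectional
plane (default 80 mm window, 0.5 mm in-plane step, nearest-neighbour — the
diameter is a property of the segmentation, not of the HU values), the
in-plane connected component containing the centerline point is kept, and
chords through the component centroid are measured at 90 uniformly spaced
angles (every 2°). The **average diameter** is the mean of these chords:
rotation-robust, equal to the true diameter on circles, strictly between
the two axes on ellipses. "Average diameter" is not further specified in
the clinical description; centroid-chord averaging was chosen over
min/max-axis averaging and equivalent-area diameter, and the extractor is a
plain function so alternatives can be swapped. On dissection phantoms the
measured contour is the outer envelope of both lumina (the flap is interior
to the component).

Per section (ascending and descending; the arch profile is computed but not
reported as a maximum, mirroring the two-number clinical output), samples
within 5 mm of a section boundary or of the centerline ends are excluded —
partition jitter of a landmark by one sample must not relocate a maximum —
and the maximum of the profile with its arc-length location is reported.

Geometry and diametry run by default on the mask resampled to 2 mm, the
same working resolution as the clinical pipeline; measurement tolerances in
the tests are stated as max(1 voxel, 5%) at that resolution.

## Dissection screening

The volume is straightened along the centerline (slices every 2.0 mm,
1.0 mm in-plane, 80 mm window; frames linearly interpolated between
centerline samples and re-orthonormalized), each slice masked to its
in-plane aortic component. Each valid slice yields 18 features: area,
equivalent diameter, eccentricity, HU mean/SD/skewness/excess kurtosis, an
8-bin normalized histogram over a fixed -100..500 HU range, the maximum
dark-ridge filter response (a pixel darker than both flanking pixels at
offset 2 along any of four orientations — a membrane detector), the
fraction of pixels more than 50 HU below the component median, and the
variance of mean HU over five concentric rings. A flap raises the ridge
response, dark fraction, SD and ring variance; all features are cheap,
deterministic and CPU-only, and the extractor sits behind a function
boundary so a learned embedding could replace it.

Features are standardized on the training set and fed to an RBF-kernel SVM
with probability calibration (`e1071`); cost and kernel width are selected
by seeded 3-fold cross-validated grid search
($C \in \{1, 10, 100\}$, $\gamma \in \{0.01, 1/18, 0.25\}$). Slice labels
derive from the phantom's dissected arc-length range. Patient-level
pooling is the mean of the top-$k$ slice probabilities with
$k = \max(3, \lceil 0.1\,n \rceil)$ — a compromise between max-pooling
(noise-fragile) and mean-pooling (diluted by short dissections) — with a
0.5 decision threshold; both are configurable. Results with fewer than 3
valid slices are flagged indeterminate. Classifiers are trained per
intensity regime; the shipped benchmark uses the contrast regime, where a
60 HU flap in a 300 HU lumen is the realistic high-contrast presentation.

## Agreement statistics

* **ICC(2,1)** — two-way absolute-agreement single-rater intraclass
  correlation from the ANOVA mean squares,
  $(\mathrm{MSR}-\mathrm{MSE}) / (\mathrm{MSR} + (k-1)\mathrm{MSE} +
  k(\mathrm{MSC}-\mathrm{MSE})/n)$ with $k = 2$; interpreted as < 0.5 poor,
  0.5–0.75 moderate, 0.75–0.9 good, > 0.9 excellent. Zero total variance is
  defined as ICC 1 with a degeneracy flag. Cross-checked against
  `stats::aov` mean squares to $10^{-10}$.
* **Bland–Altman** — bias = mean of auto − manual; limits of agreement
  bias $\pm 1.96 \cdot$ sample SD.
* **Wilcoxon signed-rank** — zeros dropped (flagged), mid-ranks for ties;
  exact two-sided p (doubled smaller tail) from the generating-function
  distribution of the positive-rank sum for up to 25 pairs — equal to full
  $2^n$ enumeration, which the tests verify — and a tie-corrected,
  continuity-corrected normal approximation beyond.
* **Spearman** — Pearson correlation on mid-ranks.
* **Error summaries** — systematic error auto − manual, absolute error its
  magnitude; medians with linear-interpolation quartiles (type 7);
  Kolmogorov–Smirnov normality of the differences against a fitted normal
  (fitted parameters, so the p-value carries the Lilliefors caveat, which
  the output flags).
* **Diagnostic metrics** — sensitivity, specificity, accuracy with exact
  Clopper–Pearson intervals. Clopper–Pearson was fixed as the CI method
  because it reproduces the published sensitivity interval for 37/42
  (74.4–96.0%) to the printed decimal, which Wilson does not.

## Numerical choices and degenerate inputs

* Quartiles: linear interpolation (R type 7), documented so IQRs are
  reproducible.
* In-plane component: if the centerline point lands on a background pixel
  (possible on a flap), the nearest labelled pixel within 3 mm is used;
  otherwise the slice is a recorded measurement gap, not an error.
* Landmark snapping: a landmark outside the mask snaps to the nearest mask
  voxel within 10 mm, else the stage errors by name.
* Chord measurement places the boundary half a sampling step beyond the
  last inside sample; ray sampling runs at half the in-plane step.
* Coordinates are physical millimetres throughout; voxel indices are
  0-based; world = index · spacing + origin.
* Seeds: every stochastic component (phantom noise, cohort draws, training
  splits, initialization, patch draws, epsilon-greedy, fold assignment,
  start positions) flows from explicit integer seeds; fixed seed implies
  bit-identical cohorts and reproducible training.

## Problem sizes in the shipped benchmarks

The restaged benchmarks run on a 40-case mixed cohort (1 mm voxels,
tight-fitting boxes): the segmentation benchmark trains depth 3 / base 8
for 16 epochs (one 32-voxel patch per training case per epoch, 32 training
/ 8 validation cases); the landmark benchmark trains 300 episodes per scale
on 32 cases and evaluates 8 held-out cases with 5 starts; the dissection
screen uses a 60-case cohort (50% prevalence, 40 train / 20 test). These
sizes were chosen as the smallest at which the benchmarks are stable
under seed changes.

## Known limitations

* Phantom realism limits (above): results certify the measurement chain,
  not clinical performance.
* The descending terminus is the celiac landmark; clinical manual reading
  measures to the diaphragm. On phantoms the two coincide by construction;
  on real data they would not.
* The RL landmark stage is best-effort at desk scale: convergence within
  its episode budget is seed-dependent in general, which is why the oracle
  and mask-topology providers exist and all downstream stages are tested
  against them.
* The dissection classifier sees only phantom flap geometry; thrombosed
  false lumina, intimal calcification and motion artifacts are outside the
  generator's vocabulary.
* `straighten()` assumes frames vary smoothly between samples; a degenerate
  interpolated frame skips the slice and records it.
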