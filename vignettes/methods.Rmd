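---
title: "Methods: post-stroke OCT-angiography analysis with strokeangio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-stroke OCT-angiography analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeangio)
```

## The problem

After a targeted photothrombotic stroke in the mouse cortex, the
microvasculature reorganizes: regenerated capillaries in the ischemic
penumbra grow preferentially toward the lesion, and capillary stalling —
transient interruption of red-blood-cell flow in single capillary
segments — becomes more frequent. Both phenomena are visible in
time-resolved OCT angiography (OCT-A), a label-free technique that
derives vascular contrast from the temporal decorrelation of the complex
OCT signal between repeated B-scans: moving red blood cells change the
phase and amplitude of the backscattered light, static tissue does not.

`strokeangio` implements the full analysis chain on top of reconstructed
complex B-frames:

1. **Angiogram construction** — global-phase-fluctuation (GPF)
   correction of repeated B-frame pairs, complex-difference
   decorrelation, 3-D Gaussian smoothing, series averaging, quality
   filtering, and en-face maximum-intensity projection (MIP).
2. **Vessel enhancement** — tubeness and Frangi filtering, binary
   masking, and skeleton-based extraction of the capillary segment
   graph.
3. **Orientation analysis** — structure-tensor local orientation and
   coherence, a synthesized lesion-direction map, and the distribution
   of capillary orientation relative to the ischemic center.
4. **Lesion quantification** — segmentation of the avascular lesion and
   day-8-normalized longitudinal area trajectories.
5. **Stalling analysis** — per-segment intensity traces, stall-event
   detection, stalling event density, stall incidence, and the
   event-count distribution.
6. **A synthetic-data generator** that emulates the acquisition, so
   every stage is verifiable against known ground truth without any
   external data.

## Angiogram model

B-scans are repeated twice at each slow-axis position. Writing the two
complex frames as $A(z,x)$ and $B(z,x)$, sub-pixel bulk motion between
the repeats multiplies $B$ by a global phasor $e^{i\varphi}$. Because
flowing blood occupies only a small fraction of the tissue, $\varphi$ is
estimated from the phase of $\sum_z A \cdot \overline{B}$ — static
scatterers dominate the sum — per A-line by default (`correct_gpf()`,
`scope = "aline"`), which also absorbs line-to-line jitter. After
correction, the decorrelation cross-section is the complex-difference
magnitude $|A - B|$, which responds jointly to phase and intensity
change and is zero on static tissue. The literature this analysis
follows cites a phase-and-intensity-difference statistic without
reproducing its formula; the complex difference is this package's
concrete choice, and a `channels = "split"` option exposes separate
$|\Delta\phi|$ and $|\Delta I|$ images for diagnostics.

Volumes are smoothed with an isotropic 3-D Gaussian ($\sigma$ = 1 px),
averaged over the retained frames of a series (the protocol keeps the
first 60 motion-artifact-free volumes; averaging raises SNR by about
$\sqrt{60}$), and flattened by MIP over the focal plane ±15 px. The
manual rejection of motion-corrupted volumes is replaced by a
deterministic rule: a frame is discarded when its mean intensity
deviates from the series median by more than 5 MADs; an explicit
keep-list overrides the rule when human judgement is available.

## Orientation relative to the lesion

Local orientation is computed from the structure tensor
$J = G_{\sigma_w} * \begin{pmatrix} I_x^2 & I_xI_y \\ I_xI_y & I_y^2
\end{pmatrix}$ with Gaussian-derivative gradients at
$\sigma_g$ = 1 px. The minor eigenvector of $J$ points along coherent
structure, giving $\alpha = \tfrac{1}{2}\,\mathrm{atan2}(-2J_{xy},\,
J_{yy}-J_{xx})$ in $[-\pi/2, \pi/2)$ (undirected, measured from the x
axis with y pointing down), and coherence
$(\lambda_{max}-\lambda_{min})/(\lambda_{max}+\lambda_{min})$. The
window $\sigma_w$ defaults to 3 px: calibration against the synthetic
generator's ground truth showed that a 3-px window pools orientation
along a capillary and recovers fully radial scenes at an aligned
fraction of ~0.93 versus ~0.90 for a 2-px window, while leaving
unaligned scenes at the uniform baseline (~0.15 measured, 1/6 ideal).

The direction from each pixel to the lesion center (mod $\pi$) forms the
synthesized map $\beta$; the quantity of interest is
$\theta = \alpha - \beta$ wrapped into $[-\pi/2, \pi/2)$, and the
headline statistic is the **aligned fraction**: the proportion of
vessel-masked pixels with $|\theta| \le \pi/12$ (±15°, ~0.26 rad). A
uniformly oriented network gives 30°/180° = 1/6.

Two weighting schemes are offered because the unit of replication is
genuinely ambiguous: the primary histogram weights pixels (as masking-
based analyses effectively do), while `weight = "segment"` contributes
one value per capillary segment — the principal axis of its skeleton
chain relative to $\beta$ — which is the right unit for distribution-
level inference such as the chi-square uniformity check: pixels of one
segment share a single orientation, and the tensor window additionally
couples neighboring pixels, so pixel-level counts are far from
independent. The lesion center defaults to the centroid of the lesion
mask, with a manual override.

## Lesion segmentation

The photothrombotic lesion appears as an extended dark, avascular region
on en-face angiograms. The reference procedure in this field is manual
delineation; `segment_lesion()` is a deterministic surrogate (and
`load_manual_lesion()` keeps the manual path authoritative). The
surrogate smooths the en-face map (σ = 5 px) so inter-capillary gaps
are filled by smeared vessel signal while the lesion stays at the
parenchyma level, thresholds at 0.35 of the way between the 2% and 75%
intensity quantiles, and applies a morphological **opening** (radius
4 px) rather than a closing: a disk-like lesion is invariant under
opening, while thin dark bridges to chance vessel-sparse pockets are
cut instead of annexed (closing was tried first and inflated small
lesions by large factors). The lesion is then the connected component
with the largest *integrated darkness* (depth below threshold summed
over the component) — a real lesion is both extended and deep, whereas
pockets are shallow — followed by hole filling and a 1-px erosion that
compensates the outward edge bias a blurred edge shows at a
sub-midpoint threshold. A candidate whose integrated darkness is below
3% of (image area × inter-quantile spread) is declared "no lesion";
on the default 128×128 grid this makes disks below roughly 24 px radius
undetectable, a deliberate floor that keeps lesion-free baselines clean.

Longitudinal trajectories normalize each depth's area by its value at a
reference day (day 8, the first session where the lesion fits the field
of view), and the depth-pair scatter data (area at the deeper plane
versus the shallower) supports the depth-ordering comparison.

## Stalling events

A stalled capillary segment disappears into the background on the
angiogram frame in which its flow is interrupted. For each graph
segment, `segment_traces()` records the per-frame mean intensity over
the 1-px-dilated chain and a local background from a surrounding
annulus (3–6 px, vessel pixels excluded — robust to illumination
gradients). A frame is flagged stalled when the segment mean falls to
within `drop_ratio` (default 0.25) of the background:
$\bar I_f \le b_f + 0.25\,(\tilde I - b_f)$, where $\tilde I$ is the
segment's median intensity across frames (a robust stand-in for its
flowing level while stalls are a minority of frames; a segment whose
median shows no contrast over background is excluded as degenerate).

Because consecutive volumes are ≥10 s apart, a flagged frame is an
independent observation: each one counts as one **stalling event**, and
runs are *not* merged (a `merge_runs` option exists but is off by
default). Aggregates follow the field's definitions: **stalling event
density** = total events / vascularized area (vessel-mask pixels outside
the lesion; segments lying mostly inside the lesion are excluded from
both numerator and segment counts), **stall incidence** = stalled
segments / total segments, plus the histogram of segments by event
count. Density is reported per px² and, when voxel geometry is known,
per mm².

## The synthetic generator

`scene_spec()` + `generate_scene()` emulate the study's acquisition: a
1 mm × 1 mm cortical patch (full grid 450 × 500; default 128 × 128 so a
complete pipeline runs in seconds, with the full size available by
argument), straight capillary segments of 10–20 px length dilated to
3-px-wide tubes (≈6 µm at ≈8 µm/px on the default grid — in the right
range for capillaries), an optional avascular disk lesion that tubes
may abut but never cross, and a controllable fraction of segments laid
exactly along the local direction to the lesion center (the rest
uniform in $[-\pi/2,\pi/2)$). `render_bframe_pair()` produces complex
repeated B-frames: static tissue has a fixed speckle field with
amplitude comparable to vessels (static brain tissue scatters strongly;
it cancels on the angiogram only because the repeats are identical —
this is also the premise of the GPF estimator), vessel voxels are
redrawn independently per repeat (full decorrelation), additive
circular complex Gaussian noise, and a unit-modulus bulk-phase factor
on the second repeat. `render_angiogram_series()` renders en-face
frames directly, with per-segment Bernoulli(`stall_prob`) stall frames
painted at background level and logged as ground truth; one frame
stands for one ≥10 s volume, so sub-frame stalls are not modeled.

What the generator deliberately does **not** emulate: physical speckle
statistics (coherence length, confocal PSF), flow-speed-dependent
decorrelation, vessel curvature and diameter variation, inter-volume
motion, and depth-dependent signal loss. Passing tests therefore
demonstrate that the *algorithms* recover known structure under
realistic geometry and noise — not that the pipeline is validated on
real tissue.

## Numerical choices and degenerate inputs

* All orientations are undirected, in $[-\pi/2, \pi/2)$; wrapping is
  `((x + pi/2) %% pi) - pi/2`. The ±π/2 boundary is a single
  orientation; tests compare angles circularly.
* Gaussian-derivative kernels are discretely renormalized so that
  constants are annihilated exactly and ramp/quadratic responses are
  exactly 1; filter responses below 1e-10 of the image scale are
  clamped to zero so flat regions give identically zero vesselness.
* Frangi's structureness scale `c` defaults to half the maximum Hessian
  norm per scale; β = 0.5; scales {1, 1.5, 2} px; tubeness σ = 2 px
  (the vessel-radius estimate). Filter parameters are unstated in the
  source protocol; these are standard literature defaults, all
  configurable.
* Otsu thresholding (on the enhanced image's own range) is the default
  masking rule for reproducibility; a fixed threshold is available.
  Masks are recomputed per timepoint, and thresholds are recorded.
* Skeletons use Zhang–Suen thinning with 8-connectivity; segments
  shorter than 5 px are pruned as spurs. Chains include their terminal
  node pixels, so incident segments share node pixels.
* A zero-energy A-line gets GPF phase 0 and a log message; an all-zero
  B-frame pair, an empty mask, an empty skeleton, zero kept frames and
  a missing reference day are errors or flagged warnings rather than
  silent results.
* Seeds: every stochastic function takes an explicit seed (or a spec
  carrying one) and restores the caller's RNG state; identical spec +
  seed is bit-identical output.

## Problem sizes used in the tests

The test-suite and the acceptance script run on 128×128 scenes with
~200 segments (orientation and lesion analyses), 40 non-touching
segments × 60 frames (stalling), 40 seeds for the uniformity property,
and 100 seeds for bulk-phase recovery; these sizes give binomial/Monte-
Carlo error bars comfortably inside the tolerances being checked while
a full run stays in the tens of seconds. The full 450×500 geometry is
exercised through the same code paths via configuration.

## Known limitations

* Small lesions (below ~24 px radius on the default grid) fall under
  the no-lesion floor, and lesions of 25–30 px can annex adjacent
  vessel-sparse pockets (up to ~+20% area) in dense networks.
* The aligned fraction saturates around 0.9–0.95 even for perfectly
  radial scenes: crossings and segment endpoints contribute pixels with
  mixed orientation.
* Stall detection assumes a segment flows in the majority of frames; a
  capillary stalled more than half the series would be scored as
  degenerate rather than heavily stalled.
* No inter-volume registration is performed; real series with drift
  would need alignment upstream.
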