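---
title: "Methods: ultrasound augmentation, imbalance balancing, and annotation auditing"
author: "usaug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultrasound augmentation, imbalance balancing, and annotation auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usaug)
```

## The problem this package addresses

Building a supervised detector for ultrasound findings — here, thyroid
nodules graded with TI-RADS categories 2, 3, 4A, 4B, 4C and 5 — runs into
two coupled obstacles. First, expert annotation is the bottleneck: a
practical workflow has junior physicians draw first-pass boxes and senior
physicians review them, and one wants to replace the first pass with model
pre-annotation as early as possible. Second, clinical class frequencies are
wildly imbalanced (the three common categories can hold ~96% of nodules),
which cripples training on the rare, clinically most interesting
categories. `usaug` implements the data-side machinery of such a workflow:
ultrasound-specific augmentation, imbalance-driven augmentation planning,
reproducible batched splitting, and quantitative auditing of any annotation
set against a gold standard. Detector training itself is out of scope; its
settings are only recorded (`default_config()$trainer`) so a prepared
dataset ships with its training provenance.

## Image and label model

Images are 8-bit grayscale matrices (`gray_image`), row-major, origin
top-left — B-mode frames without Doppler overlays. Labels are YOLO
normalized center boxes `(class, cx, cy, w, h)` with an optional confidence
(absent for human annotators). Box centers live in $[0,1]$ and extents in
$(0,1]$; boxes are allowed to protrude past the frame (rotation produces
such boxes) and are clipped at evaluation/render time, not at parse time.
Malformed label lines are an error with a line number, never silently
dropped: in an auditing tool, a swallowed annotation is a corrupted result.

## Augmentation operators

All operators are pure functions of (image, parameters): identical inputs
give byte-identical outputs. Randomness lives exclusively in the planner
that samples parameters. This split is what makes every produced dataset
re-derivable from its JSON sidecar of specs.

**Defocus.** Out-of-focus regions of a sound field blur; we emulate this
with a discrete $5\times5$ kernel $w_{ij} \propto
\exp\!\big(-(x^2+y^2)/(2\sigma^2)\big)$, renormalized to unit sum. The
continuous prefactor $1/(2\pi\sigma^2)$ normalizes the *integral*; on a
truncated grid only renormalization preserves mean brightness, which is the
point of that coefficient. Convolution uses stride 1 and **replicate
padding**: zero padding would paint a dark frame onto every augmented
image, a systematic artifact no real transducer produces. $\sigma$ is
sampled from $U[0.5, 2.5]$ by default — visible blur that does not destroy
nodule structure; configurable.

**Acoustic shadow, fast form.** A rectangle with opacity $\alpha \in
(0,1]$: $out = (1-\alpha)\,in$ inside, untouched outside. Box size is
sampled at 5–30% of the frame side and $\alpha \in [0.4, 1.0]$ — strong
enough to plausibly mask a nodule. Occluded nodules *keep their labels*:
the augmentation exists to teach robustness to exactly this masking, so
deleting the label would defeat it.

**Acoustic shadow, graded form.** A physics-inspired (not
physics-accurate) field model of the shadow behind a high-impedance
occluder: marching front by front along the beam,
$$s_{k+1} = (1-\rho)\cdot \mathrm{blur}_{1D}(s_k;\ \sigma_d), \qquad
s \leftarrow \max(s, \text{occluder}),$$
with $\rho$ the per-front decay and $\sigma_d$ the per-front lateral blur
sd (diffraction refilling the shadow from its flanks). Behind a full-width
occluder the maximum attenuation at depth $r$ is exactly $(1-\rho)^r$; with
$\sigma_d = 0$ the scheme reduces to a sharp geometric projection. The 1-D
blur uses zero padding so per-front attenuation mass can only shrink —
giving monotone decay by construction. These three closed-form behaviors
are what the tests pin down; no published equations exist for the
real phenomenon at this level of abstraction, so the scheme is validated
qualitatively (spreading + fading), not against measured fields. Beam
directions: axis presets are exact grid flips/transposes; diagonal
directions go through grid rotation and inherit interpolation smoothing.

**Sidelobe artifact.** Off-axis lobes superimpose a faint displaced copy of
the anatomy. Emulated as a convex blend $out = (1-\alpha) I + \alpha\,
\mathrm{rot}(I, \theta)$ with $\alpha \in [0.1, 0.35]$ and $|\theta| \le
10^\circ$; convexity keeps intensities in range before clipping. Labels
unchanged — the true anatomy stays put, only a ghost is added.

**Brightness/contrast and rotation.** Affine intensity remap
$\mathrm{clip}(g\cdot in + b)$ (contrast pivots at mid-gray 128). Rotation
is bilinear about the center with zero fill (ultrasound background is
black), canvas size unchanged; each box becomes the axis-aligned hull of
its four rotated corners, computed in pixel space so non-square frames are
correct, clipped to the frame, and dropped if the surviving area falls
under 25% of the original (a nodule mostly out of frame is not a training
instance). "Small angle" is nowhere quantified in the source protocol;
$\pm 10^\circ$ is our default, exposed in configuration.

## Imbalance-driven balancing

Per class, the target count is $\max_c n_c / \texttt{target\_ratio}$
(default ratio 3), so the ratio directly bounds the final max/min
imbalance. Images containing an under-target class are sampled with
replacement; each selected copy gets **exactly two distinct ops** (using
many augmentations per image has been reported counterproductive), with
fresh parameters each time, until every class's projected count passes its
target or a cap of 10 copies per original bounds dataset growth. The
projection accounts for rotation's possible box drops by running the real
box transform, so executed class counts equal the projection *exactly* — a
tested invariant. Since an image carries all its nodules, common classes
co-occurring with rare ones grow too; this mirrors what happens in real
datasets balanced this way. Balancing can be run per portion (so each
train/val portion stays balanced independently) or on a whole manifest;
augmented copies always inherit their source image's portion, which is
required to keep the train/validation split leakage-free.

The composition order (second op applied to the first op's output) is
recorded per output image in a JSON sidecar, making every augmented file
auditable and re-derivable.

## Batched splitting

The id list is shuffled once under the given seed and chunked into 25
near-equal portions (remainders go to the earlier portions,
deterministically). Batch $N$ uses exactly the first $5N$ portions; within
every 5-portion block the *last* portion is validation. This rule produces
the 4:1 train/validation ratio and — because blocks are fixed — earlier
batches' assignments never change as $N$ grows. On 8,500 images this yields
the documented sizes: 1,360 train / 340 validation originals at batch 1,
6,800 train at batch 5, and 8 of the first 10 portions training at batch 2.
The exact placement of validation portions within a block is not documented
in the source protocol; "last of each block" is the simplest rule
satisfying both stated properties.

## Annotation auditing

Model candidates are filtered at confidence 0.1 (deliberately low, for
nodule sensitivity) and deduplicated with *class-agnostic* greedy NMS at
IoU 0.7 — one anatomical structure should yield one box even when the
detector hedges between categories. Candidates are then matched to gold
boxes greedily by descending IoU, **class-blind** (class disagreement is
the signal the confusion matrix measures, so it must not block a spatial
match), requiring IoU ≥ 0.5, each box used once, ties broken by row order.
The matching threshold is a flag; 0.5 is standard detection practice, as
the pairing rule between first-pass and reviewed boxes is otherwise
undocumented.

The confusion matrix is $(C+1)\times(C+1)$: a background row collects
missed gold nodules and a background column collects false detections
(vessels, lymph nodes, parathyroid glands annotated as nodules). Per-class
accuracy divides the diagonal by the gold column total — so a missed nodule
counts against its class; the alternative (conditioning on matched pairs
only) is computable from the matrix by excluding the background row.
Overall accuracy is the summed diagonal over all gold nodules, identically
the gold-count-weighted mean of per-class accuracies; the identity is
asserted in tests at $10^{-12}$.

mAP follows the standard convention: per class, detections ranked by
confidence, greedy per-image matching to unused same-class gold at each IoU
threshold, all-points (envelope) interpolation of the precision–recall
curve, unweighted mean over classes with ≥ 1 gold instance; mAP50-95
averages thresholds 0.5 to 0.95 in steps of 0.05. The detector's internal
convention is unspecified in the source protocol; all-points is documented
here as our choice.

## Synthetic phantoms: what they do and do not establish

`generate_phantom` emulates only the *statistical shape* of a nodule
dataset: fan-sector support (apex top-center, as on a convex probe),
multiplicative unit-mean gamma speckle (sd = `speckle_scale`, default 0.25;
0 disables noise), and elliptical nodules whose class sets a stylized
intensity offset and border softness (higher categories darker and more
ill-defined). Default class probabilities (0.25, 0.45, 0.257, 0.02, 0.015,
0.008) reproduce the ~95.7% / 4.3% common/rare split. Labels are the exact
ellipse bounding boxes, so box-tightness is true by construction and
verifiable to the pixel. `corrupt_labels` resamples classes from a
row-stochastic error matrix and injects misses/false positives, modelling a
first-pass annotator with *known* error structure.

A green test on phantoms establishes that the *computations* are correct —
e.g., that the audit pipeline recovers an injected 6×6 error matrix within
multinomial 3σ over $10^4$ nodules, conditioning on matched pairs so the
check stays exact under nonzero miss rates. It does **not** establish
clinical realism (no anatomy, no TI-RADS morphology, no inter-device
variability) nor anything about detector accuracy on real data: published
headline numbers of pre-annotation studies (e.g., 76.9% human accuracy)
require private hospital images and trained weights, and this package makes
no claim about them. Phantom frames for the large recovery test are
rendered at 48 px to keep the suite inside a single-CPU time budget; every
statistical contract involved is resolution-invariant.

## Numerical and design choices

* Intensities are clamped and rounded once per operator, at the end, via a
  single funnel (`[0,255]` invariant holds by construction).
* Bilinear rotation uses inverse mapping; exact identity at 0° (and the
  sidelobe blend with itself is exactly the identity), verified bytewise.
* Greedy matching ties: candidate row order, then gold row order —
  deterministic across platforms.
* All RNG flows through R's default Mersenne-Twister via explicit seeds;
  CLI commands that sample refuse to run without `--seed`.
* Repeating the same op pair on the same image with different parameters is
  allowed (each copy's specs are recorded); whether real workflows forbid
  this is undocumented, and recording makes the choice auditable.
* Degenerate inputs fail loudly: empty shadow regions after clipping,
  occluders outside the grid, class ids out of range, unknown configuration
  keys (reported with their dotted path).

## Known limitations

* The graded shadow model is a phenomenological front-marching scheme;
  no refraction, reverberation, frequency dependence, or true impedance
  physics. Its zero-padded lateral blur makes closed-form decay exact only
  away from the grid border (tests probe the interior and bound the rest).
* Sidelobe ghosts are rotations only — real sidelobe artifacts can also be
  laterally displaced; a displacement term would be a natural extension.
* Balancing treats every nodule of a class as equally informative; it does
  not consider nodule size, image quality, or duplicate near-identical
  frames.
* mAP uses one convention; detectors reporting their own interpolations
  will differ at the second decimal.
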