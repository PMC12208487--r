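# usaug — ultrasound-specific augmentation and annotation auditing for detection datasets

`usaug` prepares and audits object-detection datasets of grayscale
ultrasound images (YOLO label format) for "AI pre-annotation" workflows, in
which a detector trained on each batch of reviewed images pre-annotates the
next batch for human correction. It is aimed at groups building medical
image databases who need (a) physically motivated augmentation to fight
severe class imbalance — e.g., thyroid nodules annotated with TI-RADS
categories 2, 3, 4A, 4B, 4C, 5, where the three common categories can carry
~96% of all nodules — and (b) quantitative auditing of any annotation set
(junior physician or model) against a senior-reviewed gold standard. The
detector itself (training, GPU inference) is deliberately out of scope; the
package produces and audits the datasets around it.

## What it implements

**Ultrasound-specific augmentation operators** (pure, seeded transforms of
an image + its boxes):

* *Simulated defocus* — convolution with the 5×5 Gaussian kernel

  `G(x, y) = 1/(2πσ²) · exp(−(x² + y²)/(2σ²))`

  renormalized to unit sum on the discrete grid, stride 1, replicate
  padding; σ is randomized to vary blur strength.
* *Acoustic shadow* (fast form) — a rectangle darkened by opacity α:
  `out = (1 − α)·in` inside the region, emulating the signal void behind a
  calcification while keeping the occluded nodule's label.
* *Acoustic shadow* (graded form, `propagate_shadow`) — a front-marching
  field model: each front perpendicular to the beam is the previous front
  laterally blurred (diffraction, rate = 1-D Gaussian sd per row) and faded
  geometrically (decay ρ per row gives max attenuation `(1 − ρ)^r` at depth
  `r` behind a full-width occluder). Renderable as contour maps or applied
  per-pixel as `out = in·(1 − attenuation)`.
* *Sidelobe artifact* — a faint ghost: the image blended with a small-angle
  rotated copy of itself, `out = (1 − α)·I + α·rot(I, θ)`.
* *Conventional ops* — brightness/contrast (`clip(gain·in + bias)`) and
  small-angle rotation with exact axis-aligned hull transformation of the
  boxes (boxes whose clipped area drops under 25% of the original are
  dropped).

**Imbalance-driven planning** (`plan_balancing` / `execute_plan`): per-class
nodule counts set a target of `max count / target_ratio` for every class;
images containing under-target classes are re-sampled (each selected copy
receives exactly **two** distinct, randomly chosen ops — using more per
image is counterproductive) until every class projects past its target or a
per-image copy cap (10) is hit. Co-occurring common-class nodules ride
along, so common classes grow slightly too, as expected.

**Batched splitting** (`make_schedule`): one seeded shuffle into 25 equal
portions, 5 cumulative batches — batch N uses the first 5·N portions, with
the last portion of each 5-block as validation (4:1 split, stable across
batches; augmented copies always follow their source image's side).

**Annotation auditing** (`evaluate_annotations` and friends): confidence
filtering (default 0.1), class-agnostic greedy NMS (IoU 0.7), class-blind
greedy IoU matching to the gold standard (IoU ≥ 0.5), a
(C+1)×(C+1) confusion matrix with a background row/column (false
detections such as vessels called nodules; missed nodules), per-class and
overall accuracy, and all-points-interpolated mAP50 / mAP50-95.

**Synthetic phantoms** (`generate_phantom` / `corrupt_labels`): seeded
speckle-textured fan-sector frames with elliptical nodules, exact
ground-truth boxes and a configurable imbalance profile (default: common
classes 95.7% / rare 4.3%), plus an error-matrix-driven label corruptor so
the whole audit pipeline can be validated against known truth.

## Worked example

```r
library(usaug)

recs <- generate_phantom(phantom_config(image_size = 96, n_images = 60, seed = 42))
m    <- write_dataset(recs, "demo_data")
class_counts(m)
#>  2  3 4A 4B 4C  5
#> 33 57 29  3  1  1

plan <- plan_balancing(m, target_ratio = 3, seed = 43)
plan
#> <balance_plan: 30 selection(s), seed 43>
#>            2  3 4A 4B 4C  5
#> before    33 57 29  3  1  1
#> target    19 19 19 19 19 19
#> projected 33 77 29 19 11 11
merged <- execute_plan(plan, m, "demo_balanced")
class_counts(merged)
#>  2  3 4A 4B 4C  5
#> 33 77 29 19 11 11
```

The planner drives 4B to its target (19) and pushes 4C and 5 from 1 to 11 —
the per-image copy cap (10 augmented copies of the single image containing
each) stops them short of 19; class 3 grows as a co-occurrence side effect.
Executed counts equal the plan's projection exactly.

Auditing a deliberately corrupted annotator against the gold labels:

```r
cor <- corrupt_labels(recs, diag(6) * 0.7 + 0.3 / 6,
                      fp_rate = 0.05, fn_rate = 0.05, seed = 45)
res <- evaluate_annotations(lapply(cor$corrupted, `[[`, "boxes"),
                            lapply(recs, `[[`, "boxes"),
                            6, tirads_classes())
round(res$accuracy$per_class, 3)
#>     2     3    4A    4B    4C     5
#> 0.606 0.719 0.621 0.667 1.000 1.000
res$accuracy$overall
#> 0.669
```

`res$confusion$counts` is the quantitative confusion matrix (rows =
annotator class, columns = gold class, plus background margins for false
detections and misses); `res$confusion$proportions` is its column-normalized
form. Overall accuracy is exactly the gold-count-weighted mean of the
per-class accuracies.

The same operations are scriptable through the CLI
(`system.file("exec", "usaug", package = "usaug")`):

```sh
usaug synth --out data --seed 3 --n-images 60
usaug balance data/manifest.yaml --out balanced --target-ratio 3 --seed 5
usaug split balanced/manifest.yaml --out batches --seed 5
usaug eval --pred pred_labels --gold gold_labels --manifest data/manifest.yaml
usaug export-config --out trainer.yaml   # epochs 80, imgsz 800, conf 0.1, ...
```

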