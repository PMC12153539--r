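---
title: "Methods: weakly supervised metastasis detection with gated ABMIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised metastasis detection with gated ABMIL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its modelling choices: the
classifier and its assumptions, the defaults and why they are what they
are, what the synthetic data does and does not emulate, and the numerical
decisions a maintainer would otherwise have to reverse-engineer from the
code.

## 1. Problem setting and assumptions

A whole-slide image (WSI) of lymph node or omentum carries a single label —
*benign* or *metastatic* — while the evidence for a positive label may be a
deposit anywhere from centimetres down to ~100 µm. We therefore model a
slide as a *bag* of patch instances under the standard MIL assumption: a
slide is metastatic if and only if at least one of its patches contains
tumour. Everything in the package flows from three commitments:

* **Weak supervision only.** No pixel- or patch-level annotation is ever
  required; ground-truth masks exist only for synthetic data, where they are
  used for *testing*, never for training.
* **Case-level separation.** All slides of one case (patient) stay on the
  same side of every split. Violations are hard errors (`run_holdout()`
  refuses to predict if a hold-out case appears in training; fold
  construction partitions cases, not slides).
* **Physical units.** All geometry is expressed through microns-per-pixel
  (`mpp`), never magnification names. The synthetic default is 1 µm/px at
  level 0; a real 40× scan is ≈ 0.25 µm/px, and the same code applies with
  that value.

## 2. The classification pipeline

### Tissue segmentation

Glass background is nearly white (HSV saturation ≈ 0), tissue is stained
(saturation ≫ 0), so a pixel is tissue iff its saturation exceeds
`sat_threshold`. The mask is computed on an area-averaged thumbnail at
1/16 of level-0 resolution, median-filtered (radius 2) to suppress salt
noise, morphologically closed (disc radius 2), and connected components
under 16 mask pixels are dropped. Defaults:

| parameter | default | unit | why |
|---|---|---|---|
| `sat_threshold` | 8/255 | saturation in [0,1] | the conventional 8-bit threshold in weakly supervised WSI pipelines |
| `mask_downsample` | 16 | – | desk-scale memory; 1 mask pixel = 16 µm at the synthetic mpp |
| `closing_radius_px`, `min_region_area_px` | 2, 16 | mask px | close stain dropouts, drop speckle |

Borders are padded by replication before filtering and closing so an
all-tissue slide stays all-tissue — the morphological operators never erode
the image boundary.

### Patch grid and reading

Non-overlapping `1024 px` boxes anchored at (0, 0), 0-based, half-open;
partial boxes at the right/bottom edge are discarded, not padded (padding
would manufacture background-heavy instances). A box is kept if its tissue
fraction on the mask is ≥ `min_tissue_frac = 0.5` — enough to exclude
mostly-glass patches while keeping patches that contain small foci.
Reading downsamples each box to `256 px` by exact block averaging (each
output pixel is the mean of its 4×4 source block), i.e. 40× → 10× apparent
magnification on a real scan.

### Feature extraction

Extraction sits behind a three-field contract — `extractor(id, dim, fn)` —
because patch encoders are interchangeable and pretrained weights are
deliberately not bundled. The shipped `toy_extractor()` is a deterministic
62-dimensional descriptor (RGB/HSV channel means and SDs, 16-bin grey
histogram, mean gradient magnitude, dark-pixel fraction below grey 0.35 as
a nucleus-density surrogate, and 4×4 block grey and saturation means). It
is *not* a stand-in of equal power for a learned encoder; it is the
minimal descriptor that separates the synthetic renderer's tumour texture
from its plain tissue, which is exactly what the tests need.

### Gated attention MIL head

Patch features are standardised per dimension (constants fitted on the
pooled training instances, stored with the model), projected by a
linear+ReLU layer to `H1` dimensions, scored by a gated attention network
(tanh branch × sigmoid branch, `H2` hidden units, mapped to a scalar), and
softmax-normalised across the bag. The slide feature is the
attention-weighted average of projected patches; a linear layer with one
output node per class and a softmax yields the two class probabilities.
The gated (rather than plain tanh) attention follows the usual default of
the weakly supervised WSI lineage this package belongs to.

Hidden sizes default to `(512, 256)` and scale down to `(min(D, 512), 128)`
for small feature dimensions; both are overridable everywhere.

### Training

Adam on class-weighted cross-entropy, one bag per optimisation step.
Class weights default to inverse frequency (`n/(2 n_c)`) because real
cohorts of this kind are imbalanced. The three regularisers are dropout
(0.25, applied to the projected patch embeddings), weight decay (1e-5, on
weight matrices, not biases), and early stopping: after each epoch the
validation loss is evaluated in evaluation mode, and training stops when it
has not improved for 20 epochs after a minimum of 50; the returned
parameters are those of the best validation epoch.

The default learning rate is **5e-3**. This is a deliberate departure from
the 2e-4 typical of foundation-model-feature pipelines: with desk-scale
descriptors and hidden sizes, Adam at 2e-4 stalls on the uniform-attention
plateau (cross-entropy ≈ log 2) for longer than any reasonable patience,
while at 5e-3 the default simulation is solved to validation loss ≈ 0
across seeds. The rate is a `train_config()` field, so the conventional
value can be restored when plugging in a high-dimensional encoder.

All training randomness (shuffling, dropout masks) derives from
`config$seed`; identical data and seed reproduce parameters bit for bit.
Analytic gradients of the full head are verified against central
differences in the test suite.

### Cross-validation, ensembling, metrics

`make_case_folds()` stratifies cases by label, shuffles within class, and
assigns folds round-robin, so per-class counts in every role are within one
case of ideal. Fold *f* tests fold-*f* cases, validates on the next fold,
trains on the remaining three: 60-20-20 at k = 5. Pooled out-of-fold
predictions give the cross-validation metrics; hold-out slides are
predicted by the element-wise mean of the five fold models' probability
vectors (the ensembled AUROC uses the mean metastatic probability).

Metrics: accuracy, balanced accuracy (mean of the two recalls), AUROC by
the Mann–Whitney midrank formula (ties half-credited; equal to exhaustive
pair counting, which the tests verify), per-class
precision/sensitivity/specificity, and F1. Because "F1" is ambiguous in
two-class reports, both the metastatic-class F1 and macro-F1 are emitted.
Ratios that are 0/0 are reported as `NA`, never silently 0.

Bootstrap: slides are resampled with replacement B = 10,000 times; the
report gives the replicate mean and 2.5/97.5 percentiles (percentile
intervals, not BCa — the simpler estimator matching how such results are
usually printed). One joint index draw per replicate serves all metrics,
and replicates containing a single class are redrawn (up to 100 attempts)
so the rank-based metrics stay defined at small n; at the cohort sizes
involved this redraw is rare and its bias negligible. The bootstrap is
seeded and deterministic.

### Heatmaps

For visualisation, patches are re-extracted with 50% overlap (stride =
half the patch size) and scored by the attention branch over the full
overlapping set, so scores again form a single attention vector. Raw
softmax weights scale like 1/N and are incomparable across slides, so
scores are converted to within-slide percentile ranks before colouring.
Each raster pixel takes the arithmetic mean of all covering patches'
scores (mean, not max: order-independent and idempotent for uniform
scores); uncovered pixels stay transparent. The colour ramp runs blue
(low) → red (high), alpha-composited at 0.4 over a 1/16 thumbnail.

## 3. What the synthetic data emulates — and what it does not

`generate_slide()` renders: a near-white background with saturation < 0.05;
overlapping elliptical tissue blobs in eosin-pink (saturation 0.25–0.45) —
so the saturation gap that tissue segmentation relies on holds *by
construction*; and, on metastatic slides, disc-shaped tumour foci placed
entirely inside tissue, drawn as hue-shifted stroma scattered with dark
violet nuclei-surrogate dots (4–7 px radius, Poisson-placed). Focus
diameters are specified in µm; the cohort generator samples 1–3 foci per
positive slide from 100–500 µm, down to the size class that real screening
finds hardest. Cases carry 1–3 slides each so case-level splitting is
genuinely exercised; every generator output is a pure function of its spec
including the seed.

`generate_feature_bags()` skips the pixel stage: background instances are
standard normal in D dimensions, witnesses are mean-shifted by
`effect_size` per dimension (default 2), positive bags get exactly
`witness_count = 3` witnesses (indices recorded as ground truth), negative
bags none, bag sizes uniform on 20–50.

Deliberately **not** emulated: realistic histology texture, stain
variation, scanner artefacts, pen marks, blur, tissue folds, or the
background architectural changes (inflammation, reactive hyperplasia) that
attract attention in real slides. Consequently, green tests here
demonstrate that the machinery is correct — segmentation recovers the
generator's mask, attention recovers planted witnesses, splits never leak —
not that any particular performance level transfers to real H&E data. On
real slides, attention is known to fall partly on background architecture
rather than tumour itself; the synthetic tumour-attention test asserts its
property only on the toy generator, where tumour is the sole discriminative
signal.

## 4. Problem sizes and numerical choices

* Default simulation study: 100 training / 40 validation / 40 test bags
  (50/20/20 per class), D = 32 — trains in well under a minute on one CPU.
* The end-to-end demo (`run_demo()`): 16 + 16 training slides (~16 cases),
  4 + 4 hold-out slides (one per case), 2048² px canvases at 1 µm/px,
  training capped at 60 epochs (min 20, patience 10) — a few minutes on one
  CPU, chosen so the whole chain stays interactive. Both demo readouts are
  small-sample estimates: out-of-fold AUROC on 32 slides and ensembled
  hold-out metrics on 8 slides can each swing noticeably across seeds, and
  a synthetic slide whose tumour focus falls in a dropped patch contributes
  irreducible label noise, exactly as a missed-sampling event would in a
  real cohort. The defaults favour a fast, complete demonstration over a
  stable benchmark; the simulation study is the calibrated readout.
* Softmaxes subtract the max before exponentiating; cross-entropy clamps
  probabilities at 1e-12; feature standardisation floors the SD at 1e-8;
  Adam uses (0.9, 0.999, 1e-8).
* Ties in attention (identical patches) resolve to exactly uniform weights
  by construction of the softmax; duplicated patches halve each copy's
  weight and leave slide probabilities unchanged.
* Degenerate inputs error loudly: empty patch sets, bags with zero
  instances, a class missing from a split, non-finite features, hold-out /
  training case overlap.

## 5. Known limitations

* The toy descriptor saturates quickly: once foci are large it adds no
  information beyond the dark fraction, and sub-patch localisation is only
  as good as 256 px patches allow.
* Bootstrap redraws (single-class replicates) slightly narrow intervals at
  very small n; at n ≥ 40 with balanced classes the effect is far below
  the Monte-Carlo error.
* Early stopping selects on validation loss, not AUROC; with tiny
  validation sets the selected epoch can be noisy.
* JSON bag containers trade compactness for text-format portability; for
  thousands-of-patch bags from a real encoder a binary array store would be
  the right swap behind `save_bag()`/`load_bag()`.
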