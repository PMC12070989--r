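---
title: "Lesion graphs: model, generator and numerical conventions"
author: "cervigraph maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion graphs: model, generator and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervigraph)
```

## The problem and the modelling idea

Grading cervical lesions from colposcopy imagery is usually framed as
pixel classification. `cervigraph` takes the complementary view: once a
segmentation mask exists, the *diagnostic signal lives in the regions* —
how large they are, how irregular their outlines, how rough their internal
texture, how bright they appear — and in the relations among regions. The
package therefore converts each labeled mask into a weighted graph whose
nodes are connected regions described by 14 features, and classifies whole
graphs with a small graph convolutional network (GCN).

This vignette records the package's own account of the method: the model
and its assumptions, the tunable parameters, what the synthetic generator
does and does not emulate, the numerical conventions, and the design
decisions taken where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Node features

Per 8-connected region of each positive mask label:

| group | features | convention |
|---|---|---|
| geometry | area, perimeter, eccentricity, solidity, major/minor axis, aspect ratio, compactness, circularity | see below |
| texture | GLCM contrast, correlation, energy, homogeneity | 32 levels over [0,1], distance 1, four angles averaged, symmetric, normalized, pairs restricted to region-interior pixels |
| intensity | mean intensity | image normalized to [0,1] by dividing 8-bit values by 255 |

Numerical conventions, all unit-tested against independent oracles:

* **Perimeter** is the Moore-boundary chain length with `sqrt(2)` weight on
  diagonal steps. Verified before freezing: a rasterized radius-20 disk
  gets circularity `4*pi*A/P^2 = 0.908` and a 10x10 square `0.970`, so no
  bias-correction factor is applied. An isolated pixel has perimeter 4
  (its unit-square boundary).
* **Moments**: eccentricity and the ellipse axes come from second-order
  central moments of the pixel centers with a `1/12` unit-square term per
  axis. That term is not cosmetic: it makes a square's eccentricity exactly
  0, floors the minor axis of 1-pixel-wide regions without an arbitrary
  epsilon, and keeps aspect ratios finite for every region.
* **Solidity** uses the convex hull of pixel *corner* points. A hull over
  pixel centers makes a filled rectangle's solidity exceed 1 (hull area
  `(w-1)(h-1)` vs. `wh` pixels); corners give exactly 1.
* **Compactness** is defined as `P^2 / (4*pi*A)`, the reciprocal of
  circularity, keeping the two features distinguishable.
* **GLCM quantization** maps intensity `x` to bin `min(floor(x*L), L-1)+1`.
  Correlation of a constant (zero-variance) region is defined as 0.
  Regions contributing fewer than 2 co-occurring pairs raise an
  `undefined-texture` error rather than emitting noise. GLCM is computed
  per region (not per image); this is configurable via `glcm_config()`.
* Whether tiny satellite fragments (e.g. produced by nearest-neighbor mask
  rescaling) should be features at all is a pipeline question, not a
  feature-extraction question: `extract_feature_table()` keeps every
  region by default, and the pipeline commands pass `min_area = 8` to drop
  fragments below 8 px.

## Graph construction

Edges carry `w_ij = 1 / (||f_i - f_j|| + eps)` with `eps = 1e-8` guarding
the zero-distance case. Original graphs are fully connected
(`n(n-1)/2` edges). Augmented graphs perturb a class's feature table with
Gaussian noise — s.d. equal to `noise_fraction` (default 0.05) of the
feature's per-table s.d., applied to area, perimeter, eccentricity, mean
intensity and GLCM contrast — then keep the edge `(i,j)` iff its distance
is at most `u * D_max`, with `u ~ Uniform(0.30, 0.60)` drawn per graph and
recorded in the graph's provenance together with the seed.

Two deliberate choices:

* **Distances on raw features.** The literal inverse-distance formula is
  applied to unstandardized features, where area (hundreds of pixels)
  dominates the metric. A per-table z-score flag exists
  (`standardize = TRUE` in the builders) but defaults to off, because the
  raw formula is the stated construction; the consequence is documented
  rather than silently corrected.
* **Node set fixed under augmentation.** Augmented graphs reuse all rows of
  the class table; nodes are never resampled, added or dropped. This is
  the minimal interpretation of feature-noise augmentation.

A known tension is recorded here rather than resolved: the surrounding
literature sometimes describes edge weights as *learned* end-to-end, while
the concrete construction above is static. `cervigraph` implements the
static definition; the GCN learns what to do with the weights, not the
weights themselves.

## The classifier

`Â = D̃^{-1/2}(A + I)D̃^{-1/2}` with unit self-loops; two ReLU graph
convolutions (`W1: 14->h`, `W2: h->h`, per-layer biases deliberately
omitted so the parameter set is exactly `{W1, W2, Wc, bc}`); global mean
pooling; affine head; softmax. Both hidden layers share `hidden_dim`
because nothing distinguishes them in the source description.

Training choices:

* **Optimizer**: Adam (`beta1 = 0.9`, `beta2 = 0.999`) by default — no
  optimizer is named in the source; plain SGD is selectable
  (`optimizer = "sgd"`). Learning rate and epochs come from the config.
* **Initialization**: Glorot-uniform, seeded; all randomness (init, batch
  shuffling, splits, noise draws) flows from one seed through a
  deterministic splitmix-style derivation, so two runs with the same seed
  produce bit-identical histories and parameters.
* **Feature standardization** (`standardize = TRUE`, the default): node
  features are z-scored with statistics pooled over training-set nodes and
  the scaler is stored inside the checkpoint. Raw features span four
  orders of magnitude (area vs. GLCM energy), which saturates ReLU and
  softmax; standardizing inside the trainer fixes this without touching
  the graph-construction contract above.
* **Loss**: mean cross-entropy with predicted probabilities floored at
  `1e-12`; softmax is computed with max-subtraction. The analytic backward
  pass is verified against central finite differences to `< 1e-4` relative
  error on every parameter tensor.
* **Early stopping**: validation loss monitored per epoch; training halts
  after `patience` (default 3) non-improving epochs and the best-epoch
  parameters are restored. `fine_tune()` additionally baselines the
  monitor at the warm start's validation loss, so fine-tuning can never
  return parameters worse than it received.
* **Batching**: graphs are processed independently and batch gradients
  averaged (batch size 8). Disjoint-union batching would be an equivalent
  optimization, not a different model.
* **Ties** in argmax prediction break toward the lowest class index.

## Cross-validation and grid search

`kfold_split()` deals each class's shuffled items cyclically with a
running pointer, which guarantees both fold sizes and per-class counts
differ by at most 1; both properties are asserted by randomized property
tests. The default grid is `hidden_dim {32, 64} x learning rate
{0.001, 0.01} x epochs {10, 20}` — 8 combinations, evaluated exhaustively
on a stratified 20 % inner split of the training fold, selected by inner
macro F1, ties resolved by grid order. The grid's epoch options apply to
grid-search *trials*; the per-fold final model trains for a separate
budget (default 100 epochs) with early stopping, reconciling the short
trial budgets with the long final-training budget. The fine-tuning rate
defaults to the selected rate divided by 10, as no fine-tuning rate is
stated anywhere.

## The synthetic generator: what it emulates, what it does not

`generate_synthetic_case()` draws, per class profile: a region count and
per-region pixel areas within stated ranges, outlines as low-order
harmonic perturbations of a disk (amplitude grows as the profile's
`circularity_target` drops), placement by rejection sampling with
non-overlap margins (whole-case retries on derived seeds keep generation
deterministic and robust), a dark noisy background (mean 0.22, s.d. 0.02)
and region interiors at the profile's `intensity_mean` with i.i.d.
Gaussian texture of s.d. `contrast_level`.

The five default profiles encode the published *trends*, scaled to a
128x128 working canvas: area dips at CIN1 and grows back toward carcinoma;
texture contrast increases monotonically with severity (`contrast_level`
0.05 -> 0.18); circularity decreases (0.90 -> 0.52); intensity means follow
the published per-class values (0.65, 0.68, 0.55, 0.58, 0.50). Region
counts are capped at what physically fits the canvas with non-overlap
margins (e.g. at most 2 of the largest carcinoma regions) — a feasibility
constraint, not a clinical claim.

What the generator does **not** emulate: vascular patterns, acetowhite
response, specular highlights, staining variation, annotation noise, or
any correlation structure between features beyond what geometry induces.
Consequently a green end-to-end test establishes that the *pipeline
machinery* — features, graphs, training, CV — can recover a class signal
of the stated kind; it does not certify clinical performance, and the
published clinical headline figures are deliberately not acceptance
targets (their datasets are not distributable).

Augmentation (`augment_pair()`) applies identical quarter-turn rotations,
flips and uniform rescaling to image and mask (nearest-neighbor for
labels, bilinear for intensities, zero-padded back to the canvas), and
brightness/contrast jitter to the image only, clipped to [0,1]. The
intensity parameter ranges (±0.15 brightness, 0.85–1.15 contrast gain,
0.9–1.1 scale) are unstated anywhere authoritative; they are configurable
and were chosen once as mild, realistic jitter.

## Storage conventions

Feature tables go to CSV with a fixed 16-column header and 10 significant
digits. Graphs go to GML; because GML keys may not contain underscores and
the available GML writers mangle such names, the package writes its own
conservative GML (camelCased keys, `classLabel`, `provenance`, `seed`,
`threshold`, per-node feature attributes, per-edge `weight`) and validates
the schema on read. Images are 8-bit grayscale PNG; masks are 8-bit PNG
holding raw label integers (the 16-bit variant was dropped because the
available PNG writer is 8-bit only — with at most a handful of regions per
mask, labels never approach 255).

## Empty and degenerate inputs

* All-zero mask: `extract_regions()` raises an empty-mask error — "no
  lesion" is a signal, not a zero-row table.
* Single-row feature table: noise injection is skipped with a warning
  (s.d. undefined); augmented graphs require at least 2 rows.
* Two empty masks compared: all segmentation scores are 1 by convention;
  this case never occurs in the published evaluation and the convention is
  the one under which "perfectly predicted absence" is not penalized.
* Degenerate one-vs-rest AUC (a class absent) returns `NA` with the
  affected classes flagged in the report, and absent-class recall is
  reported as 0 with a flag.

## Known limitations

* Pure-R training: adequate at the package's scale (tens of thousands of
  small-graph gradient steps per minute) but not for thousands of large
  graphs.
* The generator's class separation is strong by construction; the
  end-to-end criterion (macro F1 >= 0.90) is a property-based floor, not a
  reproduction of any published table.
* Macro metrics follow the arithmetic-mean definition exactly; published
  tables whose macro rows do not equal the mean of their per-class rows
  are not reproduced, by design.
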