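---
title: "Models and design choices in cytomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in cytomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomorph)
```

cytomorph automates a workflow that mirrors how a hematologist reads a
peripheral blood smear: find the informative part of the slide, identify
individual white and red blood cells, describe each cell's morphology, and
relate the slide-level composition of those morphologies to diagnosis. This
vignette explains each model, its tunable parameters, and the design
decisions taken where the problem left genuine freedom.

## Tile quality control

Digitized smears are processed as 512 x 512-pixel tiles (40x magnification,
~0.25 µm/px is assumed throughout). Only the monolayer — the region where
cells lie in a single layer — is diagnostically useful, so tiles that are too
sparse, too dense (overlapping cells), or blurred must be discarded before
detection.

`train_qc()` fits a ridge-regularized logistic model over engineered tile
descriptors: the foreground fraction, a cell-scale blob count from a
difference-of-Gaussian response, a variance-of-Laplacian sharpness score, and
the squared density terms. The squares matter: "good" is a *band* of
intermediate density, which a linear model can only carve out with quadratic
features. The verdict threshold defaults to 0.5 (probability of "good"); a
pluggable convolutional backend could replace the engineered one without
changing the contract — only the tile-in, score-out interface is fixed.

## White-cell segmentation

`segment_probabilities()` produces a per-pixel WBC probability map from a
pluggable backend. The shipped backend is a logistic pixel classifier over
raw RGB, Gaussian-smoothed RGB (local context) and local intensity standard
deviation, trained by full-batch Adam on pixels sampled from annotated tiles
with dihedral, intensity-jitter and blur augmentations
(`train_segmenter()`). This is deliberately the smallest model that honors
the encoder–decoder contract; on synthetic smears it is sufficient because
leukocyte cytoplasm and nuclei are chromatically distinct.

Test-time augmentation averages the prediction over the 8-element dihedral
group (4 rotations x optional flip), inverse-transforming each map before
averaging. Averaging over a closed group is idempotent and cannot increase
prediction variance; both properties are asserted in the test suite.

`postprocess()` turns the map into instances: threshold (default 0.5),
8-connected components, hole filling, and an area gate of 300–15000 px²,
bracketing leukocyte diameters of roughly 10–70 µm at the assumed
resolution. Distance-transform watershed splitting of touching cells exists
behind a flag but is off by default — undersegmentation is the rarer error
and aggressive splitting creates more artifacts than it fixes.

`segment_nucleus()` partitions each WBC's grayscale intensities into 2
clusters with k-means (10 restarts, fixed internal seed, so inference is
deterministic) and takes the darker cluster as the nucleus, keeping
connected components of at least 25% the size of the largest so that
separate nuclear lobes survive while specks are dropped. The darker-cluster
rule fails by construction under inverted or low contrast — the method then
returns the darker cytoplasm; this failure mode is documented and tested
rather than patched, since it mirrors how intensity-based nuclear
segmentation degrades on low-contrast stains, and downstream features carry
a quality flag instead.

## Red-cell detection and filtering

Erythrocytes are far too numerous to annotate for supervised detection, so
candidates come from classical vision: grayscale → Canny edges (Gaussian
σ = 2, hysteresis thresholds Otsu-scaled, 4-direction non-maximum
suppression) → morphological closing (disc radius 3 px; radius 2 left the
pale-centered rims fragmented on the synthetic fixtures) → hole filling →
8-connected components → an area gate of 150–3000 px² (5–9 µm erythrocytes
with margin) → exclusion of anything overlapping a WBC mask by more than
50%. Hole filling *before* the area gate is essential: the central pallor of
a biconcave red cell otherwise splits one cell into a ring and a core.

Candidates still include fused doublets, platelet clumps and debris.
`train_rbc_filter()` fits gradient-boosted trees (xgboost, single-threaded
for determinism) on the 42 cellular morphometric features to reject
non-RBC objects; `filter_rbc()` partitions candidates into accepted and
rejected sets at a 0.5 score threshold and logs every rejection. If a
fraction p0 of candidates are false positives and the filter passes a
fraction f of them, the residual false-positive proportion is p0·f
(`residual_false_positive_rate()`).

## The morphometric feature schema

Every cell gets 42 features (`feature_schema("RBC")`); each WBC gets 11
nuclear features on top (53 total). The schema is fixed, ordered and
versioned by name:

* **Shape (12)** — area (pixel count), perimeter (Cauchy–Crofton estimator
  over 4 directions, which has less raster bias than boundary-step
  counting), circularity 4πA/P², eccentricity and principal axes from
  second-order mask moments, solidity and convexity, aspect ratio, and the
  mean, standard deviation and max/min ratio of the centroid distance
  function (CDF) — distances from 128 arc-length-equispaced boundary points
  to the area centroid. The CDF standard deviation is the schema's contour
  irregularity measure. Solidity and convexity compare the traced boundary
  polygon with the convex hull of its vertices, which bounds both by 1 up to
  rasterization.
* **Color (18)** — mean, SD, moment skewness and the 5/50/95% quantiles per
  RGB channel, computed strictly on in-mask pixels (asserted with sentinel
  values outside the mask).
* **Texture (12)** — gray-level co-occurrence statistics (contrast,
  dissimilarity, homogeneity, energy, correlation, angular second moment) at
  pixel distances 1 and 3, angle-averaged over the four principal
  directions, on 32 gray levels with symmetric normalization. Correlation of
  a constant patch is defined as 1 and skewness of a constant channel as 0,
  so degenerate cells stay finite.
* **Nuclear (11)** — the six nuclear shape analogues, nucleus:cell area
  ratio, nuclear CDF standard deviation, nuclear mean and SD intensity, and
  the nucleus:cytoplasm mean-intensity ratio.

CDF resampling uses 128 points: empirically stable for objects of at least
~150 px², the smallest area the RBC gate admits.

## Morphometric moments and the elastic-net model

`compute_moments()` reduces a slide to the mean and unbiased (n−1) variance
of every feature over its cells, per cell type — the variance terms encode
cytomorphological *heterogeneity*, which carries diagnostic signal of its
own. `fit_elastic_net_cv()` classifies the four diagnostic contrasts
(disease detection, disease classification, MDS genetic subtyping, anemia
classification — each defined only on its eligible slides) with binomial
elastic-net regression: mixing parameter α = 0.5 by default, per-fold
penalty chosen by inner cross-validated deviance on the training fold only,
features z-scored with training-fold statistics only, missing values imputed
with the training-fold median, stratified outer folds. Passing `lambda = 0`
recovers plain logistic regression, which the tests exploit as an
independent oracle.

`feature_group_contribution()` attributes prediction to feature groups by
decomposing the variance of the linear predictor: group g's share is
Cov(η_g, η)/Var(η), which splits covariance cross-terms equally between the
two groups involved and sums exactly to 1.

## Morphotype analysis

The slide-classification problem is multiple-instance learning: a slide is a
bag of cells, only the bag carries a label. The morphotype model learns, per
cell type, K prototype vectors m_k in standardized feature space with a
learnable temperature τ. Cell i is softly assigned by

  a_ik = softmax_k( −τ · ‖x_i − m_k‖² ),

the slide's morphotype proportions are the mean assignment row over its
cells, and each task head is a linear model over the concatenated WBC and
RBC proportions (optionally plus standardized blood counts: white-cell
count in cells/µL, hemoglobin in g/dL, platelets/µL). Everything is
differentiable end to end; training minimizes the sum over tasks of the
binary cross-entropy averaged over task-eligible slides, with ineligible
slides masked out. The analytic gradient is verified against finite
differences in the tests.

Design choices that were genuinely open, and why they were made:

* **Initialization.** Prototypes start at k-means centers (20 restarts, up
  to 20000 subsampled cells). Good initialization matters twice over: it
  speeds optimization, and it makes independently initialized folds agree on
  the density structure — the foundation of stability selection.
* **Two learning-rate groups plus head weight decay.** Adam with a single
  learning rate moves every parameter by roughly the learning rate per step
  regardless of gradient magnitude; once the heads have solved the task, the
  remaining shallow loss slope still walks prototypes around arbitrarily,
  and the walk differs per fold. The heads therefore train fast
  (`lr_heads = 0.05`) while prototypes and temperature fine-tune slowly
  (`lr_prototypes = 5e-4`), and a small ridge penalty (1e-3) on head weights
  bounds their growth so the loss reaches a real plateau and the early stop
  (patience 50 epochs on a running-mean smoothed loss, minimum improvement
  1e-4) engages. The result: prototypes stay anchored to the density
  structure they can defend, which is exactly what makes them reproducible
  across folds.
* **Soft proportions.** Slide proportions are mean soft assignments, not
  hard argmax counts, preserving differentiability; hard labels are used
  only for count-based post-hoc statistics (`hard_assignments()`).
* **Stability selection.** `crossvalidate()` trains one model per
  stratified fold; `stability_select()` matches the best fold's prototypes
  one-to-one against every other fold's by solving the assignment problem
  that maximizes total cosine similarity, and calls a prototype stable when
  its match reaches cosine 0.8 in every fold. The assignment solver is an
  exact shortest-augmenting-path implementation, checked against brute-force
  permutation enumeration. `predict_stable()` restricts proportions to the
  stable set, renormalizes them to sum to 1, and restricts the head weights
  accordingly.

## Association statistics

* `enrichment()`: for morphotype c and annotated type t, the ratio
  P(t | c)/P(t) from hard assignments, with a continuity-corrected
  chi-squared test per 2×2 table and Benjamini–Hochberg correction across
  the grid (the multiplicity procedure was an open choice; BH is the field
  default). The identity Σ_c P(c)·enrichment(c, t) = 1 holds exactly and is
  asserted to 1e-9.
* `proportion_ratio()`: condition-contrast ratios of median per-slide
  proportions, with the top-k morphotypes selected by the absolute
  difference of medians. "Effect size" admitted two readings; the absolute
  median difference is the most direct and is the default, with a
  MAD-standardized alternative behind an option.
* `density_ratio()`: per-point Gaussian-kernel class densities in a 2-D
  embedding; the ratio of the predominant class's density to the total.
* `external_validate()`: rank-statistic AUC with standard error 1/√n and
  the interval clamped to [0, 1]. (Two formulas for the standard error
  circulate for this quantity; 1/√n is the statistically standard one and is
  used here.)

## The synthetic-data module

`render_tile()` draws what the detection stack must cope with: RBCs as
stained ellipses whose center is rendered paler than the rim (exercising the
hole-filling logic the way real central pallor does), WBCs as larger cells
with strictly darker 1–4-lobed nuclei, platelets as small dark dots,
Gaussian blur and sensor noise. `simulate_bags()` plants a known morphotype
structure: per cell type, K_true Gaussian morphotypes at a controlled
minimum centroid separation (default 6x the within-morphotype scatter);
each condition draws cells from its own mixing vector, and blood counts are
drawn per condition around the cohort-typical means (e.g. megaloblastic
anemia: low white counts, very low hemoglobin, low platelets). The default
feature dimension is 10 rather than 42/53 — the MIL machinery is
dimension-agnostic and the smaller dimension keeps simulation studies fast;
schema-sized designs are one argument away.

What the generator does *not* emulate: stain variability, scanner-specific
color response, focal-plane artifacts, rouleaux, cell types beyond the
three object classes, and any correlation between a cell's rendered
appearance and its feature-bag morphotype (tiles and bags are independent
fixtures). Passing tests on synthetic data therefore demonstrate that the
algorithms are implemented correctly and recover planted structure — not
that they meet any particular accuracy on real smears.

## Problem sizes and reproducibility

The simulation studies use sizes chosen to make their statistical targets
well-powered while staying comfortable on a laptop: the parameter-recovery
study uses 60 slides x 200 cells per cell type with K = 10 prototypes and
5-fold cross-validation; the permutation null averages 3 independent label
permutations of the same design; the moments-model study uses 45 slides
across the five conditions. Every stochastic step — scene placement,
rendering noise, bag simulation, k-means, fold assignment, Adam — runs under
an explicit seed, and all generators restore the caller's RNG state.

## Known limitations

* The engineered QC and segmentation backends are contracts filled with the
  smallest adequate model; real smears would warrant convolutional backends
  trained on expert annotations.
* Whole-slide formats are supported only through the plain-raster reader;
  proprietary scanner formats need a reader plugin providing
  open/dimensions/read-region.
* The nucleus segmentation inherits the darker-region assumption and the
  granularity caveat for eosinophils/basophils.
* Enrichment uses hard assignments; with very diffuse soft assignments the
  hard argmax discards calibration information.
* Morphotype identities are statistical constructs: interpreting a stable
  prototype as a named cell type requires expert annotation, which the
  enrichment analysis supports but cannot replace.
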