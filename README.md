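# cytomorph

Computational cytomorphology of peripheral blood smears: automated
detection, morphometric characterization and disease-association analysis of
white and red blood cells in digitized slides.

Blood diseases such as the myelodysplastic syndromes (MDS) and deficiency
anemias alter both the abundance and the morphology of circulating cells —
hypolobulated or hyperlobulated neutrophils, enlarged or hypochromic red
cells, shifted cell-type proportions. Assessing these changes by eye is slow
and shows substantial inter-observer variation. cytomorph is for
computational hematology researchers who want a fully scriptable pipeline
from slide tiles to slide-level diagnostic models, with every stage testable
against synthetic ground truth.

The pipeline:

1. **Tile quality control** (`train_qc()`, `classify_tile()`) — keep only
   monolayer-like 512×512 tiles (not sparse, not dense, not blurred).
2. **White-cell segmentation** (`train_segmenter()`,
   `segment_probabilities()`, `postprocess()`, `segment_nucleus()`) — a
   pluggable pixel-probability backend with dihedral test-time augmentation,
   rule-based instance extraction, and nucleus/cytoplasm partitioning by
   2-means intensity clustering.
3. **Red-cell detection** (`detect_rbc_candidates()`, `train_rbc_filter()`,
   `filter_rbc()`) — Canny-edge candidate generation with hole filling for
   central pallor, then a gradient-boosted morphometric filter that removes
   platelet clumps, fused doublets and other non-RBC objects.
4. **Morphometry** (`extract_features()`, `feature_schema()`) — a fixed
   schema of 42 cellular features per cell (shape, color, co-occurrence
   texture) plus 11 nuclear features per WBC (53 total).
5. **Moments model** (`compute_moments()`, `fit_elastic_net_cv()`) —
   per-slide feature means and variances classified with cross-validated
   elastic-net logistic regression over four diagnostic tasks.
6. **Morphotype analysis** (`init_model()`, `mil_train()`,
   `crossvalidate()`, `stability_select()`) — the core method: a
   multiple-instance-learning model that learns soft cell prototypes
   ("computational morphotypes", CMs) jointly with linear slide classifiers
   over CM proportions,

   a_ik = softmax_k(−τ·‖x_i − m_k‖²),  p(slide) = mean_i a_i,
   logit_t = w_t·[p_wbc; p_rbc; blood counts] + c_t,

   trained end-to-end by Adam on a masked multi-task cross-entropy, with
   cross-fold stability selection of prototypes (optimal cosine matching
   across folds).
7. **Association statistics** (`enrichment()`, `proportion_ratio()`,
   `density_ratio()`, `external_validate()`) — enrichment of expert cell
   types within morphotypes with chi-squared tests, condition
   proportion-ratio contrasts, embedding density ratios, and validation AUC
   with 1/√n standard errors.

A synthetic-data module (`render_tile()`, `simulate_bags()`,
`simulate_annotations()`) generates smear tiles with ground-truth masks and
per-cell feature bags with planted morphotype mixtures, so the whole
pipeline runs and is verified without any external data.

## Worked example

Plant two conditions whose morphotype mixtures differ, then recover the
structure:

```r
library(cytomorph)

mix <- list(control   = c(0.40, 0.40, 0.10, 0.10),
            MDS_other = c(0.10, 0.10, 0.40, 0.40))
des <- bag_design(conditions = c(control = 30, MDS_other = 30),
                  cells_per_slide = c(200, 200),
                  K_true = c(wbc = 4, rbc = 4), separation = 6,
                  mixing = list(wbc = mix, rbc = mix), seed = 10)
d  <- simulate_bags(des)

cv <- crossvalidate(d$bags, K = c(wbc = 10, rbc = 10),
                    objectives = "disease_detection", folds = 5, seed = 42)
cv$cv_auc
#> disease_detection
#>                 1

rep <- stability_select(cv, theta = 0.8)
rep
#> <stability_report ref=1 theta=0.80 stable: 6 WCM, 8 RCM>
```

The held-out cross-validated AUC of 1 says the planted condition difference
is fully recovered from morphotype proportions alone; of the 10 prototypes
per cell type, 6 white-cell and 8 red-cell morphotypes recur across all five
folds at cosine ≥ 0.8, and those stable morphotypes include, for each cell
type, at least four lying within cosine 0.9 of a planted centroid. The same
bags summarized as morphometric moments give
`fit_elastic_net_cv(moments_table(d$bags), "disease_detection")$cv_auc` of
1 as well — on cleanly separable synthetic data both routes saturate.

Fitted objects follow broom/ggplot2 conventions: `tidy()`, `glance()` and
`autoplot()` work on moments fits, stability reports and enrichment tables.

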