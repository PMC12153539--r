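# wsimil

Weakly supervised detection of metastatic carcinoma in whole-slide images
(WSIs) with attention-based multiple-instance learning (ABMIL), evaluated the
way computational-pathology studies report it: case-level stratified
cross-validation, ensembled hold-out testing, and bootstrap confidence
intervals — plus attention heatmaps for qualitative review.

## Who this is for

Staging a tubo-ovarian carcinoma means reviewing large amounts of
accompanying tissue — lymph nodes and omentum — for metastatic deposits that
may be anything from bulky tumour down to foci ~100 µm across. Only the
slide-level diagnosis (benign vs. metastatic) is routinely available as a
label; nobody outlines tumour pixel by pixel at scale. That makes the
problem *multiple-instance learning*: a slide is a bag of tissue patches,
the label belongs to the bag, and a positive bag is positive because of a
(possibly tiny) subset of witness patches.

`wsimil` implements that pipeline end-to-end in R, and ships a synthetic
slide/bag generator with known tumour masks and witness instances, so every
stage is testable without any real patient data.

## The model

Each slide is tiled into non-overlapping 1024 px patches of tissue
(segmented from background by HSV-saturation thresholding), downsampled 4×
to 256 px, and embedded by a pluggable feature extractor. Given patch
features $h_1, \dots, h_N$, a gated attention network scores each patch

$$s_k = w^\top\big(\tanh(V\,\tilde h_k)\odot\sigma(U\,\tilde h_k)\big) + b,
\qquad a_k = \frac{e^{s_k}}{\sum_j e^{s_j}},$$

where $\tilde h_k$ is the ReLU-projected embedding of $h_k$. The slide
feature is the attention-weighted average $z = \sum_k a_k \tilde h_k$, and a
fully connected layer with one output node per class followed by a softmax
gives $P(\text{benign})$ and $P(\text{metastatic})$; the maximum is the
prediction. Attention weights $a_k \in [0,1]$ sum to 1 over the slide and
drive the heatmaps. Training minimises class-weighted cross-entropy with
Adam (one bag per step), regularised by dropout, weight decay and early
stopping on a validation split.

Evaluation is at the case (patient) level: stratified 5-fold
cross-validation with 60-20-20 training–validation–testing splits, pooled
out-of-fold metrics, ensembled (probability-averaged) hold-out predictions,
and 10,000-iteration bootstrap percentile CIs for accuracy, balanced
accuracy, AUROC, F1 and per-class precision/sensitivity/specificity.
Case-level leakage between splits is a hard error, never a warning.

## Worked example

Hold-out evaluation metrics from a confusion structure — 50 benign slides
all called correctly, 2 of 50 metastatic slides missed:

```r
library(wsimil)
y_true <- rep(c("benign", "metastatic"), each = 50)
y_pred <- y_true; y_pred[51:52] <- "benign"
counts <- confusion_counts(y_true, y_pred)
counts
#>             prediction
#> truth        benign metastatic
#>   benign         50          0
#>   metastatic      2         48
accuracy_metrics(counts)
#> # A tibble: 1 × 2
#>   accuracy balanced_accuracy
#>      <dbl>             <dbl>
#> 1     0.98              0.98
class_metrics(counts, positive_class = "benign")
#> # A tibble: 1 × 5
#>   positive_class precision sensitivity specificity    f1
#>   <chr>              <dbl>       <dbl>       <dbl> <dbl>
#> 1 benign             0.962           1        0.96 0.980
```

So a screening tool that misses 2 of 50 metastatic slides still reads 98%
balanced accuracy; the benign-class precision of 0.962 says 2 of every 52
slides triaged "benign" would actually carry tumour.

Training on synthetic feature bags (background instances N(0, I); witness
instances mean-shifted by 2 SD; 3 witnesses per positive bag):

```r
tr <- generate_feature_bags(bag_sim_spec(n_bags_per_class = 50, seed = 1))
va <- generate_feature_bags(bag_sim_spec(n_bags_per_class = 20, seed = 2))
te <- generate_feature_bags(bag_sim_spec(n_bags_per_class = 20, seed = 3))
fit <- abmil_train(abmil_init(32, seed = 1), tr$bags, tr$labels,
                   va$bags, va$labels, config = train_config(seed = 1))
preds <- predict_slides(fit, te$bags)
auroc(te$labels, preds$prob_metastatic)
#> [1] 1
b <- te$bags[[which(te$labels == "metastatic")[1]]]
round(sort(attention_weights(fit, b), decreasing = TRUE)[1:4], 3)
#> [1] 0.485 0.361 0.153 0.000
```

The trained attention puts essentially all of its mass on the three
ground-truth witness instances of the bag — the behaviour the heatmaps
visualise on slides.

The full image pipeline (synthetic cohort → segmentation → patches → toy
descriptor → 5-fold CV → ensembled hold-out → heatmap PNG) is one call:

```r
demo <- run_demo(out_dir = "demo_run", seed = 1)   # a few minutes, 1 CPU
glance(demo$holdout$report)
```

## Scope

The package deliberately does not bundle any pretrained encoder: feature
extraction is behind the `extractor()` contract, the shipped
`toy_extractor()` is a deterministic 62-dimensional colour/texture
descriptor sufficient for the synthetic slides, and a real histopathology
foundation model can be plugged in as `extractor(id, dim, fn)`. Stain
normalisation, augmentation, and annotation-overlap scoring of heatmaps are
out of scope. See `vignettes/wsimil-methods.Rmd` for the modelling details,
defaults and limitations.
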