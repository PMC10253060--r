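# fundusbalance

Class-imbalance-aware training and evaluation for four-class retinal
fundus image classification (normal, glaucoma, age-related macular
degeneration, diabetic retinopathy), aimed at researchers studying
imbalance-handling strategies for medical image screening models.

Corpora pooled from many public fundus collections are severely
imbalanced — on the order of 86k normal, 34k DR, 3.8k glaucoma and 600
AMD images — and a naive classifier buys accuracy by ignoring the
minority classes. `fundusbalance` implements a threshold-based
**two-stage** remedy and the machinery to compare it fairly with the
standard resampling baselines:

- **Threshold split.** Let *t* be the cardinality of the reference
  minority class (glaucoma). The fine-tuning subset keeps all glaucoma
  and AMD images plus uniform random samples of min(*t*, n_c) normal and
  DR images; the excess normal/DR images form a binary pre-training
  subset. For the census above: fine-tuning 3,787/3,787/632/3,787
  (11,993 images), pre-training 82,628 normal + 30,592 DR.
- **Two-stage training.** Binary pre-training (normal vs DR, weighted
  cross-entropy *L* = −w_y log p_y with weights 1:2, weighted-mean batch
  reduction) on the excess subset; then the head is replaced with a
  4-output layer, half the feature-extractor layer groups are frozen,
  and the model is fine-tuned on the balanced subset with weights
  (1, 0.9, 1.5, 1.2). Both stages use rectified-Adam (batch 32, weight
  decay 1e-5), a per-epoch cosine schedule
  η(t) = η_min + ½(η_max − η_min)(1 + cos(πt/T_max)) with T_max = 20,
  and early stopping on validation loss (patience 5, best weights
  restored).
- **Baselines.** Random minority oversampling (ROS, with replacement up
  to the maximum class count) and random majority undersampling (RUS,
  down to the minimum), applied to training folds only.
- **Evaluation.** Stratified k-fold cross-validation with rotating
  validation/test folds; evaluation folds are thresholded to the
  fine-tuning class ratios so all arms are scored on identical data.
  Per class: one-vs-rest accuracy, F1, sensitivity, specificity and
  rank-statistic AUC (percent), macro averages, overall accuracy, mean ±
  sd over folds, and ROC curves with pointwise std bands.

A synthetic fundus-image generator (circular retina field, optic
disc/cup geometry with class-conditional cup-to-disc ratio, exudate /
hemorrhage / drusen lesions, exposure and noise artifacts, heterogeneous
resolutions) makes the whole pipeline testable without external data,
and a compact self-contained CNN trainer (`tiny-cnn`, compiled conv
kernels, hand-written backprop verified against finite differences)
replaces GPU-scale backbones at desk scale. See the methods vignette
(`vignettes/fundus-imbalance-methods.Rmd`) for the full model
description and design rationale.

## Worked example

```r
library(fundusbalance)

# a small corpus with the merged-census imbalance ratios (1/100 scale)
corpus <- generate_corpus(census_ratio_counts(1 / 100),
                          synthesis_params(), out_dir = "demo-corpus",
                          seed = 1)
class_counts(corpus)
#>   NORMAL GLAUCOMA      AMD       DR
#>      864       38        6      344
#> attr(,"total")
#> [1] 1252

sp <- threshold_split(corpus, seed = 1)
sp
#> <split_result> threshold = 38
#> pretrain:   NORMAL GLAUCOMA      AMD       DR
#>      826        0        0      306
#> attr(,"total")
#> [1] 1132
#> finetune:   NORMAL GLAUCOMA      AMD       DR
#>       38       38        6       38
#> attr(,"total")
#> [1] 120

cosine_lr(c(0, 10, 20))   # the annealed learning rate at epochs 0/10/20
#> [1] 0.000300 0.000155 0.000010
```

The split keeps every glaucoma and AMD image for fine-tuning, caps
normal and DR at the glaucoma cardinality (38), and routes the 1,132
excess majority-class images to binary pre-training. A full three-arm
comparison on one corpus is a single call:

```r
cmp <- compare_methods(corpus, methods = c("twostage", "ros", "rus"),
                       k = 3, seed = 1)
cmp$table   # macro F1 / sensitivity / specificity / AUC, overall
            # accuracy (mean ± sd over folds) and the permuted-label
            # chance band per method
```

or, end to end with artifacts (config echo, manifests, fold plan,
metric tables, ROC bands, summary JSON):

```r
run_pipeline(pipeline_config(), out_dir = "demo-run")
```

A thin command-line wrapper is installed at
`inst/scripts/fundusbalance.R`:

```sh
Rscript inst/scripts/fundusbalance.R --config my-config.yaml --out run1 --seed 7
```

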