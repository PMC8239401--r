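# bidirtss

Promoters and enhancers both fire transcription divergently from a pair of
closely spaced transcription start sites (TSSs), but with different
transcript fates: promoter pairs couple an unstable antisense RNA with a
stable sense mRNA (unstable–stable, "US"), while enhancers produce unstable
RNA in both directions ("UU", the eRNA signature). `bidirtss` is an R
package for asking how far the DNA sequence of a fixed window around the
TSS-pair midpoint distinguishes the two classes, which positions carry the
signal, and how much of it is plain GC composition. It is aimed at
regulatory-genomics analysts who want a small, fully reproducible,
CPU-only pipeline for this question.

## What is in the box

* **Constrained CNN family.** Two zero-padded, stride-1 convolutional
  layers (ReLU), each followed by max-pooling whose stride equals its
  window, then a 512-unit hidden layer and one sigmoid output giving
  P(promoter). The pool windows are coupled, `pool_1 × pool_2 = 100`, and
  the window length `l` must divide by 100, so the flattened input to the
  hidden layer is `(l/100) × 128` for every member (640 at l = 500) and
  pooling configurations are comparable at fixed dense capacity. Training:
  Adam (lr 3e-4, per-step decay 1e-6), batches of 30, exactly 40 epochs,
  dropout 0.5, binary cross-entropy
  `L = −(1/N) Σ [z log y + (1−z) log(1−y)]`. The conv/pool engine is
  compiled (RcppArmadillo), deterministic under a seed, and
  finite-difference-checked in the tests.
* **Evaluation.** Stratified 90/10 hold-out split (training size rounded
  half up) plus stratified fivefold cross-validation; AU-ROC in the
  Mann–Whitney rank form with half credit for ties; sweep helpers for the
  seven pool pairs, filter counts 30–120 and filter sizes 9/19/29.
* **Gradient saliency.** Per-position importance = |∂score/∂x| at the
  observed channel, normalized per sequence to sum to 1; positions above
  the uniform share 1/l (0.002 at l = 500) are called important; aggregate
  maps over the top-predicted promoters (P > 0.95, top 50) in
  midpoint-relative coordinates.
* **Hexamer-SVM baseline.** 4096-dimensional hexamer frequencies (position
  information discarded) into an RBF SVM grid-searched over C = 2⁻³…2¹,
  γ = 2⁻¹³…2⁻¹ with the same CV protocol.
* **GC statistics.** `(G+C)/(A+T+G+C)` over whole windows,
  midpoint-relative slices such as [+20, +120), or pooled over
  saliency-important positions.
* **Synthetic generator.** Labelled windows with class-dependent global GC
  (63% vs 50%) and an elevated-GC downstream region at [+20, +120) (67% vs
  51%), optional planted motifs, byte-reproducible under a seed — so the
  whole pipeline is testable without external data.

## Worked example

Generate a synthetic dataset, hold out 10%, train the 90-filter pool-10
model, and inspect what it learned:

```r
library(bidirtss)

data <- generate_dataset(synthetic_spec(n_promoter = 300, n_enhancer = 300,
                                        seed = 4))
set.seed(99)
split <- bidirtss:::stratified_holdout(data$labels, 0.9)
fit <- train_model(data[split$train], architecture_spec(500),
                   training_spec(seed = 7))
test <- data[split$test]

compute_auroc(test$labels, predict(fit, test))
#> [1] 1

top  <- select_top_predictions(fit, data[data$labels == 1], top_n = 50)
map  <- aggregate_saliency(normalize_scores(compute_saliency(fit, top)))
region_mean(map, 20, 120)   # downstream importance
#> [1] 0.001994709
region_mean(map, -250, 0)   # upstream importance
#> [1] 0.001907976

regional_gc(data[data$labels == 1], c(20, 120))$mean
#> [1] 0.6721333
regional_gc(data[data$labels == 0], c(20, 120))$mean
#> [1] 0.5096333
```

The hold-out AUC of 1 says the planted composition difference is easily
separable at this size; the saliency mass over [+20, +120) exceeds the
upstream mean, i.e. the model concentrates importance on the region where
the promoter class is GC-enriched (0.67 vs 0.51 here, matching the
generator's parameters); the uniform-baseline share per position would be
1/500 = 0.002.

## Command line

A thin CLI over the same functions is installed at
`system.file("cli/regseq-tss", package = "bidirtss")` with subcommands
`simulate`, `encode`, `train`, `saliency`, `baseline`, `gcstats`.
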