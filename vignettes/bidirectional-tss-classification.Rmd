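---
title: "Classifying promoter and enhancer sequences at bidirectional TSSs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying promoter and enhancer sequences at bidirectional TSSs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Active promoters and enhancers both initiate transcription divergently from a
pair of closely spaced transcription start sites (TSSs). What differs is the
fate of the transcripts: a promoter pair couples an unstable antisense RNA
with a stable sense mRNA (an unstable–stable, "US", pair), while an enhancer
emits unstable RNA in both directions (a "UU" pair, the eRNA signature).
`bidirtss` asks whether the DNA sequence in a fixed window around the TSS-pair
midpoint suffices to tell the two classes apart, which sequence positions
carry that information, and how far simple composition (GC content) explains
it.

The package works on fixed-length windows — 500 bp (250 bp of flank on either
side of the midpoint) or 600 bp (300 bp flanks) — encoded one-hot with channel
order (A, C, G, T) and labelled promoter = 1, enhancer = 0. Windows are
oriented so that the stable (sense) TSS points in the +x direction; all
downstream coordinates such as "+20..+120 bp" are read in that frame as
half-open midpoint-relative intervals, `[+20, +120)`. Whether the original
US/UU windows were reverse-complemented to such a canonical frame is not
something the window coordinates record, so the package fixes this convention
and the synthetic generator produces data in it.

## The classifier family

The model is a deliberately constrained family of small convolutional
networks:

* convolution 1: `n_filters_1` filters (30 by default; 60/90/120 in wider
  variants) of odd size `filter_size_1` (9/19/29), stride 1, zero-padded to
  preserve length, ReLU;
* max-pool 1: window `pool_1`, stride equal to the window;
* convolution 2: 128 filters of size 5, same padding, ReLU;
* max-pool 2: window `pool_2 = 100 / pool_1`;
* a 512-unit ReLU hidden layer and a single sigmoid output giving
  P(promoter).

The two pool windows are coupled so their product is always 100, and the
input length must be divisible by 100. Consequently the flattened input to
the hidden layer is `(l / 100) * 128` values — 640 for 500-bp windows —
for *every* member of the family. This is the point of the constraint: one
can sweep the pooling configuration (the seven pairs (1,100), (2,50), (4,25),
(10,10), (25,4), (50,2), (100,1), named CNN-1 … CNN-100) while holding the
fully connected capacity fixed, so performance differences are attributable
to how much positional resolution each layer retains, not to parameter count
in the dense part. `hidden_input_size()` exposes the invariant and
`architecture_spec()` refuses uncoupled pools.

Training follows a fixed regime (`training_spec()`): mini-batch gradient
descent with batches of 30 sequences for exactly 40 epochs (no early
stopping), minimizing binary cross-entropy

L = −(1/N) Σᵢ [ zᵢ log yᵢ + (1 − zᵢ) log(1 − yᵢ) ]

with z the true labels and y the sigmoid outputs, under the Adam optimizer at
learning rate 3e-4 and a per-update decay of 1e-6, interpreted
multiplicatively as `lr_t = lr / (1 + decay · t)` at update step `t` (the
convention of the deep-learning frameworks of that generation; "per epoch"
would be the other reading, and the decay is small enough that the choice is
almost immaterial over 40 epochs). Inverted dropout with p = 0.5 is applied
after each convolutional layer's activation and after the hidden layer,
active only during training. Weights are Glorot-uniform; all randomness
(initialization, shuffling, dropout masks) is drawn from R's RNG under the
`training_spec()` seed, so a fixed seed reproduces a training run bit for
bit. The forward and backward passes are implemented in compiled code
(RcppArmadillo) with the convolutions unrolled into BLAS matrix products;
the gradient path is validated against a central-finite-difference oracle in
the test suite.

Evaluation (`cross_validate()`) first splits off a stratified 10% hold-out
test set — training size rounded half up, so 6,862 windows give 6,176/686 and
65,765 give 59,189/6,576 — then runs stratified fivefold cross-validation on
the training portion. Stratification is a package choice the evaluation
protocol itself leaves open; with a 1,884 / 4,978 class imbalance,
unstratified folds would add avoidable variance. Each fold-model is scored
by AU-ROC (the Mann–Whitney rank form, ties at half credit) on its
validation fold and on the hold-out set, and the summary metric is the mean
of the two AUC means, reported as mean ± sd over folds.
`run_architecture_sweep()` tabulates this over a spec list
(`pool_sweep_specs()`, `filter_count_sweep_specs()`,
`filter_size_sweep_specs()`).

## Saliency

For interpretation the package uses first-order (gradient) saliency. Around
a concrete input X the class score is locally S(X) ≈ wᵀX + b with w the
gradient of the score at X, obtained by one backward pass. The raw
importance of position i is |∂S/∂x_{i,c}| at the *observed* channel c (the
base actually present); per sequence the raw scores are normalized to sum
to 1, and a position is called *important* when its normalized score
strictly exceeds 1/l — the share every position of a perfectly
uninformative sequence would get: 0.002 for l = 500 and 1/600 ≈ 0.00167 for
l = 600. Uniform scores therefore call nothing important, and an all-zero
gradient (a degenerate model) is mapped to the uniform vector rather than
left undefined.

Three design points the saliency literature leaves open are fixed as
follows, each switchable:

* gradients are taken on the pre-sigmoid score, not the probability — this
  makes saliency invariant to output-bias shifts and avoids the vanishing
  `p(1−p)` factor on confident predictions (`target = "probability"`
  rescales);
* the per-position score is the absolute gradient at the observed channel
  (`reduce = "observed"`); the max-over-channels variant is available, but
  the sum-normalization presumes one non-negative score per position, which
  the observed-channel convention delivers naturally;
* dropout is disabled during saliency (inference mode).

Aggregate maps (`aggregate_saliency()`) stack the normalized scores of the
top-predicted promoters — the up-to-50 sequences with P(promoter) > 0.95,
`select_top_predictions()` — over midpoint-relative columns −l/2 … l/2−1,
and `region_mean()` reads off region summaries such as the mean importance
in [+20, +120).

## The hexamer-SVM baseline

The reference baseline encodes each window as frequencies of all 4⁶ = 4096
hexamers (sliding windows, stride 1, lexicographic A<C<G<T order; windows
containing N are skipped and the denominator reduced), discarding all
positional information, and trains a radial-basis-kernel SVM tuned by grid
search over C = 2⁻³…2¹ and γ = 2⁻¹³…2⁻¹ (65 combinations), each scored by
the same stratified fivefold-CV AU-ROC protocol as the CNN. The exponent
ranges are integer grids; base 2 is the dominant convention for RBF grids
and is configurable, since only the exponent ranges are prescribed. Raw
frequencies are used without further scaling. The kernel matrices are
precomputed from one BLAS-backed squared-distance matrix shared across the
γ grid, which is what makes the 65-point search cheap; the solver behind
the surface is kernlab's C-SVC. Comparing the positionally blind baseline
with the CNN isolates the value of *where* sequence features sit, not just
which k-mers occur.

## The synthetic generator

`synthetic_spec()` / `generate_dataset()` produce labelled windows with the
sequence-level structure that separates US from UU windows in real data:

| parameter | default | meaning |
|---|---|---|
| `l` | 500 | window length (bp), midpoint-centred |
| `n_promoter`, `n_enhancer` | 1000 each | class sizes |
| `promoter_gc_global` | 0.63 | whole-window GC of the promoter class |
| `enhancer_gc_global` | 0.50 | whole-window GC of the enhancer class |
| `promoter_gc_downstream` | 0.67 | GC over [+20, +120) |
| `enhancer_gc_downstream` | 0.51 | GC over [+20, +120) |
| `tss_spacing_*` | 120 / 91 | sense–antisense TSS distance (metadata) |

Each position is drawn independently; within the GC mass, G and C are
equally likely (the statistics being modelled are G+C totals, so the split
is unidentified and fixed at 50:50), likewise A and T. The non-downstream
positions get the GC level that makes the whole-window expectation equal
the global parameter — (l·gc_global − 100·gc_down)/(l − 100), e.g. 0.62 for
the promoter defaults — and parameter combinations that would push that
level outside (0, 1) are rejected at spec time. TSS spacing is carried as
metadata only (sense TSS at +spacing/2), at the class mean, since no
generated sequence feature depends on it. Optional motif plants overwrite
the background at a uniform position inside a stated window with a
per-class probability, recording the offset, which supports
splice-site/poly(A)-signal style experiments.

What the generator deliberately does *not* emulate: dinucleotide and CpG
structure (each site is independent), core-promoter motifs (TATA, Inr),
transcription-factor binding grammar, and any coupling between spacing and
sequence. Tests passing on this generator therefore demonstrate that the
pipeline recovers planted composition signals with correct coordinates and
calibrated null behaviour — not that real promoters and enhancers are
separable at any particular AUC; real-data performance claims are
explicitly out of scope here.

## GC statistics

`gc_content()` implements (G+C)/(A+T+G+C) with N excluded from both
numerator and denominator and an undefined (NA) result for an empty
effective set; `regional_gc()` applies it per sequence over a
midpoint-relative slice; `gc_at_important_positions()` pools G/C counts
over each sequence's important-position set across a group and reports the
count-weighted fraction — pooling is used rather than a mean of
per-sequence fractions because important sets vary in size (single-digit
sets would otherwise dominate the average); group percentages of this kind
do not record which aggregation produced them, so the package states its
choice.

## Numerical choices

* Probabilities are clipped to [1e-12, 1−1e-12] inside the loss only.
* Max-pool ties break to the first (leftmost) maximum; ReLU passes zero
  gradient at exactly 0.
* AUC uses average ranks, i.e. tied pairs count half.
* The degenerate all-zero saliency vector normalizes to uniform 1/l.
* The grid search takes the first maximum in enumeration order on ties, so
  reruns are identical.
* Finite-difference gradient checks abstain at coordinates where the two
  one-sided differences disagree (a ReLU/max-pool kink within ε of the
  input), where neither the analytic gradient nor any finite difference is
  the other's truth.

## Problem sizes used in the checks

The packaged checks run, on one CPU: signal detection with CNN-10(90) on the
default generator at n = 2000 (hold-out AUC and downstream saliency
localization of the top-predicted promoters, sign test across sequences); a
null control at n = 2000 with class-identical composition, where hold-out
AUC should sit in the chance band; and the CNN-vs-SVM comparison at
n = 1600 on purely positional signal (matched global GC 0.55, promoter
downstream 0.67), grid-searching the SVM on the full training split. GC
recovery uses 500 sequences per class, where the binomial standard error of
a class mean is ~0.2 percentage points.

## Limitations

* The engine is CPU-only and sized for these window lengths; it is not a
  general deep-learning framework.
* Saliency is a local first-order explanation; it does not decompose
  interactions, and alternatives (integrated gradients, DeepLIFT) are out
  of scope.
* The generator's independence assumption makes hexamer information
  essentially a function of composition; real k-mer grammar is richer, so
  the CNN-vs-SVM gap measured here speaks to positional signal only.
* Real-data AUCs depend on the underlying TSS-pair annotations and are not
  reproduced by the synthetic benchmark.
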