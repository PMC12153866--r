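---
title: "Methods: explainable cancer-type classification and informative mutational signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable cancer-type classification and informative mutational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infosig)
```

## Scope and model

infosig classifies cancer types from somatic single-nucleotide variant
catalogs and then asks *why* the classifier decides as it does. The chain
is: context counting under pyrimidine collapsing, a feed-forward classifier
under stratified cross-validation, layer-wise relevance propagation (LRP,
epsilon rule), and informative mutational signatures — per-class frequency
profiles paired with positive median feature relevance — with a
relevance-weighted distance and reference-catalog combination fitting on
top.

### Mutation-context features

Every substitution is reported on the strand whose reference base is a
pyrimidine; a purine reference is reverse-complemented together with its
flanks. This yields 6 substitution classes, 96 trinucleotide classes and
2 x 24 one-sided dinucleotide classes, 150 features in all. The dinucleotide
and single-nucleotide counts are computed as exact marginals of the
trinucleotide counts — they are mathematically determined by them, and the
row-sum identities (tri sum = mono sum = each one-sided di sum) are enforced
as invariants in the test suite. Flanks are always read from the reference
genome, not from the input records; a record whose stated reference base
disagrees with the genome is an error, while records at chromosome termini
or with a non-ACGT base in the window are skipped and tallied in a skip
report. Canonical column order is (substitution class, 5' flank, 3' flank)
for the 96, then the 24 five-prime and 24 three-prime dinucleotide features,
then the 6 classes; matrices are therefore byte-comparable.

Positional features cut the concatenated genome into fixed-size bins
(default 1 Mb), ignoring chromosome borders, keeping the final partial bin:
`ceiling(total length / bin size)` bins. Gene features count SNVs per named
interval; a mutation inside k overlapping genes increments all k — the
simplest reproducible rule. Region filtering (WGS / WES / WIIS) requires the
exon/intron/intergenic annotation to partition the genome and fails on any
unannotated position rather than silently dropping it. Coordinates follow
the native dialects: VCF positions are 1-based, BED intervals 0-based
half-open, and all internal interval arithmetic is 0-based half-open.

### Classifier

`network_spec()` defaults encode the selected architecture: 4 hidden layers
of 1024 relu units, learning rate 1.95e-4, dropout 1e-6, L2 penalty 1e-3, at
most 50 epochs, patience 10. Choices the architecture description leaves
open were fixed as follows and are all recorded in the spec object:

* **Optimizer** — Adam with the stated learning rate; the L2 penalty enters
  the gradient (classical weight decay). Adam is the community default for
  this architecture class and converges at desk scale within the 50-epoch
  cap.
* **Batching** — seeded mini-batches of 32 at every sample size. Full-batch
  training was considered and rejected: under a hard 50-epoch cap it allows
  only 50 gradient steps, which cannot converge at learning rates of order
  1e-4.
* **Input scaling** — per-feature standardization fitted on the training
  portion only (validation samples never touch the statistics), avoiding
  leakage across the fold boundary. Constant features get unit scale.
* **Early stopping** — "stagnation" means no strict improvement over the
  running best validation accuracy. After `patience` consecutive stagnant
  epochs training stops and the parameters of the last improving epoch are
  restored, so a run whose accuracy is constant from epoch 7 ends after
  epoch 17 with epoch-7 weights.
* **Dropout** — hidden layers only, inverted scaling, inactive at
  prediction and during the LRP forward trace.
* **Ties** — a tied maximal probability resolves to the lowest class index,
  deterministically.

Class weights are `N_total / N_class`, computed on the training portion of
each fold. Stratified folds divide each class separately into k near-equal
pieces (sizes differ by at most one; which folds take the remainder is
randomized under the seed). The high-confidence retraining round keeps
samples whose softmax confidence is *strictly* above the threshold (default
0.9).

### Relevance propagation

LRP initializes the output layer with the predicted class's pre-softmax
value and propagates backward with the sign-following epsilon rule; relu
layers propagate through the traced activations. Numerical choices:

* **epsilon** — default 1e-6; conservation checks use 1e-9. Small enough
  that on bias-free networks the input relevances sum back to the
  pre-softmax value within 1e-4, large enough to stabilize near-zero
  pre-activations.
* **Bias relevance is absorbed**, not redistributed: the rule as stated
  assigns input shares only via `a_i w_ij`.
* **Target class** — explanations target the *predicted* label (the class
  relevance statistics describe each predicted type); any fixed target can
  be requested.
* Relevance attaches to the standardized inputs the network actually
  consumes.
* Normalization divides by the total absolute relevance per prediction;
  all-zero rows are flagged and excluded from aggregation rather than
  producing NaNs.

The quantitative-LRP set walks features by descending absolute raw
relevance, accumulating the *signed* values, and stops at the first prefix
reaching 80% of the pre-softmax output (a config flag switches to
absolute-value accumulation for sensitivity analysis). Only positive
pre-softmax predictions are analyzed; if the threshold is unreachable the
full feature list is returned flagged. Driver candidates are genes appearing
in strictly more than a threshold fraction (20%, 10% or 2%) of a class's
per-sample sets.

### Informative signatures, distances and catalog fitting

The informative signature of a class is the mean of its samples'
count-normalized 96-context rows (zero-mutation samples excluded with a
warning) paired with `max(median normalized relevance, 0)` per feature.

The feature-focused distance between unit-sum profiles is the summed
absolute difference divided by 2 — its maximum, attained by disjoint
one-hot vectors, verified by brute force in the acceptance suite. The
relevance-weighted distance is

```
D(A, B) = sum_i (r_i^A + r_i^B) |f_i^A - f_i^B| / (max_i r_i^A + max_i r_i^B)
```

where each relevance vector is first clipped to its positive part and
renormalized to sum 1; this reading makes weights comparable across classes
and bounds D by 1 in the one-hot worst case (checked by brute force). For
fitting a single target against a catalog there is only one relevance
vector; the normalizer becomes `2 * max_i r_i`, the one-vector analog.

Catalog fitting searches all single signatures and all unordered pairs with
convex weights on a 0.05 grid. Pairs at a 0.05 step were chosen over
continuous optimization or larger arities because the search stays
exhaustive and exactly reproducible at desk scale (a few thousand
candidates for a 20-signature catalog); both the step and the restriction
to pairs are config arguments. A combination *fits* if its distance is
below 5% of the maximal distance.

### Evaluation utilities

Metrics are one-vs-rest precision, recall, F1 and MCC with unweighted macro
averaging; zero-denominator ratios are reported as 0 and flagged rather
than NaN, which keeps downstream aggregation stable. Feature testing uses
two-sided Wilcoxon rank-sum tests of per-sample counts — class versus the
pooled rest, and pairwise versus every other class with Holm-Bonferroni
adjustment within each class/feature family. The phrasing "comparison of
the mean number" is interpreted as a comparison of the count distributions
via the rank test; a rank test is not a test of means, and this reading is
deliberate. Unsupervised baselines (z-score PCA, average-linkage
agglomerative and k-means clustering under Euclidean distance) are thin
wrappers over `prcomp`, `hclust` and `kmeans` with constant columns dropped
before z-scoring.

## The synthetic cohort generator

The generator is the package's test surface: it emulates an imbalanced
multi-class cohort whose classes are convex mixtures of known 96-context
profiles, with log-normal per-sample mutation burden, on a toy genome with
exon/intron/intergenic and gene structure.

* **Placement** is rejection-free: the simulator indexes every interior
  genomic position by its collapsed reference trinucleotide (32 keys, both
  strands under pyrimidine collapsing) and samples uniformly within the
  matching key, so empirical context frequencies converge to the mixture
  profile (L1 < 0.05 at 1e5 draws, tested). When the site carries the
  purine strand the emitted ref/alt are complemented. Sites are unique
  within a sample — somatic SNV catalogs list unique positions — and
  chromosome termini are never chosen since no trinucleotide context
  exists there.
* **Burden** is log-normal, parameterized by its median and log-sd
  (defaults 500 and 0.5): mutation burdens in sequenced cohorts are
  heavy-tailed and right-skewed, and the log-normal is the standard
  desk-scale stand-in.
* **Metadata** (sex, age group) are drawn independently of class by
  default, so they cannot act as confounders; a config switch injects
  class-dependent frequencies for confounder-robustness experiments.
* **Driver hotspots**: `plant_driver_hotspots()` adds
  `Poisson((multiplier - 1) * c)` extra mutations to a gene for each
  affected sample with current count `c`, which multiplies the expected
  count by the factor without assuming anything about the gene's context
  composition; extra alt alleles are uniform over the three non-reference
  bases.

What the toy genome does *not* emulate — and therefore what passing tests
do not show about real data: genome-scale base composition bias (toy
sequence is i.i.d. uniform), mutation-rate covariation with replication
timing or chromatin, indels and structural variants, transcription-strand
asymmetry (no SBS192), and realistic gene/exon geometry. The bin count of a
real reference is likewise not reproduced: the package simply bins whatever
genome it is given, since the exact bin tally of a given assembly depends
on unstated region exclusions.

## Problem sizes and study conditions used in the checks

The cross-validated recovery experiment simulates 6 classes x 60 samples
(burden median 300, log-sd 0.5) on a 300 kb two-chromosome genome, with
each class profile concentrating 90% of its mass on 3 disjoint dominant
contexts. For these 150-feature, few-hundred-sample problems the
experiments use a reduced network (2 x 64 units, learning rate 1e-3) — the
default 4 x 1024 architecture is sized for cohorts of thousands of
genome-wide samples and is wildly over-parameterized for the toy setting,
where the smaller model trains to the same separation. All seeds are fixed
in the test files. Under these conditions the out-of-fold macro MCC
exceeds 0.9, the top-5 positive median relevance features of every class
recover at least 2 of its 3 planted contexts, and relevance-ordered feature
deletion degrades accuracy at least as fast as random deletion.

## Known limitations

* The classifier is a dense feed-forward network; no architecture search is
  performed beyond what `network_spec()` exposes.
* LRP is implemented for relu-affine stacks only (the architecture used);
  alpha-beta and gamma rule variants are out of scope.
* `fit_signature_combination()` does not refit per-sample exposures; it
  explains class-level profiles only, and de novo signature extraction
  (NMF) is out of scope.
* The relevance-weighted distance can exceed 1 for adversarial inputs with
  near-uniform relevance; on random unit-sum draws it stays within [0, 1]
  (property-tested), and the catalog-fitting decision only compares it to
  its own worst case.
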