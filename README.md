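# infosig

Explainable cancer-type classification from somatic mutation catalogs, and
**informative mutational signatures**: per-cancer-type mutation frequency
profiles weighted by how much each mutation class actually drives the
classifier's decision.

## The problem

Somatic single-base substitutions (SBS), counted in their trinucleotide
context under pyrimidine collapsing, form 96-dimensional *mutational
signatures* that reflect mutagenic exposures and impaired DNA-repair
mechanisms. Frequency profiles alone separate cancer types poorly: many
types share dominant processes (e.g. clock-like C>T deamination), so
unsupervised embeddings and clusterings of the profiles mix them. This
package takes the supervised, explainable route:

1. **Features.** From per-sample SNV catalogs (VCF) and a reference genome,
   build the 150-column context matrix — 96 trinucleotide (`A[C>T]G`), 48
   one-sided dinucleotide (`A[C>T]`, `[C>T]G`) and 6 bare substitution
   classes — plus megabase-bin mutation densities and per-gene mutation
   counts, each computable on the whole genome (WGS), the exome only (WES)
   or intronic+intergenic regions (WIIS).
2. **Classifier.** A feed-forward relu network (default 4 x 1024) trained
   with class-weighted cross-entropy (weight = N_total / N_class), L2
   penalty, dropout, stratified 10-fold cross-validation and early stopping
   on validation accuracy.
3. **Explanation.** Layer-wise relevance propagation with the epsilon rule:
   the pre-softmax output of the predicted class is redistributed backward,

   ```
   R_{i<-j} = z_ij / (z_j + eps) * R_j   (z_j >= 0)
   R_{i<-j} = z_ij / (z_j - eps) * R_j   (z_j <  0),   z_ij = a_i w_ij
   ```

   giving each input feature a signed relevance, normalized by the total
   absolute relevance per prediction.
4. **Informative signatures.** Per cancer type, pair the mean 96-context
   frequency profile with the positive median normalized relevance per
   feature; compare signatures by a relevance-weighted distance and explain
   them as convex combinations of a reference (COSMIC-style) catalog, with a
   5%-of-maximal-distance fitting rule. A *quantitative-LRP* set (the
   shortest descending-|relevance| prefix reaching 80% of the pre-softmax
   output) scores candidate driver genes.

A synthetic-cohort simulator with known ground-truth signature mixtures
makes every stage testable without controlled-access data.

## Worked example

Simulate three cancer types — two pure mutational processes and one 50/50
mixture — then classify, explain, and recover the mixture from the catalog:

```r
library(infosig)
library(dplyr)

ref  <- make_toy_reference(c(200000, 100000), exon_fraction = 0.1,
                           gene_count = 6, seed = 1)
sigs <- make_signature_set(3, n_dominant = 3, noise = 0.1, seed = 2)

cfg <- cohort_config(
  class_defs = list(typeA = c(sig01 = 1),
                    typeB = c(sig02 = 1),
                    typeC = c(sig02 = 0.5, sig03 = 0.5)),
  samples_per_class = c(typeA = 20, typeB = 20, typeC = 20),
  burden_median = 300, burden_sigma = 0.5, seed = 3)
cohort <- simulate_cohort(ref, sigs, cfg)
#> <synthetic_cohort> 60 samples, 19655 mutations, 3 classes

features <- context_features(cohort$mutations, ref,
                             samples = cohort$labels$sample_id)

spec <- network_spec(hidden_layers = 2, neurons_per_layer = 64,
                     learning_rate = 1e-3, seed = 4)
cv <- crossvalidate(features, cohort$labels, spec, k = 5, seed = 5)

truth <- cohort$labels$cancer_type[match(cv$predictions$sample_id,
                                         cohort$labels$sample_id)]
confusion_and_metrics(truth, cv$predictions$.pred)
#> <metrics_report> 3 classes
#>   macro: precision 0.921, recall 0.917, F1 0.917, MCC 0.877
```

Macro MCC 0.877 over the out-of-fold predictions: the network separates the
three processes almost perfectly even though typeB and typeC share a
component. Now explain the predictions and build informative signatures:

```r
rel <- bind_rows(lapply(seq_along(cv$models), function(f) {
  ids <- cv$folds$sample_id[cv$folds$fold == f]
  lrp_epsilon(cv$models[[f]], filter(features, sample_id %in% ids))
}))
stats <- aggregate_relevance(normalize_relevance(rel))

typeC_ids <- filter(cohort$labels, cancer_type == "typeC")$sample_id
sigC <- informative_signature(filter(features, sample_id %in% typeC_ids),
                              filter(stats, class == "typeC"))
fit_signature_combination(sigC, sigs)
#> <combination_fit> typeC: sig02 (0.50) + sig03 (0.50)
#>   distance 0.01122  [fits]
```

The relevance-weighted catalog fit recovers typeC's ground-truth 50/50
combination of sig02 and sig03 with a near-zero distance, well inside the
5% fitting rule. `autoplot(sigC)` draws the signature with relevance-scaled
bars; `tidy()` / `glance()` tidy the fitted objects.

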