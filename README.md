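# klrseq

Quantifying tissue-specific regulatory information in enhancer DNA
sequences with sparse gapped k-mer logistic regression.

Enhancers drive cell type-specific transcription, but genome
segmentations built from epigenetic marks only say *where* an enhancer
is active, not what in its sequence makes it tissue-specific. klrseq
trains classifiers that separate enhancer sequences active in one set
of tissues from enhancer sequences active in the remaining tissues, and
uses their cross-validated performance as a lower bound on the
tissue-specific information encoded in the DNA. Because the classifier
is a sparse linear model on interpretable features, its coefficients
double as a ranked list of candidate regulatory *code words* that can
be validated against ATAC-seq footprints. The package is aimed at
regulatory genomicists who have per-tissue element calls (BED), a
genome (FASTA), and optionally ATAC reads, and want an interpretable
sequence model rather than a black box.

## The model

Sequences are mapped to *code words*: equivalence classes
`p|q` of a gapped k-mer and its reverse complement (gap `n` matches any
base; `p <= q` under `a < c < g < n < t`). All words of length 4–8 with
concrete ends form a feature space of m = 156,570 dimensions. For
observations `x_i` (counts scaled to unit variance without centering,
or binary occurrences) and labels `y_i ∈ {0, 1}`, the model minimizes
the class-weighted ℓ1-penalized negative log-likelihood

    −Σ_i [ y_i w₁ log σ(x_i θ) + (1−y_i) w₀ log(1−σ(x_i θ)) ] + λ‖θ₋₀‖₁

with `w₀ = n / 2Σ(1−y_i)`, `w₁ = n / 2Σy_i` and an unpenalized
intercept. A just-in-time proximal SAGA solver handles the
high-dimensional sparse data, and a *leapfrog* search chooses λ so that
exactly `q` features carry nonzero coefficients. Tissue-bipartition
datasets (one-vs-rest "leaves", hierarchical-clustering "clustered"
collections, enhancer-vs-random, chromosome-split control), 10-fold
cross-validation with nested selection of q, stable-coefficient
merging, ATAC footprint aggregation (+4/−5 Tn5 shift, 2-bp reads), and
sliding-window genome scans complete the pipeline. A synthetic-data
generator with planted motifs makes every stage testable end to end.

## Worked example

```r
library(klrseq)

## the canonical gapped k-mer space
sp <- codeword_space(4, 4)
#> codeword_space: k = 4..4, m = 210 canonical code words
count_features("acgt", sp)
#> acgt|acgt acnt|angt annt|annt
#>         1         2         1
canonical_label("gataag")
#> [1] "cttatc|gataag"
```

The single 4-bp window of `acgt` matches its 2^(k−2) = 4 gappifications
once each: the palindromes `acgt|acgt` and `annt|annt` once, and the
class `acnt|angt` twice (once per orientation) — counts are exactly
reverse-complement invariant.

```r
## end-to-end planted-motif recovery on synthetic enhancers
rec <- recovery_experiment(seed = 101, n_per_tissue = 300)
rec$cv
#> klr_cv (random-stratified, 10 folds): pooled PR-AUC 0.757 (baseline 0.498), ROC-AUC 0.793
head(rec$top_words, 5)
#>   rank     code_word coefficient
#> 1    1 cttatc|gataag  0.53875678
#> 2    2 cttanc|gntaag  0.37693643
#> 3    3   gataa|ttatc  0.18712045
#> 4    4   ataag|cttat  0.06761300
#> 5    5   aggaa|ttcct  0.06082592
```

Two tissues were simulated (motifs `gataag` and `taaaca`, one mutated
copy per active element, per-position mutation 0.1); the classifier was
cross-validated on the liver-vs-rest dataset and the ten fold models
merged by minimum absolute coefficient. The planted liver code word
`cttatc|gataag` ranks first, followed by its gapped variants — the
pipeline recovers the planted signal from about 6000 candidate
features. The pooled PR-AUC (0.76 here, against a 0.50 baseline)
reflects the noise conditions, not the implementation: almost half the
planted copies are mutated, and `llr_oracle_scores()` gives the exact
Bayes ceiling of this configuration for comparison.

```r
## Tn5-shift round trip and footprint protection
fp <- footprint_experiment(seed = 301)
#> round-trip mismatches: 0; center/flank ratio: 0.37
```

Generated reads shift back to their sampled cut sites exactly, and a
cut-site depletion of 0.2 over planted motifs yields an aggregate
footprint whose center is well below the flanks, while the
element-center control profile stays flat.

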