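---
title: "Methods: enhancer prediction from ATAC-seq open-chromatin regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer prediction from ATAC-seq open-chromatin regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the feature definitions and their exact
conventions, the evaluation and importance procedures, the synthetic-data
generator that serves as the package's study conditions, and the main design
decisions and limitations. It is a methods reference, not a benchmark report:
quantitative results are produced only by the test suite and by
`scripts/acceptance.R`, never asserted here.

## Problem setting and assumptions

Given ATAC-seq open-chromatin regions (OCRs, narrowPeak calls) and the
fragment-level alignment evidence behind them, the task is to predict which
OCRs act as enhancers. Training labels are taken from a ChromHMM-style
chromatin-state segmentation available in reference cell types; the trained
classifier is then applied to samples where only ATAC-seq exists.

Assumptions: fragments are already deduplicated and filtered upstream (the
package does not deduplicate); coordinates follow the conventions of each
format — narrowPeak/BED/bedGraph are 0-based half-open, and all internal
interval arithmetic uses that convention; one genome build is shared by every
input.

## The 24 features

Features are computed per OCR from five sources. Exact conventions, chosen
once and applied identically everywhere:

**Peak-call features (5).** `peak_score`, `peak_length` (end − start),
`fold_change`, `summit_pileup` (number of fragments overlapping the summit
base), `summit_center_distance` (|summit − peak midpoint|).

**Insert/cut features (10).** A fragment overlaps a peak if the two
half-open intervals intersect. Insert sizes are binned with left-open,
right-closed brackets: (0, 50], (50, 150], (150, 300], (300, 500],
(500, ∞); counts and their total (`n_inserts_all`) plus the mean insert
size. `long_short_ratio` = (long + 1) / (short + 1), where *short* means
size ≤ 150 and the +1 pseudocounts keep the ratio finite for empty classes.
Each fragment contributes two Tn5 cut sites, at `start` and `end − 1`
(the last covered base). `n_cuts` counts cut sites inside the peak;
`n_overrepresented_cuts` counts 5-bp windows whose cut count k is both
greater than the uniform expectation and has upper binomial tail
P(X ≥ k) < 5 × 10⁻⁴ under a uniform-cut null within the peak.

**Sequence features (4).** `conservation_mean` (bedGraph track averaged
over covered bases), `gc_pct`, `cpg_pct` (CG dinucleotides over
length − 1 possible positions, as a percentage), and `n_ctcf_motifs`.

**Motif features (2 + CTCF above).** `known_motif_pct` and
`denovo_motif_pct`: percent of peak bases covered by at least one motif hit
from the respective PWM set. Scanning uses `Biostrings::countPWM`-style
log₂-odds scores on both strands with a per-motif threshold of 0.8 × the
maximum achievable score. Both-strand scanning means a palindromic
consensus yields two hits at one site; this is intentional and tested.

**Location features (3).** `annotation_code` (categorical: promoter-proximal
/ intragenic / intergenic, encoded as small integers), signed-magnitude
`tss_distance` to the nearest transcription start site, and `gene_type_code`
for the nearest gene's biotype. Categorical codes enter the network as
numeric codes; this matches the flat feature-vector design and is documented
rather than hidden.

## Labeling from a segmentation

`assign_state()` gives each peak the chromatin state with the largest
base-pair overlap; ties break by a fixed state-priority order so results
never depend on input order. `default_state_mapping()` collapses states to
classes: EnhA/Enh/EnhWk → enhancer; TssA/Tss/TssFlnk → promoter;
Tx/TxWk/Ins/ReprPC/Quies → other; genic-enhancer (EnhG), ambiguous and
unsegmented peaks are excluded from training because their class identity is
uncertain. When two segmentations must be harmonized,
`harmonize_states()` clusters pooled emission rows by 1 − Pearson distance
with average-linkage hierarchical clustering (k = 10 by default) and flags
the cluster with maximal CTCF emission as insulator. The cluster-to-class
map is configuration, not code, so users can audit and override it.

## Classifier

The native classifier is a single-hidden-layer perceptron: ReLU hidden
layer, softmax output, full-batch Adam (β₁ = 0.9, β₂ = 0.999), L2 weight
decay, He-scaled initialization. Defaults (`mlp_hyperparams()`): 16 hidden
units, L2 = 10⁻⁴, learning rate 0.01, max 300 epochs, early stopping on a
10% validation split with patience 25. All randomness flows through a
single integer seed via `child_seed()`, a Lehmer-style mixer that keeps all
derived seeds below 2³¹, so fits are exactly reproducible.

An OCR is called an enhancer when P(enhancer) > 0.5 strictly; a probability
of exactly 0.5 is a negative call. Training sets are class-balanced by
downsampling the majority class; features are standardized to training-set
mean/SD. In `cross_validate()` (stratified k-fold), balancing and
standardization are refit within each fold and fold probabilities are pooled
for one ROC/PRC curve — no held-out information touches any training step.
ROC AUC is computed as the concordance rank statistic (ties half-weighted);
PRC AUC by step interpolation. Baselines (logistic regression, LDA, QDA,
SVM, random forest, k-NN) wrap established implementations (`stats`,
`MASS`, `e1071`, `randomForest`, `class`) behind the same interface; the
contribution — the MLP, the features and the analysis algorithms — is
implemented natively.

## Feature importance

Both procedures hold the architecture fixed and operate *after*
standardization, masking features to zero — i.e., pinning them at their
training means, which is the neutral input for a standardized network:

- **Single-feature models**: all but one feature masked; the feature's
  cross-validated AUC measures its marginal signal.
- **Backward elimination**: each round masks one additional feature,
  keeping whichever removal maximizes mean CV accuracy (ties broken by
  canonical feature order); the full pipeline (balance, standardize, fit)
  is re-run for every candidate, and the trace records AUC after each
  removal down to a single surviving feature.

Masking instead of retraining on a reduced design keeps the comparison
architecture-invariant and makes rounds comparable.

## Cohort analyses

`consensus_peaks()` merges per-individual peaks by single-linkage overlap
per chromosome and keeps consensus loci supported by at least
`min_samples` individuals. Leave-one-individual-out evaluation
(`loio_evaluate()`) trains on all-but-one individual *and* only on training
loci from a disjoint locus split, so neither individuals nor genomic loci
leak between train and test.

The caQTL analysis asks whether predicted enhancer probability tracks
genotype at chromatin-accessibility QTLs. Variants map to OCRs within
±100 bp (closest-to-midpoint when several qualify). Per variant, the
point-biserial correlation is the Pearson correlation between per-individual
P(enhancer) and the carrier indicator (dosage ≥ 1 of the opening allele);
variants whose genotypes do not stratify the cohort are excluded with a
reason. caQTL and control variant correlations are compared by a one-sided
Wilcoxon rank-sum test (caQTL greater). `caqtl_analysis()` refuses to run —
hard error, not a warning — if the model's embedded `training_loci`
manifest intersects the tested loci, making train/test leakage structurally
impossible. `annotation_refinement()` counts OCR × individual rows whose
segmentation class is non-enhancer but whose predicted probability exceeds
0.5 ("rescued"), the mechanism for refining reference annotations at
disease-associated loci.

## Synthetic data generator

The generator is the package's study condition: its defaults were chosen
once, for realism, and are never tuned to test outcomes.

- **Reference layout**: slot anchors every 3000 bp; slot types drawn
  promoter/enhancer/background with probability 0.25/0.40/0.35. Enhancer
  and promoter slots get planted GC islands and consensus motifs (planting
  probability 0.60/0.35/0.15 by type); a conservation track is emitted with
  *locus-level* variance (a per-slot level plus per-bin noise), because real
  conservation varies between loci — a single per-type level would make
  conservation an unrealistically clean classifier.
- **Fragments**: per-region counts are negative binomial with mean 100
  (enhancer), 200 (promoter), 40 (background) and dispersion 0.3; insert
  sizes come from a 3-component normal mixture at 60/200/400 bp with
  class-specific weights, mimicking nucleosome-free, mono- and
  di-nucleosomal fragments.
- **Cohorts**: Hardy–Weinberg genotypes at allele frequency 0.4; caQTL
  variants scale a region's fragment mean by effect^(dosage − 1), so
  heterozygous reference is the baseline; an individual's peak is called
  only when it has ≥ 10 fragments (`peak_min_count`), so low-accessibility
  individuals genuinely lack predictions.
- **Determinism**: every emitted float is quantized to 6 significant
  figures so that writing the fixture files and re-reading them reproduces
  the in-memory feature matrix byte-identically.

What the generator does *not* emulate: mappability artifacts, copy-number
variation, GC amplification bias, linkage between variants, cell-type
mixtures, or real motif grammar. Conclusions about the method's behaviour on
real data must come from real data.

The importance-analysis tests additionally use `simulate_labeled_features()`,
a direct feature-level simulator with explicitly graded effect sizes and
pure-noise features. This is deliberate: in the full generative pipeline
almost every feature carries some signal and several carry none by
construction, so "the injected noise feature is eliminated first" is only a
well-posed expectation when effect sizes are controlled at the feature
level.

## Numerical and design choices

- Binomial tails use `stats::pbinom(k − 1, n, p, lower.tail = FALSE)`;
  Fisher tests and rank-sum tests use `stats::fisher.test` /
  `stats::wilcox.test` (exact where applicable). These are standard,
  well-tested primitives; the test suite still cross-checks them against
  independent enumerations.
- Interval joins use `IRanges::findOverlaps`; sequence handling uses
  `Biostrings`. Reimplementing either would add risk without insight.
- Seeds: every stochastic step takes a seed derived by `child_seed(seed, i)`
  so separate stages draw from independent, reproducible streams.
- Promoters can be kept as a third class, merged into *other*, or excluded;
  the two-class enhancer-vs-other configuration is the default because it
  matches the downstream use (enhancer calling).

## Limitations

- Categorical features enter as integer codes, not one-hot (the default;
  one-hot encoding is available via `mlp_hyperparams(one_hot = TRUE)`), so
  the network sees an artificial ordering of annotation categories.
- The strict 0.5 calling threshold is untuned; applications that need
  calibrated probabilities should recalibrate on their own data.
- The segmentation is treated as ground truth during training even though
  the refinement analysis exists precisely because it is imperfect; label
  noise therefore bounds achievable apparent accuracy.
- Backward elimination is greedy; it does not explore feature subsets and
  can keep a redundant feature if an early removal was unlucky.
- The generator's simplifications (above) mean synthetic performance levels
  should be read as internal-consistency checks, not forecasts for real
  tissue.
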