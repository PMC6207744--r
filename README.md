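# enhancerpred

Neural-network prediction of enhancer activity from ATAC-seq open-chromatin
regions (OCRs).

Chromatin-state annotations of regulatory elements (enhancers, promoters)
usually require a panel of histone-modification ChIP-seq assays, which is
impractical for many primary samples. This package implements an alternative:
it learns to recognize enhancers from a **single ATAC-seq experiment**, using
24 features computed per OCR from the peak calls, the fragment-level insert
and cut-site structure of the ATAC signal, the underlying sequence
(GC/CpG content, conservation, known/de-novo motif coverage, CTCF motifs),
and genomic location relative to gene annotation. Labels for training come
from an existing chromatin-state segmentation (ChromHMM-style) in cell types
where one is available; the trained model then transfers to samples where
only ATAC-seq exists.

Intended audience: computational genomics groups working with ATAC-seq in
primary tissues, e.g. for interpreting disease-associated non-coding variants.

## Model

Each OCR \(i\) is summarized by a feature vector \(x_i \in \mathbb{R}^{24}\)
(standardized per training set) with class label \(y_i \in\)
{enhancer, promoter, other} (or the two-class collapse, promoter merged into
*other* or dropped, depending on the labeling configuration). The classifier
is a single-hidden-layer perceptron

\[ p(y \mid x) = \mathrm{softmax}\big(W_2\, \mathrm{ReLU}(W_1 x + b_1) + b_2\big) \]

trained by full-batch Adam with L2 weight decay, He initialization, and early
stopping on a 10% validation split. An OCR is *called* an enhancer when
\(p(\text{enhancer} \mid x) > 0.5\) (strictly). Training sets are
class-balanced by downsampling; standardization, balancing and model fitting
are all refit inside every cross-validation fold so no information leaks from
held-out data. Five baseline families (logistic regression, LDA/QDA, SVM,
random forest, k-NN) are available for comparison via `train_baseline()`.

Feature importance is measured two ways, both holding the architecture
fixed: single-feature models (all other features zero-masked after
standardization, i.e. fixed at their training means) and backward elimination
(repeatedly dropping the feature whose removal best preserves mean CV
accuracy).

For cohorts of individuals, the package builds consensus OCRs across samples,
evaluates generalization by leave-one-individual-out (LOIO) splits that also
hold out loci, and tests whether predicted enhancer probabilities respond to
chromatin-accessibility QTL genotypes (point-biserial correlation per
variant, one-sided rank-sum comparison of caQTL vs. control variants).

All inputs are standard formats: FASTA genomes, narrowPeak peak calls, BED
fragment files, bedGraph conservation tracks, JASPAR PFM motif files, and
BED segmentations. A self-contained synthetic-data generator
(`generate_reference()`, `generate_celltype()`, `generate_cohort()`) produces
realistic datasets in these same formats for testing and demonstration.

## Worked example

```r
library(enhancerpred)

# 1. Simulate a reference and one cell type at the package defaults
ref <- generate_reference(seed = 1, n_chroms = 1, chrom_len = 2e6)
ct  <- generate_celltype(ref, n_per_class = c(enhancer = 200, other = 200),
                         seed = 2)

# 2. Extract the 24 features for every open-chromatin region
fm <- build_feature_matrix(ct$peaks, ct$fragments, ref$genome,
                           ref$conservation, ref$pwms_known, ref$pwms_denovo,
                           ref$annotation)
dim(fm)
#> [1] 400  25        # peak_id column + 24 features
round(fm[1:3, c("peak_length", "n_inserts_all", "long_short_ratio", "gc_pct")], 3)
#>   peak_length n_inserts_all long_short_ratio gc_pct
#> 1         284            60            2.100 40.493
#> 2         518           113            0.769 40.734
#> 3         458           125            0.740 40.393

# 3. Label peaks from the chromatin-state segmentation
labels <- label_peaks(ct$peaks, ct$segmentation)
table(labels)
#> enhancer    other
#>      200      200
ds <- labeled_dataset(fm, labels, "example_celltype")

# 4. Five-fold cross-validation of the neural network
cv <- cross_validate(ds, k = 5, seed = 3)
round(unlist(cv$pooled[c("roc_auc", "prc_auc", "accuracy_at_0.5")]), 4)
#>         roc_auc         prc_auc accuracy_at_0.5
#>          0.9943          0.9968          0.9900

# 5. Train on everything and score new regions
model <- train_mlp(downsample_balance(ds, seed = 4), seed = 5)
pr <- predict(model, ds$features)
head(round(pr$prob, 3))
#>                     enhancer other
#> synthetic_peak00001        0     1
#> synthetic_peak00002        1     0
#> synthetic_peak00003        1     0
#> ...
```

To read real data instead of simulating it, use `read_narrowpeak()`,
`read_fragments_bed()`, `read_fasta_genome()`, `read_bedgraph()`,
`read_jaspar_pfms()`, `read_segmentation_bed()` and
`read_gene_annotation()`; the pipeline from step 2 onward is identical.

## Interface

The package's interface is its exported R functions, the `scripts/`
entry point above, and the methods vignette
(`vignettes/enhancer-prediction-methods.Rmd`); there is no separate binary
CLI.

## License

MIT (see `LICENSE`).
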