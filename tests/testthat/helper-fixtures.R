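# Shared fixtures, built once per test run. Everything is generated in code;
# no files ship with the package.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small reference shared by feature/labeling/synthetic tests.
tiny_reference <- function() {
  cached("tiny_reference", generate_reference(seed = 101, n_chroms = 1, chrom_len = 2e5))
}

# Large reference for the end-to-end recovery checks: enough free slots for
# 1000 regions/class plus three disjoint synthetic cell types.
big_reference <- function() {
  cached("big_reference", generate_reference(seed = 701, n_chroms = 3, chrom_len = 3e6))
}

# Full-pipeline labeled dataset at n = 1000/class on the big reference.
big_dataset <- function() {
  cached("big_dataset", {
    ref <- big_reference()
    ct <- generate_celltype(ref, n_per_class = c(enhancer = 1000, other = 1000),
                            seed = 702)
    fm <- build_feature_matrix(ct$peaks, ct$fragments, ref$genome,
                               ref$conservation, ref$pwms_known, ref$pwms_denovo,
                               ref$annotation)
    labeled_dataset(fm, label_peaks(ct$peaks, ct$segmentation), "sim_celltype")
  })
}

# Larger reference for cohort tests (more free slots per class).
cohort_reference <- function() {
  cached("cohort_reference", generate_reference(seed = 202, n_chroms = 1, chrom_len = 5e5))
}

# A modest cell type on that reference.
tiny_celltype <- function() {
  cached("tiny_celltype", {
    generate_celltype(tiny_reference(),
                      n_per_class = c(enhancer = 20, promoter = 10, other = 20),
                      seed = 11)
  })
}

make_peak <- function(chrom = "chr1", start = 100L, end = 200L, name = "p1",
                      summit_offset = (end - start) %/% 2L, fold_change = 5,
                      peak_score = 100, neglog10_p = 5, neglog10_q = 3) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, peak_score = peak_score, strand = ".",
             fold_change = fold_change, neglog10_p = neglog10_p,
             neglog10_q = neglog10_q, summit_offset = as.integer(summit_offset),
             stringsAsFactors = FALSE)
}

make_fragments <- function(starts, ends, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(starts)), start = as.integer(starts),
             end = as.integer(ends), size = as.integer(ends - starts),
             stringsAsFactors = FALSE)
}

# Consensus-like PWM: probability p_match on the consensus base per column.
make_consensus_pwm <- function(consensus, id = "pwm1", is_ctcf = FALSE,
                               p_match = 0.97) {
  bases <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - p_match) / 3, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) mat[bases[j], j] <- p_match
  list(id = id, matrix = mat, is_ctcf = is_ctcf, score_threshold = NA_real_)
}

# Brute-force ROC AUC: fraction of concordant positive/negative pairs,
# ties counted one half.
bruteforce_auc <- function(probs, y) {
  pos <- probs[y]; neg <- probs[!y]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Exact upper binomial tail by summation (independent of pbinom's tail path).
binom_tail_sum <- function(k, n, p) {
  if (k > n) return(0)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

expect_tsv_roundtrip <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, path)
  back <- read_table_tsv(path)
  expect_equal(names(back), names(df))
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      expect_equal(signif(back[[j]], 6), signif(df[[j]], 6))
    } else {
      expect_equal(back[[j]], df[[j]])
    }
  }
}
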