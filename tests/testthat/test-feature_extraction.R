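# Feature extraction: each extractor against hand-computed or brute-force
# oracles, plus the structural invariants of the 24-column matrix.

test_that("peak features follow the narrowPeak fields and fragment coverage", {
  peak <- make_peak(start = 100, end = 200, summit_offset = 50)
  f <- extract_peak_features(peak, make_fragments(integer(), integer()))
  expect_equal(unname(f[c("peak_length", "summit_pileup", "summit_center_distance")]),
               c(100, 0, 0))
  f2 <- extract_peak_features(make_peak(start = 100, end = 200, summit_offset = 10),
                              make_fragments(integer(), integer()))
  expect_equal(unname(f2["summit_center_distance"]), 40)  # |110 - 150|
  # coverage at the summit base: [140,180) covers 150, [10,90) does not
  f3 <- extract_peak_features(make_peak(start = 100, end = 200, summit_offset = 50),
                              make_fragments(c(140, 10), c(180, 90)))
  expect_equal(unname(f3["summit_pileup"]), 1)
})

test_that("insert sizes bin by the (a,b] bracket convention", {
  sizes <- c(40, 60, 150, 151, 300, 301, 500, 501)
  frags <- make_fragments(rep(0, 8), sizes)
  f <- extract_insert_features(make_peak(start = 0, end = 1000, summit_offset = 1), frags)
  expect_equal(unname(f[c("n_inserts_0_50", "n_inserts_50_150", "n_inserts_150_300",
                          "n_inserts_300_500", "n_inserts_500_plus")]),
               c(1, 2, 2, 2, 1))
  expect_equal(unname(f["n_inserts_all"]), 8)
  expect_equal(unname(f["insert_size_mean"]), 250.375)
})

test_that("long/short ratio uses +1 pseudocounts with 150 counting short", {
  frags <- make_fragments(c(0, 0, 0), c(100, 100, 200))
  f <- extract_insert_features(make_peak(start = 0, end = 500, summit_offset = 1), frags)
  expect_equal(unname(f["long_short_ratio"]), 2 / 3)
  # no fragments at all: ratio 1/1, mean 0
  f0 <- extract_insert_features(make_peak(), make_fragments(integer(), integer()))
  expect_equal(unname(f0["long_short_ratio"]), 1)
  expect_equal(unname(f0["insert_size_mean"]), 0)
})

test_that("cut sites are fragment start and end-1, counted inside the peak", {
  peak <- make_peak(start = 100, end = 200)
  cuts <- cut_sites(peak, make_fragments(150, 400))
  expect_equal(cuts, 150L)  # end-1 = 399 falls outside
  f <- extract_insert_features(peak, make_fragments(150, 400))
  expect_equal(unname(f["n_cuts"]), 1)
  # both ends inside
  expect_equal(sort(cut_sites(peak, make_fragments(120, 180))), c(120L, 179L))
})

test_that("over-represented cut windows match the exact binomial tail", {
  peak <- make_peak(start = 0, end = 50, summit_offset = 25)
  expect_equal(count_overrepresented_cuts(peak, integer()), 0L)
  # 20 cuts all in window 1: P(X>=20 | n=20, p=0.1) = 0.1^20 << 0.0005
  expect_equal(count_overrepresented_cuts(peak, rep(2L, 20)), 1L)
  # 2 cuts in each window: P(X>=2 | 20, 0.1) ~ 0.608 -> none called
  spread <- rep(seq(0, 45, by = 5), each = 2)
  expect_equal(count_overrepresented_cuts(peak, spread), 0L)
  expect_error(count_overrepresented_cuts(peak, 1L, window = 0), "positive")
})

test_that("over-represented cut counts equal an enumeration oracle on random peaks", {
  oracle <- function(peak, cuts, window = 5L, alpha = 5e-4) {
    len <- peak$end - peak$start
    n_win <- ceiling(len / window)
    called <- 0L
    for (w in seq_len(n_win)) {
      lo <- peak$start + (w - 1L) * window
      hi <- min(peak$start + w * window, peak$end)
      k <- sum(cuts >= lo & cuts < hi)
      p <- (hi - lo) / len
      if (k > length(cuts) * p && binom_tail_sum(k, length(cuts), p) < alpha) {
        called <- called + 1L
      }
    }
    called
  }
  set.seed(42)
  for (i in 1:300) {
    len <- sample(8:200, 1)
    peak <- make_peak(start = 1000, end = 1000 + len, summit_offset = len %/% 2)
    n_cuts <- sample(0:50, 1)
    # mixture of clustered and uniform cuts so some windows are truly enriched
    cuts <- c(sample(peak$start:(peak$end - 1), min(n_cuts, len), replace = TRUE),
              rep(peak$start + sample(0:(len - 1), 1), sample(0:15, 1)))
    expect_equal(count_overrepresented_cuts(peak, cuts), oracle(peak, cuts))
  }
})

test_that("GC and CpG percentages follow their definitions, case-insensitively", {
  expect_equal(enhancerpred:::gc_percent("GGCC"), 100)
  expect_equal(enhancerpred:::gc_percent("ggcc"), 100)
  expect_equal(enhancerpred:::gc_percent("GCAT"), 50)
  expect_equal(enhancerpred:::gc_percent("GCATNN"), 100 * 2 / 6)  # N in denominator
  expect_equal(enhancerpred:::cpg_percent("CGCG"), 100 * 2 / 3)
  expect_equal(enhancerpred:::cpg_percent("cgcg"), 100 * 2 / 3)
  expect_equal(enhancerpred:::cpg_percent("CCCC"), 0)
  # overlapping-context count: CGCGCG has CG at 1,3,5
  expect_equal(enhancerpred:::cpg_percent("CGCGCG"), 100 * 3 / 5)
})

test_that("conservation averages bedGraph coverage with missing bases as 0", {
  ref <- tiny_reference()
  peak <- make_peak(chrom = "chr1", start = 10, end = 60)
  cons <- data.frame(chrom = "chr1", start = c(0L, 30L), end = c(20L, 40L),
                     score = c(0.5, 1.0))
  f <- extract_sequence_features(peak, ref$genome, cons)
  # covered: 10 bp at 0.5 + 10 bp at 1.0 over 50 bp
  expect_equal(unname(f["conservation_mean"]), (10 * 0.5 + 10 * 1) / 50)
  f0 <- extract_sequence_features(peak, ref$genome, NULL)
  expect_equal(unname(f0["conservation_mean"]), 0)
})

test_that("PWM scanning finds consensus hits on both strands symmetrically", {
  # ACGT is its own reverse complement, so a double-strand scan counts each
  # occurrence on both strands
  pwm <- make_consensus_pwm("ACGT")
  expect_equal(scan_pwm("TTACGTTT", pwm), 2L)
  expect_equal(scan_pwm("AAACGTAA", pwm), 2L)
  expect_equal(scan_pwm("AAAAAA", pwm), 0L)
  expect_equal(scan_pwm("ACG", pwm), 0L)  # shorter than motif
  # non-palindromic consensus: one forward hit, found once
  np <- make_consensus_pwm("AACGTG")
  expect_equal(scan_pwm("TTAACGTGTT", np), 1L)
  # and the reverse-complement sequence yields the same single hit
  expect_equal(scan_pwm("AACACGTTAA", np), 1L)
  # strand symmetry on random sequences
  set.seed(7)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(scan_pwm(s, pwm), scan_pwm(rc, pwm))
  }
})

test_that("motif features binarize known/denovo hits but sum CTCF counts", {
  known <- list(make_consensus_pwm("ACGTAC", "k1"),
                make_consensus_pwm("TTTTCC", "k2"),
                make_consensus_pwm("GGGGAA", "k3"),
                make_consensus_pwm("CCAGGTT", "ctcf1", is_ctcf = TRUE))
  denovo <- list(make_consensus_pwm("ACGTGT", "d1"))
  seq <- paste0("ACGTAC", "TTAAGG", "ACGTAC", "CCAGGTT", "AAA", "CCAGGTT", "TCAA")
  f <- extract_motif_features(seq, known, denovo)
  # k1 hits twice (binarized), k2/k3 absent, ctcf1 hits twice (counted)
  expect_equal(unname(f["known_motif_pct"]), 100 * 2 / 4)
  expect_equal(unname(f["n_ctcf_motifs"]), 2)
  expect_equal(unname(f["denovo_motif_pct"]), 0)
  expect_error(extract_motif_features(seq, list(), denovo), "empty known")
})

test_that("location features give signed TSS distance and fixed codes", {
  ann <- list(tss = data.frame(chrom = "chr1", pos = 1000L, strand = "+",
                               gene_id = "g1", gene_type = "protein_coding"),
              contexts = data.frame(chrom = "chr1", start = 900L, end = 1100L,
                                    label = "promoter-TSS"))
  class(ann) <- "gene_annotation"
  # summit at 1500, TSS at 1000 (+) -> +500
  f <- extract_location_features(make_peak(start = 1400, end = 1600,
                                           summit_offset = 100), ann)
  expect_equal(unname(f["tss_distance"]), 500)
  # summit exactly on the TSS -> 0, and promoter-TSS context code
  f0 <- extract_location_features(make_peak(start = 950, end = 1050,
                                            summit_offset = 50), ann)
  expect_equal(unname(f0["tss_distance"]), 0)
  expect_equal(unname(f0["annotation_code"]),
               unname(location_vocabularies()$annotation["promoter-TSS"]))
  # minus strand flips the sign
  ann$tss$strand <- "-"
  fm <- extract_location_features(make_peak(start = 1400, end = 1600,
                                            summit_offset = 100), ann)
  expect_equal(unname(fm["tss_distance"]), -500)
  # unknown labels collapse to the "other" code
  ann$tss$gene_type <- "weird"
  fo <- extract_location_features(make_peak(start = 1400, end = 1600,
                                            summit_offset = 100), ann)
  expect_equal(unname(fo["gene_type_code"]),
               unname(location_vocabularies()$gene_type["other"]))
})

test_that("feature matrix has canonical shape, is deterministic and finite", {
  ref <- tiny_reference()
  ct <- tiny_celltype()
  fm1 <- build_feature_matrix(ct$peaks, ct$fragments, ref$genome, ref$conservation,
                              ref$pwms_known, ref$pwms_denovo, ref$annotation)
  expect_equal(names(fm1), c("peak_id", feature_names()))
  expect_equal(nrow(fm1), nrow(ct$peaks))
  expect_true(all(is.finite(as.matrix(fm1[, -1]))))
  # identical run -> byte-identical TSV
  fm2 <- build_feature_matrix(ct$peaks, ct$fragments, ref$genome, ref$conservation,
                              ref$pwms_known, ref$pwms_denovo, ref$annotation)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_table(fm1, p1); write_table(fm2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # zero-fragment peak stays finite
  far <- make_peak(chrom = "chr1", start = 50, end = 180, name = "empty")
  fm0 <- build_feature_matrix(far, ct$fragments[0, ], ref$genome, ref$conservation,
                              ref$pwms_known, ref$pwms_denovo, ref$annotation)
  expect_true(all(is.finite(as.matrix(fm0[, -1]))))
  expect_equal(fm0$n_inserts_all, 0)
})

test_that("insert bins always sum to the total insert count", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(0:60, 1)
    starts <- sample(0:2000, n, replace = TRUE)
    sizes <- sample(1:900, n, replace = TRUE)
    f <- extract_insert_features(make_peak(start = 0, end = 3000, summit_offset = 1),
                                 make_fragments(starts, starts + sizes))
    expect_equal(unname(f["n_inserts_0_50"] + f["n_inserts_50_150"] +
                          f["n_inserts_150_300"] + f["n_inserts_300_500"] +
                          f["n_inserts_500_plus"]),
                 unname(f["n_inserts_all"]))
    expect_lte(unname(f["n_cuts"]), 2 * unname(f["n_inserts_all"]))
  }
})

test_that("strict mode aborts with the peak id; lenient mode drops and warns", {
  ref <- tiny_reference()
  bad <- make_peak(chrom = "chr1", start = 0, end = 10 + length(ref$genome[[1]]),
                   name = "overhang", summit_offset = 5)
  expect_error(
    build_feature_matrix(bad, make_fragments(integer(), integer()), ref$genome,
                         ref$conservation, ref$pwms_known, ref$pwms_denovo,
                         ref$annotation),
    "overhang")
  ok <- make_peak(chrom = "chr1", start = 100, end = 300, name = "fine")
  expect_warning(
    fm <- build_feature_matrix(rbind(ok, bad), make_fragments(integer(), integer()),
                               ref$genome, ref$conservation, ref$pwms_known,
                               ref$pwms_denovo, ref$annotation, mode = "lenient"),
    "overhang")
  expect_equal(fm$peak_id, "fine")
})
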