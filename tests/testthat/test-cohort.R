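# Cohort analysis: consensus peaks, leave-one-individual-out evaluation,
# point-biserial correlations, the caQTL rank-sum comparison and annotation
# refinement.

test_that("consensus peaks merge by single linkage and honor min_samples", {
  p1 <- make_peak(start = 100, end = 300, name = "a")
  p2 <- make_peak(start = 250, end = 450, name = "b")
  p3 <- make_peak(start = 400, end = 600, name = "c")
  private <- make_peak(start = 5000, end = 5200, name = "d")
  sets <- list(s1 = rbind(p1, private), s2 = p2, s3 = p3)
  cons <- consensus_peaks(sets, min_samples = 2)
  # chained overlaps a-b, b-c merge into one consensus spanning a..c
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 100L)
  expect_equal(cons$end, 600L)
  expect_equal(cons$n_samples, 3L)
  # private peak dropped at min_samples = 2
  expect_false(grepl("5000", cons$member_ids[1]))
  # shared-by-two retained
  cons1 <- consensus_peaks(list(s1 = p1, s2 = p2, s3 = private), min_samples = 2)
  expect_equal(cons1$samples, "s1,s2")
  expect_error(consensus_peaks(sets, min_samples = 9), "exceeds")
  expect_error(consensus_peaks(sets[1]), ">= 2 samples")
})

test_that("consensus output is invariant to sample input order", {
  ct <- tiny_celltype()
  sets <- list(s1 = ct$peaks[1:30, ], s2 = ct$peaks[10:40, ], s3 = ct$peaks[20:50, ])
  a <- consensus_peaks(sets, min_samples = 2)
  b <- consensus_peaks(rev(sets), min_samples = 2)
  expect_equal(a, b)
})

test_that("locus splits are disjoint and reproducible", {
  cons <- data.frame(consensus_id = sprintf("c%03d", 1:40))
  sp <- split_consensus_loci(cons, seed = 4)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_equal(sort(c(sp$train, sp$test)), sort(cons$consensus_id))
  expect_identical(sp, split_consensus_loci(cons, seed = 4))
})

test_that("point-biserial equals the Pearson correlation with the group indicator", {
  res <- point_biserial(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(res$r, 0.98995, tolerance = 1e-5)
  expect_equal(res$r, cor(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), tolerance = 1e-12)
  # randomized equivalence with an independent Pearson implementation
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    probs <- runif(n)
    dos <- sample(0:2, n, replace = TRUE)
    if (length(unique(dos >= 1)) < 2) next
    expect_equal(point_biserial(probs, dos)$r,
                 cor(as.numeric(dos >= 1), probs), tolerance = 1e-12)
  }
  # dosage 1 and 2 fall in the same (opening-allele carrier) group
  expect_equal(point_biserial(c(0.9, 0.8, 0.2), c(2, 1, 0))$r,
               cor(c(1, 1, 0), c(0.9, 0.8, 0.2)), tolerance = 1e-12)
})

test_that("point-biserial handles degenerate inputs as documented", {
  # constant probabilities: r = 0 by convention, flagged
  res <- point_biserial(c(0.5, 0.5, 0.5, 0.5), c(0, 0, 1, 2))
  expect_equal(res$r, 0)
  expect_true(res$zero_variance)
  # non-stratifying genotypes: excluded with reason
  res2 <- point_biserial(c(0.9, 0.2, 0.4), c(1, 2, 1))
  expect_false(res2$stratifies)
  expect_true(is.na(res2$r))
  # missing values dropped first
  res3 <- point_biserial(c(0.9, NA, 0.2, 0.1), c(1, 1, 0, NA))
  expect_equal(res3$n, 2L)
})

test_that("rank-sum comparison has the documented one-sided direction", {
  # caQTL correlations lower than controls: one-sided p near 1
  p_hi <- wilcox.test(c(1, 2, 3), c(4, 5, 6), alternative = "greater")$p.value
  expect_equal(p_hi, 1)
  # reversed: exactly 1 / choose(6,3)
  p_lo <- wilcox.test(c(4, 5, 6), c(1, 2, 3), alternative = "greater")$p.value
  expect_equal(p_lo, 1 / choose(6, 3), tolerance = 1e-12)
})

test_that("leave-one-individual-out keeps individuals and loci independent", {
  ref <- cohort_reference()
  cohort <- generate_cohort(ref, n_individuals = 6,
                            n_regions = c(enhancer = 40, other = 40),
                            n_caqtl = 6, n_control = 6, seed = 31)
  mats <- cohort_feature_matrices(cohort, ref)
  cds <- cohort_datasets(mats, cohort$regions)
  cons <- data.frame(consensus_id = cohort$regions$region_id)
  sp <- split_consensus_loci(cons, seed = 2)
  res <- suppressWarnings(
    loio_evaluate(cds, sp, mlp_hyperparams(hidden = 8, max_epochs = 150), seed = 3))
  expect_gt(nrow(res), 0L)
  expect_true(all(res$roc_auc > 0.5))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_error(loio_evaluate(cds[1:2], sp), ">= 3 individuals")
})

test_that("caQTL analysis rejects models trained on tested loci", {
  preds <- data.frame(ocr_id = "locus_0001", individual = "ind01", prob = 0.9)
  genotypes <- list(variants = data.frame(id = "rs1", chrom = "chr1", pos = 5L,
                                          opening_allele = "A"),
                    dosages = matrix(1L, 1, 1, dimnames = list("rs1", "ind01")))
  vmap <- data.frame(ocr_id = "locus_0001", variant_id = "rs1")
  fake_model <- structure(list(training_loci = "locus_0001"), class = "model_bundle")
  expect_error(
    caqtl_analysis(preds, genotypes, vmap, caqtl_ids = "locus_0001",
                   control_ids = character(), model = fake_model),
    "training leakage")
})

test_that("variant-OCR mapping uses the 100 bp proximity rule", {
  ocrs <- data.frame(ocr_id = c("o1", "o2"), chrom = "chr1",
                     start = c(1000L, 5000L), end = c(1500L, 5400L))
  variants <- data.frame(id = c("v_in", "v_near", "v_far"), chrom = "chr1",
                         pos = c(1200L, 1590L, 2000L))
  vm <- map_variants_to_ocrs(ocrs, variants)
  expect_equal(vm$variant_id[vm$ocr_id == "o1"], "v_in")
  # v_near is within 100 bp of o1's end but v_in is closer to the midpoint
  vm2 <- map_variants_to_ocrs(ocrs, variants[2:3, ])
  expect_equal(vm2$variant_id, "v_near")
  expect_false("o2" %in% vm2$ocr_id)
})

test_that("refinement recovers a planted fraction of mislabeled enhancers", {
  ref <- cohort_reference()
  train_ct <- generate_celltype(ref, n_per_class = c(enhancer = 25, other = 25),
                                seed = 61, cell_type = "train")
  disease_ct <- generate_celltype(ref, n_per_class = c(enhancer = 25, other = 25),
                                  seed = 62, exclude_slots = train_ct$used_slots,
                                  cell_type = "disease")
  # mislabel 10 true-enhancer regions as quiescent in the segmentation truth:
  # their fragments keep the enhancer profile but their annotation says other
  mislabel <- which(disease_ct$truth$class == "enhancer")[1:10]
  chromhmm_class <- disease_ct$truth$class
  chromhmm_class[mislabel] <- "other"
  build_ds <- function(ct, labels) {
    fm <- build_feature_matrix(ct$peaks, ct$fragments, ref$genome,
                               ref$conservation, ref$pwms_known, ref$pwms_denovo,
                               ref$annotation)
    labeled_dataset(fm, labels, "x")
  }
  model <- suppressWarnings(
    train_mlp(downsample_balance(build_ds(train_ct, train_ct$truth$class), 3),
              seed = 63))
  ds_dis <- build_ds(disease_ct, disease_ct$truth$class)
  prob <- predict(model, ds_dis$features)$prob[, "enhancer"]
  rows <- data.frame(ocr_id = rownames(ds_dis$features), individual = "ind01",
                     chromhmm_class = chromhmm_class, prob = prob)
  res <- annotation_refinement(rows)
  # 10 of 35 non-enhancer rows are truly enhancers: recovered fraction ~ 0.29
  expect_equal(res$n_non_enhancer, 35L)
  q <- 10 / 35
  expect_lt(abs(res$n_rescued / res$n_non_enhancer - q), 0.1)
})

test_that("annotation refinement counts rescued OCR-individual pairs", {
  rows <- data.frame(ocr_id = sprintf("o%d", 1:10), individual = "ind01",
                     chromhmm_class = rep(c("other", "enhancer"), c(10, 0)),
                     prob = c(0.9, 0.8, 0.7, 0.6, rep(0.2, 6)))
  res <- annotation_refinement(rows)
  expect_equal(res$n_non_enhancer, 10L)
  expect_equal(res$n_rescued, 4L)
  expect_equal(res$n_still_unannotated, 6L)
  # all rows already enhancers: nothing to refine
  rows$chromhmm_class <- "enhancer"
  res0 <- annotation_refinement(rows)
  expect_equal(res0$n_non_enhancer, 0L)
  expect_equal(res0$n_rescued, 0L)
})
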