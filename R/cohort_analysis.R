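# Individual-level cohort analysis: consensus peaks across samples,
# leakage-free leave-one-individual-out evaluation, genotype/probability
# point-biserial correlations at caQTL OCRs, and annotation refinement of
# disease-associated OCRs.

#' Consensus peaks across cohort samples
#'
#' Overlapping peaks from different samples are merged by single linkage
#' (chained overlaps collapse into one consensus interval spanning the whole
#' chain). A consensus is retained when the number of distinct contributing
#' samples reaches `min_samples`.
#'
#' @param peak_sets named list of peak data frames, one per sample.
#' @param min_samples minimum number of distinct samples (default more than
#'   half the cohort).
#' @return data frame: `consensus_id`, `chrom`, `start`, `end`, `n_samples`,
#'   `samples` (comma-separated), `member_ids` (comma-separated
#'   sample:peak ids).
#' @export
consensus_peaks <- function(peak_sets, min_samples = floor(length(peak_sets) / 2) + 1L) {
  if (length(peak_sets) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (min_samples > length(peak_sets)) {
    stop("min_samples exceeds the number of samples", call. = FALSE)
  }
  if (is.null(names(peak_sets))) names(peak_sets) <- paste0("s", seq_along(peak_sets))
  all <- do.call(rbind, lapply(names(peak_sets), function(s) {
    p <- peak_sets[[s]]
    data.frame(sample = s, peak = p$name, chrom = p$chrom, start = p$start,
               end = p$end, stringsAsFactors = FALSE)
  }))
  # sample order must not matter: sort before merging
  all <- all[order(all$chrom, all$start, all$end, all$sample, all$peak), , drop = FALSE]
  out <- list()
  for (chr in sort(unique(all$chrom))) {
    a <- all[all$chrom == chr, , drop = FALSE]
    # single-linkage merge along sorted starts
    grp <- cumsum(c(1L, as.integer(a$start[-1] >= cummax(a$end[-nrow(a)]))))
    for (g in unique(grp)) {
      m <- a[grp == g, , drop = FALSE]
      samples <- sort(unique(m$sample))
      if (length(samples) < min_samples) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(m$start), end = max(m$end),
        n_samples = length(samples), samples = paste(samples, collapse = ","),
        member_ids = paste(paste(m$sample, m$peak, sep = ":"), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(consensus_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_samples = integer(),
                      samples = character(), member_ids = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  cbind(data.frame(consensus_id = sprintf("cons_%05d", seq_len(nrow(res))),
                   stringsAsFactors = FALSE), res)
}

#' Split consensus loci into disjoint training and testing halves
#'
#' @param consensus consensus-peak data frame.
#' @param seed integer seed.
#' @param train_fraction fraction of loci assigned to training (default 0.5).
#' @return list with `train` and `test` consensus_id vectors (disjoint).
#' @export
split_consensus_loci <- function(consensus, seed = 1L, train_fraction = 0.5) {
  set.seed(seed)
  ids <- consensus$consensus_id
  n_train <- floor(train_fraction * length(ids))
  train <- sort(sample(ids, n_train))
  list(train = train, test = sort(setdiff(ids, train)))
}

#' Leave-one-individual-out evaluation on a cohort
#'
#' Consensus loci are split 50/50 into disjoint training and testing locus
#' sets. For each individual i, a model is trained on the training-locus rows
#' of all other individuals (balanced by down-sampling) and evaluated on the
#' testing-locus rows of individual i, so train and test are independent both
#' in individuals and in genomic loci.
#'
#' @param cohort named list of `labeled_dataset`s, one per individual, whose
#'   feature rownames are `<consensus_id>` locus identifiers.
#' @param locus_split list with `train`/`test` locus id vectors
#'   ([split_consensus_loci()]).
#' @param hyperparams [mlp_hyperparams()].
#' @param seed integer seed.
#' @return data frame: `individual`, `roc_auc`, `prc_auc`, `accuracy`,
#'   `n_test`; attribute `"locus_split"` carries the split for leakage audits.
#' @export
loio_evaluate <- function(cohort, locus_split, hyperparams = mlp_hyperparams(),
                          seed = 1L) {
  if (length(cohort) < 3L) stop("need >= 3 individuals", call. = FALSE)
  stopifnot(!length(intersect(locus_split$train, locus_split$test)))
  rows <- list()
  for (i in seq_along(cohort)) {
    ind <- names(cohort)[i]
    test_ds <- cohort[[i]]
    te <- which(rownames(test_ds$features) %in% locus_split$test)
    if (!length(te) || length(unique(test_ds$labels[te])) < 2L) {
      warning(sprintf("individual %s skipped: no two-class test rows", ind), call. = FALSE)
      next
    }
    train_list <- lapply(cohort[-i], function(d) {
      subset_dataset(d, which(rownames(d$features) %in% locus_split$train))
    })
    model <- train_combined(train_list, hyperparams, child_seed(seed, i))
    stopifnot(!length(intersect(rownames(test_ds$features)[te], model$training_loci)))
    pr <- stats::predict(model, test_ds$features[te, , drop = FALSE])
    ev <- evaluate(enhancer_prob(pr$prob), as.character(test_ds$labels[te]))
    rows[[length(rows) + 1L]] <- data.frame(
      individual = ind, roc_auc = ev$roc_auc, prc_auc = ev$prc_auc,
      accuracy = ev$accuracy_at_0.5, n_test = length(te), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "locus_split") <- locus_split
  out
}

#' Point-biserial correlation between genotype group and probabilities
#'
#' Genotypes are binarized: group 0 = homozygous for the chromatin-closing
#' allele (dosage 0), group 1 = carrying at least one opening allele (dosage
#' >= 1). The correlation is the Pearson correlation between that indicator
#' and the probabilities. Samples missing either value are dropped first.
#'
#' @param probs per-sample enhancer probabilities (NA = no peak called).
#' @param dosages per-sample opening-allele dosages in {0,1,2,NA}.
#' @return list: `r` (0 by convention when the probabilities have zero
#'   variance, flagged by `zero_variance`), `n`, `n_group0`, `n_group1`,
#'   `stratifies` (FALSE when either genotype group is empty; `r` is NA then).
#' @export
point_biserial <- function(probs, dosages) {
  keep <- !is.na(probs) & !is.na(dosages)
  probs <- probs[keep]
  group <- as.numeric(dosages[keep] >= 1)
  n0 <- sum(group == 0); n1 <- sum(group == 1)
  if (n0 == 0 || n1 == 0) {
    return(list(r = NA_real_, n = length(probs), n_group0 = n0, n_group1 = n1,
                stratifies = FALSE, zero_variance = FALSE))
  }
  if (stats::var(probs) == 0) {
    return(list(r = 0, n = length(probs), n_group0 = n0, n_group1 = n1,
                stratifies = TRUE, zero_variance = TRUE))
  }
  # explicit point-biserial form: (m1 - m0)/s * sqrt(n0*n1/n^2)
  n <- length(probs)
  m1 <- mean(probs[group == 1]); m0 <- mean(probs[group == 0])
  s <- sqrt(sum((probs - mean(probs))^2) / n)
  r <- (m1 - m0) / s * sqrt(n0 * n1 / n^2)
  list(r = r, n = n, n_group0 = n0, n_group1 = n1,
       stratifies = TRUE, zero_variance = FALSE)
}

#' Genotype correlation analysis at caQTL and control OCRs
#'
#' For each testable OCR (variant inside or within `max_dist` bp of the OCR),
#' computes the point-biserial correlation between per-individual enhancer
#' probabilities and binarized genotypes, then compares the caQTL and control
#' correlation distributions with a one-sided Mann-Whitney (rank-sum) test
#' (alternative: caQTL correlations greater). Also reports the fraction of
#' caQTL OCRs predicted enhancer (probability > 0.5) in at least one
#' individual. OCRs used here must be absent from the model's training-locus
#' manifest; this is asserted, not assumed.
#'
#' @param predictions data frame with columns `ocr_id`, `individual`, `prob`
#'   (NA when the individual has no peak at the locus).
#' @param genotypes genotype list ([read_genotypes()]).
#' @param variant_map data frame `ocr_id`, `variant_id` linking OCRs to their
#'   variant.
#' @param caqtl_ids,control_ids OCR id vectors for the two sets.
#' @param model optional `model_bundle`; when given, its `training_loci` must
#'   not intersect the tested OCR ids (hard error otherwise).
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return list: `records` (per-OCR data frame with set, r, n, group sizes),
#'   `p_value`, `caqtl_median_r`, `control_median_r`,
#'   `caqtl_enhancer_fraction`.
#' @export
caqtl_analysis <- function(predictions, genotypes, variant_map, caqtl_ids,
                           control_ids, model = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  tested <- c(caqtl_ids, control_ids)
  if (!is.null(model)) {
    leaked <- intersect(tested, model$training_loci)
    if (length(leaked)) {
      stop(sprintf("training leakage: %d tested OCRs were in the training set (e.g. %s)",
                   length(leaked), leaked[1]), call. = FALSE)
    }
  }
  samples <- colnames(genotypes$dosages)
  recs <- lapply(tested, function(ocr) {
    vid <- variant_map$variant_id[match(ocr, variant_map$ocr_id)]
    if (is.na(vid) || !vid %in% rownames(genotypes$dosages)) return(NULL)
    pr <- predictions[predictions$ocr_id == ocr, , drop = FALSE]
    probs <- pr$prob[match(samples, pr$individual)]
    pb <- point_biserial(probs, genotypes$dosages[vid, ])
    data.frame(ocr_id = ocr, variant_id = vid,
               set = if (ocr %in% caqtl_ids) "caqtl" else "control",
               r = pb$r, n = pb$n, n_group0 = pb$n_group0, n_group1 = pb$n_group1,
               stratifies = pb$stratifies, zero_variance = pb$zero_variance,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  usable <- records[records$stratifies & !is.na(records$r), , drop = FALSE]
  r_ca <- usable$r[usable$set == "caqtl"]
  r_co <- usable$r[usable$set == "control"]
  p <- if (length(r_ca) && length(r_co)) {
    stats::wilcox.test(r_ca, r_co, alternative = alternative)$p.value
  } else NA_real_
  enh_frac <- {
    pr_ca <- predictions[predictions$ocr_id %in% caqtl_ids, , drop = FALSE]
    called <- tapply(pr_ca$prob, pr_ca$ocr_id, function(p) any(p > 0.5, na.rm = TRUE))
    mean(called[!is.na(called)])
  }
  list(records = records, p_value = p,
       caqtl_median_r = stats::median(r_ca), control_median_r = stats::median(r_co),
       caqtl_enhancer_fraction = enh_frac,
       n_caqtl_tested = length(r_ca), n_control_tested = length(r_co))
}

#' Link variants to OCRs by proximity
#'
#' A variant is associated with an OCR when it falls inside the OCR or within
#' `max_dist` bp of its boundaries.
#'
#' @param ocrs data frame `ocr_id`, `chrom`, `start`, `end`.
#' @param variants variant data frame (`id`, `chrom`, `pos`).
#' @param max_dist maximum distance in bp (default 100).
#' @return data frame `ocr_id`, `variant_id` (closest variant per OCR).
#' @export
map_variants_to_ocrs <- function(ocrs, variants, max_dist = 100L) {
  rows <- lapply(seq_len(nrow(ocrs)), function(i) {
    sel <- variants$chrom == ocrs$chrom[i] &
      variants$pos >= ocrs$start[i] - max_dist &
      variants$pos < ocrs$end[i] + max_dist
    if (!any(sel)) return(NULL)
    cand <- variants[sel, , drop = FALSE]
    mid <- (ocrs$start[i] + ocrs$end[i]) / 2
    data.frame(ocr_id = ocrs$ocr_id[i], variant_id = cand$id[which.min(abs(cand$pos - mid))],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(ocr_id = character(), variant_id = character())
}

#' Refine disease-associated OCR annotations with per-individual predictions
#'
#' Rows are OCR x individual pairs carrying a segmentation-derived class.
#' Counts how many rows are non-enhancer by the segmentation, how many of
#' those are rescued as predicted enhancers (probability > 0.5), and how many
#' remain unannotated.
#'
#' @param rows data frame with `ocr_id`, `individual`, `chromhmm_class`
#'   (class label) and `prob` (prediction, NA when absent).
#' @return list: `n_rows`, `n_non_enhancer`, `n_rescued`,
#'   `n_still_unannotated`.
#' @export
annotation_refinement <- function(rows) {
  non_enh <- rows$chromhmm_class != "enhancer"
  rescued <- non_enh & !is.na(rows$prob) & rows$prob > 0.5
  list(n_rows = nrow(rows),
       n_non_enhancer = sum(non_enh),
       n_rescued = sum(rescued),
       n_still_unannotated = sum(non_enh) - sum(rescued))
}
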