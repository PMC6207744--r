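# Convenience plumbing that chains the modules: peaks -> features -> labeled
# dataset, and the per-individual cohort variants of the same. Sequence,
# conservation, motif and location features depend only on the locus, so for
# cohorts they are computed once per region and reused for every individual.

#' Static (locus-level) features for a set of regions
#'
#' Computes the conservation/GC/CpG/motif/location feature columns once per
#' region, using the region midpoint as a provisional summit. Intended for
#' cohort analyses where the same loci are re-extracted per individual.
#'
#' @param regions data frame with `region_id` (or `ocr_id`/`name`), `chrom`,
#'   `start`, `end`.
#' @param reference a [generate_reference()]-style list (genome, conservation,
#'   PWM libraries, annotation).
#' @return data frame keyed by `peak_id` with the 9 static feature columns.
#' @export
static_features <- function(regions, reference) {
  id_col <- intersect(c("region_id", "ocr_id", "name"), names(regions))[1]
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    peak <- data.frame(chrom = regions$chrom[i], start = regions$start[i],
                       end = regions$end[i], name = regions[[id_col]][i],
                       summit_offset = (regions$end[i] - regions$start[i]) %/% 2L,
                       stringsAsFactors = FALSE)
    seq <- get_sequence(reference$genome, peak$chrom, peak$start, peak$end)
    c(extract_sequence_features(peak, reference$genome, reference$conservation),
      extract_motif_features(seq, reference$pwms_known, reference$pwms_denovo),
      extract_location_features(peak, reference$annotation))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(peak_id = regions[[id_col]], stringsAsFactors = FALSE), out)
}

#' Build a labeled dataset for one cell type from generated or real inputs
#'
#' @param peaks peak data frame.
#' @param fragments fragment data frame.
#' @param reference reference list (genome, conservation, PWMs, annotation).
#' @param seg segmentation used for labeling.
#' @param mapping state-to-class mapping.
#' @param source source tag.
#' @param keep_classes classes retained (default enhancer + other: the binary
#'   enhancer-vs-other task with segmentation-labeled promoters excluded).
#' @return a `labeled_dataset`.
#' @export
build_labeled_dataset <- function(peaks, fragments, reference, seg,
                                  mapping = default_state_mapping(),
                                  source = "celltype",
                                  keep_classes = c("enhancer", "other")) {
  fm <- build_feature_matrix(peaks, fragments, reference$genome,
                             reference$conservation, reference$pwms_known,
                             reference$pwms_denovo, reference$annotation)
  labels <- label_peaks(peaks, seg, mapping)
  labels[!labels %in% keep_classes] <- "excluded"
  labeled_dataset(fm, labels, source)
}

#' Per-individual feature matrices for a synthetic cohort
#'
#' @param cohort a [generate_cohort()] object.
#' @param reference the reference it was generated from.
#' @param static optional precomputed [static_features()] for
#'   `cohort$regions` (computed here when NULL).
#' @return named list of feature data frames (peak_id = region/locus id).
#' @export
cohort_feature_matrices <- function(cohort, reference, static = NULL) {
  if (is.null(static)) static <- static_features(cohort$regions, reference)
  lapply(cohort$individuals, function(ind) {
    build_feature_matrix(ind$peaks, ind$fragments, reference$genome,
                         reference$conservation, reference$pwms_known,
                         reference$pwms_denovo, reference$annotation,
                         static = static)
  })
}

#' Labeled datasets per individual from cohort feature matrices
#'
#' @param matrices output of [cohort_feature_matrices()].
#' @param regions cohort region table (`region_id`, `class`).
#' @param keep_classes classes retained (default enhancer/other).
#' @return named list of `labeled_dataset`s keyed by individual; feature
#'   rownames are locus ids, so locus-level train/test splits apply directly.
#' @export
cohort_datasets <- function(matrices, regions, keep_classes = c("enhancer", "other")) {
  lapply(stats::setNames(names(matrices), names(matrices)), function(ind) {
    fm <- matrices[[ind]]
    cls <- regions$class[match(fm$peak_id, regions$region_id)]
    cls[!cls %in% keep_classes] <- "excluded"
    labeled_dataset(fm, cls, source = ind)
  })
}

#' Per-individual enhancer probabilities at selected loci
#'
#' Individuals without a called peak at a locus get NA (no prediction).
#'
#' @param model a `model_bundle`.
#' @param matrices per-individual feature matrices.
#' @param ocr_ids loci to predict at.
#' @return data frame `ocr_id`, `individual`, `prob`.
#' @export
cohort_predictions <- function(model, matrices, ocr_ids) {
  rows <- lapply(names(matrices), function(ind) {
    fm <- matrices[[ind]]
    present <- fm$peak_id[fm$peak_id %in% ocr_ids]
    prob <- rep(NA_real_, length(ocr_ids))
    if (length(present)) {
      sub <- fm[match(present, fm$peak_id), , drop = FALSE]
      pr <- stats::predict(model, sub)
      prob[match(present, ocr_ids)] <- enhancer_prob(pr$prob)
    }
    data.frame(ocr_id = ocr_ids, individual = ind, prob = prob,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
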