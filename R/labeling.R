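# ChromHMM-style labeling: map each OCR to the segmentation state covering
# the most of its bases, group states into {enhancer, promoter, other,
# excluded}, harmonize state vocabularies across cell types by clustering
# emission profiles, and compare against alternative enhancer definitions.

#' Class labels used throughout the package
#' @return character vector of the four class labels.
#' @export
class_labels <- function() c("enhancer", "promoter", "other", "excluded")

#' Assign a segmentation state to each peak (max-bp overlap rule)
#'
#' A peak overlapping one state gets that state; a peak overlapping several
#' gets the state covering the most base pairs of the peak. Equal-bp ties are
#' broken by a fixed priority list (enhancer-like states first, then
#' promoter-like, then the rest alphabetically), which keeps assignment
#' deterministic. Peaks with no overlapping segment get the sentinel
#' `"unsegmented"`.
#'
#' @param peaks peak data frame.
#' @param seg segmentation data frame ([read_segmentation()]).
#' @param priority character vector of state labels, highest priority first,
#'   used only to break exact bp ties.
#' @return character vector of state labels, one per peak.
#' @export
assign_state <- function(peaks, seg, priority = default_state_priority()) {
  n <- nrow(peaks)
  out <- rep("unsegmented", n)
  if (!n || !nrow(seg)) return(out)
  hits <- overlap_pairs(peaks$chrom, peaks$start, peaks$end,
                        seg$chrom, seg$start, seg$end)
  if (!nrow(hits)) return(out)
  ov_bp <- pmin(peaks$end[hits[, 1]], seg$end[hits[, 2]]) -
    pmax(peaks$start[hits[, 1]], seg$start[hits[, 2]])
  states <- seg$state[hits[, 2]]
  # aggregate bp per (peak, state): same state may occur in several segments
  key <- paste(hits[, 1], states, sep = "\r")
  bp <- tapply(ov_bp, key, sum)
  kp <- as.integer(sub("\r.*", "", names(bp)))
  ks <- sub(".*\r", "", names(bp))
  krank <- match(ks, priority)
  krank[is.na(krank)] <- length(priority) + rank_alpha(ks)[is.na(krank)]
  ord <- order(kp, -as.numeric(bp), krank)  # per peak: most bp, then priority
  first <- !duplicated(kp[ord])
  out[kp[ord][first]] <- ks[ord][first]
  out
}

rank_alpha <- function(x) as.integer(factor(x, levels = sort(unique(x))))

#' Default tie-break priority for state assignment
#' @return character vector (enhancer-like > promoter-like > others).
#' @export
default_state_priority <- function() {
  c("EnhA", "Enh", "EnhWk", "EnhG", "TssA", "Tss", "TssFlnk", "Tx", "TxWk",
    "Ins", "ReprPC", "Quies")
}

#' Default state-to-class mapping for a common 15-state-style vocabulary
#'
#' Genic enhancers (`EnhG`) and ambiguous states are mapped to `"excluded"`
#' because their histone-mark definitions overlap transcribed (non-enhancer)
#' regions; the sentinel `"unsegmented"` is always excluded.
#'
#' @return named character vector: state label -> class label.
#' @export
default_state_mapping <- function() {
  c(EnhA = "enhancer", Enh = "enhancer", EnhWk = "enhancer",
    TssA = "promoter", Tss = "promoter", TssFlnk = "promoter",
    Tx = "other", TxWk = "other", Ins = "other", ReprPC = "other",
    Quies = "other",
    EnhG = "excluded", Ambig = "excluded", unsegmented = "excluded")
}

#' Group states into class labels
#'
#' @param states character vector of state labels.
#' @param mapping named character vector state -> class (must be total over
#'   the states present; `"unsegmented"` always maps to excluded).
#' @return character vector of class labels.
#' @export
group_states <- function(states, mapping = default_state_mapping()) {
  if (!"unsegmented" %in% names(mapping)) mapping <- c(mapping, unsegmented = "excluded")
  missing <- setdiff(unique(states), names(mapping))
  if (length(missing)) {
    stop(sprintf("states not in mapping: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(unique(mapping), class_labels())
  if (length(bad)) {
    stop(sprintf("mapping targets outside %s: %s", paste(class_labels(), collapse = "/"),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  unname(mapping[states])
}

#' Label peaks from a segmentation in one step
#'
#' @inheritParams assign_state
#' @param mapping state -> class mapping.
#' @return character vector of class labels, one per peak.
#' @export
label_peaks <- function(peaks, seg, mapping = default_state_mapping(),
                        priority = default_state_priority()) {
  group_states(assign_state(peaks, seg, priority), mapping)
}

#' Harmonize state vocabularies across cell types by emission clustering
#'
#' Pools the per-state emission rows of several cell types (restricted to
#' their common mark set), computes 1 - Pearson correlation distances between
#' states and clusters them with average-linkage hierarchical clustering.
#' When a CTCF mark is present, the state with maximal CTCF emission in each
#' cell type is additionally flagged as the insulator state.
#'
#' @param emissions list of emission matrices (states x marks, entries in
#'   [0,1], unique rownames per matrix), one per cell type.
#' @param k number of clusters to cut (default 10).
#' @param ctcf_mark name of the CTCF mark column, if any (default "CTCF").
#' @return data frame with `cell_type`, `state`, `cluster`, `is_insulator`.
#' @export
harmonize_states <- function(emissions, k = 10L, ctcf_mark = "CTCF") {
  stopifnot(length(emissions) >= 1L)
  marks <- Reduce(intersect, lapply(emissions, colnames))
  if (!length(marks)) stop("empty mark intersection across emission matrices", call. = FALSE)
  rows <- do.call(rbind, lapply(seq_along(emissions), function(i) {
    m <- emissions[[i]][, marks, drop = FALSE]
    if (any(m < 0 | m > 1)) stop("emission entries must be in [0,1]", call. = FALSE)
    data.frame(cell_type = names(emissions)[i] %||% as.character(i),
               state = rownames(emissions[[i]]), i = i, m, check.names = FALSE)
  }))
  if (nrow(rows) < 2L) stop("need at least 2 states to cluster", call. = FALSE)
  emat <- as.matrix(rows[, marks, drop = FALSE])
  cors <- suppressWarnings(stats::cor(t(emat)))
  cors[is.na(cors)] <- 0  # zero-variance emission rows: no correlation signal
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = "average")
  k <- min(k, nrow(rows))
  cl <- stats::cutree(hc, k = k)
  # renumber clusters by first appearance so output is input-order invariant
  # up to the documented renumbering
  insulator <- rep(FALSE, nrow(rows))
  if (ctcf_mark %in% marks) {
    for (i in unique(rows$i)) {
      sel <- which(rows$i == i)
      insulator[sel[which.max(emat[sel, ctcf_mark])]] <- TRUE
    }
  }
  data.frame(cell_type = rows$cell_type, state = rows$state,
             cluster = unname(cl), is_insulator = insulator,
             stringsAsFactors = FALSE)
}

#' Label peaks against an alternative enhancer definition
#'
#' Enhancer calls come from an external interval set (e.g. bidirectional-CAGE
#' enhancers or EP300 binding sites): a peak overlapping any interval by
#' >= 1 bp is an enhancer. Promoter and excluded calls keep their
#' segmentation-derived class (promoter takes precedence over an overlapping
#' alternative-enhancer call); the negative "other" class is likewise taken
#' from the segmentation mapping.
#'
#' @param peaks peak data frame.
#' @param enhancer_bed data frame of enhancer intervals (`chrom`,`start`,`end`).
#' @param seg segmentation data frame.
#' @param mapping state -> class mapping.
#' @return character vector of class labels per peak.
#' @export
label_alternative <- function(peaks, enhancer_bed, seg,
                              mapping = default_state_mapping()) {
  base <- label_peaks(peaks, seg, mapping)
  hits <- overlap_pairs(peaks$chrom, peaks$start, peaks$end,
                        enhancer_bed$chrom, enhancer_bed$start, enhancer_bed$end)
  is_enh <- seq_len(nrow(peaks)) %in% hits[, 1]
  out <- ifelse(base %in% c("promoter", "excluded"), base,
                ifelse(is_enh, "enhancer", "other"))
  out
}

#' Overlap enrichment between two interval sets over a universe
#'
#' Counts universe elements overlapping both sets, each alone, and neither,
#' and computes the one-sided (enrichment) Fisher exact p-value of the 2x2
#' table.
#'
#' @param set_a,set_b data frames of intervals (`chrom`,`start`,`end`).
#' @param universe data frame of intervals; counting is per universe element.
#' @return list with `table` (2x2 matrix) and `p_value`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  if (!nrow(universe)) stop("empty universe", call. = FALSE)
  in_a <- seq_len(nrow(universe)) %in%
    overlap_pairs(universe$chrom, universe$start, universe$end,
                  set_a$chrom, set_a$start, set_a$end)[, 1]
  in_b <- seq_len(nrow(universe)) %in%
    overlap_pairs(universe$chrom, universe$start, universe$end,
                  set_b$chrom, set_b$start, set_b$end)[, 1]
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(a = c("in_a", "not_a"), b = c("in_b", "not_b")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(table = tab, p_value = p)
}

#' Exclude promoter-proximal peaks by TSS distance
#'
#' One of the two promoter-handling options: peaks whose summit lies within
#' `threshold` bp of any TSS are marked excluded before enhancer-vs-other
#' modeling. The alternative (default in this package, as in the analyses
#' shipped here) is excluding peaks labeled promoter by the segmentation.
#'
#' @param labels current class labels.
#' @param tss_distance signed TSS distances (feature column).
#' @param threshold absolute distance cutoff in bp (default 1000).
#' @return updated class labels.
#' @export
exclude_promoter_proximal <- function(labels, tss_distance, threshold = 1000) {
  ifelse(abs(tss_distance) <= threshold & labels != "excluded", "excluded", labels)
}
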