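# Extraction of the 24 per-OCR features: 5 peak-driven, 10 insert/cut-driven,
# 3 sequence-driven, 3 motif-driven and 3 genomic-location-driven values.

#' Canonical feature names, in fixed column order
#'
#' @return character vector of the 24 feature names.
#' @export
feature_names <- function() {
  c("peak_score", "peak_length", "fold_change", "summit_pileup",
    "summit_center_distance",
    "n_inserts_all", "n_inserts_0_50", "n_inserts_50_150", "n_inserts_150_300",
    "n_inserts_300_500", "n_inserts_500_plus", "insert_size_mean",
    "long_short_ratio", "n_cuts", "n_overrepresented_cuts",
    "conservation_mean", "gc_pct", "cpg_pct",
    "n_ctcf_motifs", "known_motif_pct", "denovo_motif_pct",
    "annotation_code", "tss_distance", "gene_type_code")
}

#' Feature groups (for ablation models)
#'
#' @return named list mapping group name to member feature names.
#' @export
feature_groups <- function() {
  fn <- feature_names()
  list(peak = fn[1:5], insert_cut = fn[6:15], sequence = fn[16:18],
       motif = fn[19:21], location = fn[22:24])
}

#' Integer vocabularies for the categorical location features
#'
#' Genomic-context labels and gene-type labels are stored in the feature
#' matrix as fixed integer codes; unknown labels map to the "other" code (0).
#' @return list with `annotation` and `gene_type` named integer vectors.
#' @export
location_vocabularies <- function() {
  list(
    annotation = c(other = 0L, intergenic = 1L, `promoter-TSS` = 2L, exon = 3L,
                   intron = 4L, TTS = 5L, UTR = 6L),
    gene_type = c(other = 0L, protein_coding = 1L, lincRNA = 2L, pseudogene = 3L,
                  miRNA = 4L, snoRNA = 5L)
  )
}

#' Peak-driven features (n = 5)
#'
#' `peak_score`, `peak_length` and `fold_change` are carried over from the
#' peak caller; `summit_pileup` is the number of fragments whose interval
#' covers the summit base; `summit_center_distance` is the absolute distance
#' between the summit and the peak midpoint.
#'
#' @param peak single-row peak data frame (see [read_narrowpeak()]).
#' @param fragments data frame of fragments overlapping the peak.
#' @return named numeric vector of 5 values.
#' @export
extract_peak_features <- function(peak, fragments) {
  summit <- peak$start + peak$summit_offset
  pileup <- if (nrow(fragments)) {
    sum(fragments$start <= summit & fragments$end > summit)
  } else 0L
  c(peak_score = as.numeric(peak$peak_score),
    peak_length = as.numeric(peak$end - peak$start),
    fold_change = as.numeric(peak$fold_change),
    summit_pileup = as.numeric(pileup),
    summit_center_distance = abs(summit - floor((peak$start + peak$end) / 2)))
}

#' Insert/cut-driven features (n = 9; over-represented cuts are separate)
#'
#' Insert sizes are binned into (0,50], (50,150], (150,300], (300,500] and
#' (500,inf) bp, following the nucleosome-occupancy interpretation of the
#' fragment-size distribution (sub-nucleosomal, nucleosome-free, mono-, di-,
#' and 3+ nucleosomes). The long/short boundary is 150 bp with 150 counting
#' as short; `long_short_ratio` uses +1 pseudocounts in numerator and
#' denominator so empty classes stay finite. `n_cuts` counts Tn5 cut sites
#' (fragment start and end-1, two per fragment) that fall inside the peak.
#'
#' @inheritParams extract_peak_features
#' @return named numeric vector of 9 values.
#' @export
extract_insert_features <- function(peak, fragments) {
  sizes <- fragments$size
  n <- length(sizes)
  bins <- c(n_inserts_0_50 = sum(sizes > 0 & sizes <= 50),
            n_inserts_50_150 = sum(sizes > 50 & sizes <= 150),
            n_inserts_150_300 = sum(sizes > 150 & sizes <= 300),
            n_inserts_300_500 = sum(sizes > 300 & sizes <= 500),
            n_inserts_500_plus = sum(sizes > 500))
  long <- sum(sizes > 150)
  short <- n - long
  cuts <- cut_sites(peak, fragments)
  c(n_inserts_all = n, bins,
    insert_size_mean = if (n) mean(sizes) else 0,
    long_short_ratio = (long + 1) / (short + 1),
    n_cuts = length(cuts))
}

#' Tn5 cut sites of fragments falling inside a peak
#'
#' Each fragment contributes two candidate cut positions: its start and its
#' last covered base (end - 1). Only positions within `[peak.start, peak.end)`
#' are returned.
#'
#' @inheritParams extract_peak_features
#' @return integer vector of 0-based cut positions (possibly with duplicates).
#' @export
cut_sites <- function(peak, fragments) {
  if (!nrow(fragments)) return(integer())
  pos <- c(fragments$start, fragments$end - 1L)
  pos[pos >= peak$start & pos < peak$end]
}

#' Count windows with over-represented Tn5 cuts
#'
#' The peak is tiled with consecutive windows of `window` bp (the last window
#' may be shorter). Under the uniform null each cut falls into window w with
#' probability len(w)/peak_length; a window is called over-represented when
#' its observed count k exceeds the expectation n*p and the one-tailed
#' binomial tail P(X >= k | n, p) is below `alpha`.
#'
#' @param peak single-row peak data frame.
#' @param cut_positions 0-based cut positions, all within the peak.
#' @param window window width in bp (default 5).
#' @param alpha one-tailed binomial significance cutoff (default 0.0005).
#' @return integer count of significant windows.
#' @export
count_overrepresented_cuts <- function(peak, cut_positions, window = 5L, alpha = 0.0005) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  n <- length(cut_positions)
  if (!n) return(0L)
  if (any(cut_positions < peak$start | cut_positions >= peak$end)) {
    stop("cut positions outside peak", call. = FALSE)
  }
  len <- peak$end - peak$start
  n_win <- ceiling(len / window)
  idx <- pmin((cut_positions - peak$start) %/% window + 1L, n_win)
  k <- tabulate(idx, nbins = n_win)
  w_len <- rep(window, n_win)
  w_len[n_win] <- len - (n_win - 1L) * window
  p <- w_len / len
  expected <- n * p
  # one-tailed upper binomial tail P(X >= k)
  tail_p <- stats::pbinom(k - 1L, size = n, prob = p, lower.tail = FALSE)
  sum(tail_p < alpha & k > expected)
}

#' Sequence-driven features (n = 3)
#'
#' `conservation_mean` averages the per-base conservation score over the peak
#' with uncovered bases contributing 0; `gc_pct` is the percentage of G/C
#' bases (case-insensitive, N counted in the denominator only); `cpg_pct` is
#' the CG-dinucleotide count over (length - 1), as a percentage.
#'
#' @param peak single-row peak data frame.
#' @param genome named `DNAStringSet` (or FASTA path).
#' @param conservation data frame `chrom`, `start`, `end`, `score` (bedGraph
#'   intervals), or `NULL` for no track (conservation_mean = 0).
#' @return named numeric vector of 3 values.
#' @export
extract_sequence_features <- function(peak, genome, conservation = NULL) {
  seq <- get_sequence(genome, peak$chrom, peak$start, peak$end)
  c(conservation_mean = conservation_mean(peak, conservation),
    gc_pct = gc_percent(seq),
    cpg_pct = cpg_percent(seq))
}

conservation_mean <- function(peak, conservation) {
  if (is.null(conservation) || !nrow(conservation)) return(0)
  sel <- conservation$chrom == peak$chrom &
    conservation$start < peak$end & conservation$end > peak$start
  if (!any(sel)) return(0)
  iv <- conservation[sel, , drop = FALSE]
  covered_bp <- pmin(iv$end, peak$end) - pmax(iv$start, peak$start)
  sum(covered_bp * iv$score) / (peak$end - peak$start)
}

gc_percent <- function(seq) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

cpg_percent <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 2L) return(0)
  hits <- gregexpr("(?=CG)", s, perl = TRUE)[[1]]
  n_cg <- if (hits[1] == -1L) 0L else length(hits)
  100 * n_cg / (n - 1L)
}

#' Count PWM hits in a sequence (both strands)
#'
#' Scores every position on the forward sequence and its reverse complement
#' with the log2-odds of the PWM against the background and counts positions
#' scoring at or above the PWM's threshold (when unset, 0.8 x the maximum
#' achievable log-odds). Scanning is delegated to
#' [Biostrings::countPWM()].
#'
#' @param sequence DNA string.
#' @param pwm PWM object (see [read_pwm_library()]).
#' @param background base frequencies (A,C,G,T), default uniform.
#' @return integer hit count; sequences shorter than the motif yield 0.
#' @export
scan_pwm <- function(sequence, pwm, background = rep(0.25, 4)) {
  L <- ncol(pwm$matrix)
  if (nchar(sequence) < L) return(0L)
  lo <- pwm_logodds(pwm, background)
  thr <- pwm$score_threshold
  if (is.null(thr) || is.na(thr)) thr <- 0.8 * sum(apply(lo, 2, max))
  fwd <- Biostrings::DNAString(sequence)
  n_f <- Biostrings::countPWM(lo, fwd, min.score = thr)
  n_r <- Biostrings::countPWM(lo, Biostrings::reverseComplement(fwd), min.score = thr)
  as.integer(n_f + n_r)
}

pwm_logodds <- function(pwm, background = rep(0.25, 4)) {
  eps <- 1e-4  # guards probability-format motifs that contain exact zeros
  p <- pwm$matrix + eps
  p <- sweep(p, 2, colSums(p), "/")
  lo <- log2(p / background)
  rownames(lo) <- c("A", "C", "G", "T")
  lo
}

#' Motif-driven features (n = 3)
#'
#' Known/de novo motif hits are binarized per PWM (present / not present) and
#' summarized as the percentage of library PWMs with at least one hit in the
#' OCR. CTCF hits are the total (not binarized) count over PWMs flagged
#' `is_ctcf`.
#'
#' @param sequence peak DNA sequence.
#' @param known list of known-motif PWMs (non-empty).
#' @param denovo list of de novo PWMs (non-empty).
#' @param background base frequencies for scoring.
#' @return named numeric vector of 3 values.
#' @export
extract_motif_features <- function(sequence, known, denovo, background = rep(0.25, 4)) {
  if (!length(known)) stop("empty known-motif library: known_motif_pct undefined", call. = FALSE)
  if (!length(denovo)) stop("empty denovo-motif library: denovo_motif_pct undefined", call. = FALSE)
  known_hits <- vapply(known, function(p) scan_pwm(sequence, p, background), 0L)
  denovo_hits <- vapply(denovo, function(p) scan_pwm(sequence, p, background), 0L)
  is_ctcf <- vapply(known, function(p) isTRUE(p$is_ctcf), FALSE)
  c(n_ctcf_motifs = sum(known_hits[is_ctcf]),
    known_motif_pct = 100 * mean(known_hits > 0),
    denovo_motif_pct = 100 * mean(denovo_hits > 0))
}

#' Genomic-location features (n = 3)
#'
#' `tss_distance` is the signed distance from the peak summit to the nearest
#' TSS: positive when the summit lies downstream of the TSS in the gene's
#' orientation, 0 when it sits on the TSS. `annotation_code` encodes the
#' genomic context at the summit and `gene_type_code` the type of the nearest
#' gene, both via [location_vocabularies()].
#'
#' @param peak single-row peak data frame.
#' @param annotation `gene_annotation` object (see [read_gene_annotation()]).
#' @return named numeric vector of 3 values.
#' @export
extract_location_features <- function(peak, annotation) {
  tss <- annotation$tss
  if (!nrow(tss)) stop("empty TSS annotation", call. = FALSE)
  summit <- peak$start + peak$summit_offset
  same <- tss$chrom == peak$chrom
  cand <- if (any(same)) tss[same, , drop = FALSE] else tss
  d_abs <- abs(summit - cand$pos)
  i <- which.min(d_abs)
  signed <- if (cand$strand[i] == "-") cand$pos[i] - summit else summit - cand$pos[i]
  vocab <- location_vocabularies()
  ctx_label <- "intergenic"
  if (!is.null(annotation$contexts) && nrow(annotation$contexts)) {
    ctx <- annotation$contexts
    hit <- ctx$chrom == peak$chrom & ctx$start <= summit & ctx$end > summit
    if (any(hit)) ctx_label <- ctx$label[which(hit)[1]]
  }
  ann_code <- vocab$annotation[ctx_label]
  if (is.na(ann_code)) ann_code <- vocab$annotation["other"]
  gt_code <- vocab$gene_type[cand$gene_type[i]]
  if (is.na(gt_code)) gt_code <- vocab$gene_type["other"]
  c(annotation_code = unname(as.numeric(ann_code)),
    tss_distance = as.numeric(signed),
    gene_type_code = unname(as.numeric(gt_code)))
}

#' Build the full 24-column feature matrix for a set of peaks
#'
#' Runs all five extractor families per peak and assembles a data frame with
#' one row per peak in canonical column order. Deterministic given identical
#' inputs. Motif, sequence and location features depend only on the genome
#' and annotation; when re-extracting the same loci against new fragment
#' data (e.g. another individual), those columns can be supplied precomputed
#' via `static` (a data frame keyed by `peak_id`) to skip re-scanning.
#'
#' @param peaks peak data frame ([read_narrowpeak()] schema).
#' @param fragments fragment data frame covering the peaks' chromosomes.
#' @param genome named `DNAStringSet` or FASTA path.
#' @param conservation conservation track data frame or `NULL`.
#' @param known,denovo PWM lists.
#' @param annotation `gene_annotation` object.
#' @param mode `"strict"` aborts on any per-peak failure; `"lenient"` drops
#'   the failing peak with a warning.
#' @param static optional precomputed static-feature data frame (`peak_id` +
#'   conservation/GC/CpG/motif/location columns).
#' @return data frame: `peak_id` plus the 24 features of [feature_names()].
#' @export
build_feature_matrix <- function(peaks, fragments, genome, conservation,
                                 known, denovo, annotation,
                                 mode = c("strict", "lenient"), static = NULL) {
  mode <- match.arg(mode)
  if (is.character(genome) && length(genome) == 1L) genome <- read_genome(genome)
  n <- nrow(peaks)
  rows <- vector("list", n)
  ok <- rep(TRUE, n)
  static_cols <- c("conservation_mean", "gc_pct", "cpg_pct", "n_ctcf_motifs",
                   "known_motif_pct", "denovo_motif_pct", "annotation_code",
                   "tss_distance", "gene_type_code")
  hits <- overlap_pairs(peaks$chrom, peaks$start, peaks$end,
                        fragments$chrom, fragments$start, fragments$end)
  frag_idx <- split(hits[, 2], factor(hits[, 1], levels = seq_len(n)))
  for (i in seq_len(n)) {
    peak <- peaks[i, , drop = FALSE]
    res <- tryCatch({
      frags <- fragments[frag_idx[[i]], , drop = FALSE]
      pk <- extract_peak_features(peak, frags)
      ins <- extract_insert_features(peak, frags)
      cuts <- cut_sites(peak, frags)
      over <- count_overrepresented_cuts(peak, cuts)
      if (!is.null(static)) {
        st <- static[match(peak$name, static$peak_id), static_cols]
        stv <- as.numeric(st[1, ])
        names(stv) <- static_cols
      } else {
        seqch <- get_sequence(genome, peak$chrom, peak$start, peak$end)
        stv <- c(extract_sequence_features(peak, genome, conservation),
                 extract_motif_features(seqch, known, denovo),
                 extract_location_features(peak, annotation))
      }
      c(pk, ins, n_overrepresented_cuts = as.numeric(over), stv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (mode == "strict") {
        stop(sprintf("feature extraction failed for peak %s: %s",
                     peak$name, conditionMessage(res)), call. = FALSE)
      }
      warning(sprintf("dropping peak %s: %s", peak$name, conditionMessage(res)),
              call. = FALSE)
      ok[i] <- FALSE
    } else {
      rows[[i]] <- res[feature_names()]
    }
  }
  rows <- rows[ok]
  mat <- as.data.frame(do.call(rbind, rows))
  names(mat) <- feature_names()
  cbind(data.frame(peak_id = peaks$name[ok], stringsAsFactors = FALSE), mat)
}
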