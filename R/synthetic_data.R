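# Fully self-contained synthetic ATAC-seq fixtures: a random genome with
# planted GC-rich promoter islands and motif instances, TSS/context
# annotation, a conservation track, per-"cell-type" peak/fragment sets with
# class-conditional fragment-count and insert-size structure, matching
# segmentations, and a cohort with caQTL genotype effects on accessibility.
# All randomness flows from one seed through child_seed() streams.

#' Default class-conditional generating profiles
#'
#' Encodes the qualitative contrasts seen in real ATAC-seq data: promoters
#' carry the most fragments, enhancers fewer, other elements fewest;
#' nucleosome-free (short) inserts dominate promoters and enhancers while
#' other elements carry more mono/di-nucleosomal fragments. Fragment counts
#' are negative binomial (overdispersion 0.3); insert sizes come from a
#' 3-component normal mixture with means 60/200/400 bp.
#'
#' @return named list of per-class profiles.
#' @export
class_profiles <- function() {
  list(
    enhancer = list(frag_mean = 100, frag_disp = 0.3,
                    insert_weights = c(0.50, 0.35, 0.15)),
    promoter = list(frag_mean = 200, frag_disp = 0.3,
                    insert_weights = c(0.60, 0.32, 0.08)),
    other = list(frag_mean = 40, frag_disp = 0.3,
                 insert_weights = c(0.30, 0.40, 0.30))
  )
}

insert_mixture_means <- function() c(60, 200, 400)
insert_mixture_sds <- function() c(15, 50, 80)

synthetic_motifs <- function() {
  list(
    known = c(M_AP1 = "TGACTCAT", M_EBOX = "CACGTGAC", M_NFKB = "GGGATTTC",
              M_FOX = "TGTTTACT", M_GATA = "GATAAGGA", M_RUNT = "AACCACAA",
              M_IRF = "CATTGTTC", M_NR = "AGGTCAAG", M_SP1 = "CCCGCCCC",
              M_ETS = "AGGAAGTG"),
    ctcf = c(M_CTCF = "CCACCAGGGGGC"),
    denovo = c(D_1 = "ACGTACGT", D_2 = "TTGACGCA", D_3 = "GCCAATCA",
               D_4 = "AGATAAGC")
  )
}

consensus_to_pwm <- function(id, consensus, is_ctcf = FALSE, p_match = 0.85) {
  bases <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - p_match) / 3, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) mat[bases[j], j] <- p_match
  list(id = id, matrix = mat, is_ctcf = is_ctcf, score_threshold = NA_real_)
}

#' Generate a synthetic reference: genome, annotation, conservation, motifs
#'
#' The genome is random sequence (GC ~ 40%) with candidate region "slots"
#' every `spacing` bp, typed promoter / enhancer / background. Promoter slots
#' get a 1 kb GC- and CpG-rich island with a TSS at its center plus
#' promoter/exon/intron/TTS context intervals; enhancer slots get several
#' planted known/de novo motif instances; background slots get sparse motif
#' plants and occasional CTCF sites (insulator-like). Conservation is
#' elevated over promoter and enhancer slots and written as 25-bp bins
#' (uncovered bases read as 0).
#'
#' @param seed integer seed; the same seed reproduces the reference
#'   byte-for-byte.
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_len chromosome length in bp (default 6e5, minimum 1e4).
#' @param spacing distance between slot anchors (default 3000 bp).
#' @return list: `genome` (`DNAStringSet`), `annotation` (`gene_annotation`),
#'   `conservation` (bedGraph data frame), `pwms_known`, `pwms_denovo`
#'   (PWM lists; CTCF flagged in `pwms_known`), `slots` (data frame with
#'   `slot_id`, `chrom`, `anchor`, `type`, `n_motifs_planted`), `params`.
#' @export
generate_reference <- function(seed = 1L, n_chroms = 2L, chrom_len = 6e5L,
                               spacing = 3000L) {
  if (chrom_len < 1e4) stop("chrom_len must be >= 10 kb", call. = FALSE)
  motifs <- synthetic_motifs()
  pwms_known <- c(
    lapply(names(motifs$known), function(id) consensus_to_pwm(id, motifs$known[id])),
    lapply(names(motifs$ctcf), function(id) consensus_to_pwm(id, motifs$ctcf[id], TRUE))
  )
  pwms_denovo <- lapply(names(motifs$denovo),
                        function(id) consensus_to_pwm(id, motifs$denovo[id]))

  chroms <- paste0("chr", seq_len(n_chroms))
  bg_prob <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  seqs <- character(n_chroms); names(seqs) <- chroms
  slot_rows <- list(); tss_rows <- list(); ctx_rows <- list(); cons_rows <- list()
  slot_counter <- 0L
  for (ci in seq_len(n_chroms)) {
    set.seed(child_seed(seed, 10L + ci))
    seq_v <- sample(names(bg_prob), chrom_len, replace = TRUE, prob = bg_prob)
    anchors <- seq(3000L, chrom_len - 3000L, by = spacing)
    types <- sample(c("promoter", "enhancer", "background"), length(anchors),
                    replace = TRUE, prob = c(0.25, 0.40, 0.35))
    n_planted <- integer(length(anchors))
    for (ai in seq_along(anchors)) {
      a <- anchors[ai]
      slot_counter <- slot_counter + 1L
      if (types[ai] == "promoter") {
        # GC/CpG-rich island of 1 kb centered on the TSS
        island <- sample(names(bg_prob), 1000L, replace = TRUE,
                         prob = c(A = 0.19, C = 0.31, G = 0.31, T = 0.19))
        seq_v[(a - 500L):(a + 499L) + 1L] <- island
        strand <- sample(c("+", "-"), 1L)
        gene_type <- sample(c("protein_coding", "lincRNA", "pseudogene"), 1L,
                            prob = c(0.8, 0.15, 0.05))
        tss_rows[[length(tss_rows) + 1L]] <- data.frame(
          chrom = chroms[ci], pos = a, strand = strand,
          gene_id = sprintf("gene_%05d", slot_counter), gene_type = gene_type,
          stringsAsFactors = FALSE)
        dir <- if (strand == "+") 1L else -1L
        s_raw <- c(a - 500L, a + dir * 500L, a + dir * 800L)
        e_raw <- c(a + 500L, a + dir * 800L, a + dir * 1500L)
        ctx_rows[[length(ctx_rows) + 1L]] <- data.frame(
          chrom = chroms[ci], start = pmin(s_raw, e_raw), end = pmax(s_raw, e_raw),
          label = c("promoter-TSS", "exon", "intron"), stringsAsFactors = FALSE)
      }
      # motif planting on a non-overlapping grid around the anchor
      p_plant <- switch(types[ai], enhancer = 0.60, promoter = 0.35, background = 0.15)
      plant <- c(motifs$known[stats::runif(length(motifs$known)) < p_plant],
                 motifs$denovo[stats::runif(length(motifs$denovo)) <
                                 switch(types[ai], enhancer = 0.5, promoter = 0.2,
                                        background = 0.1)])
      if (types[ai] == "background" && stats::runif(1) < 0.30) {
        plant <- c(plant, rep(motifs$ctcf, sample(1:3, 1L)))
      }
      if (length(plant)) {
        grid <- a - 300L + 20L * (seq_len(30L) - 1L)
        pos <- sample(grid, length(plant))
        for (pi in seq_along(plant)) {
          m <- strsplit(plant[[pi]], "")[[1]]
          seq_v[pos[pi]:(pos[pi] + length(m) - 1L) + 1L] <- m
        }
      }
      n_planted[ai] <- length(plant)
      # conservation: 25-bp bins over +/- 500 bp. Regulatory slots are only
      # mildly elevated over background, and most variance sits at the locus
      # level (as in real per-base conservation, where whole elements are
      # conserved or not), so class distributions overlap heavily.
      lvl <- switch(types[ai], background = 0.15, 0.30) + stats::rnorm(1, 0, 0.15)
      bins <- seq(a - 500L, a + 475L, by = 25L)
      cons_rows[[length(cons_rows) + 1L]] <- data.frame(
        chrom = chroms[ci], start = bins, end = bins + 25L,
        score = signif(pmin(pmax(stats::rnorm(length(bins), lvl, 0.10), 0), 1), 6),
        stringsAsFactors = FALSE)
    }
    slot_rows[[ci]] <- data.frame(
      slot_id = sprintf("%s_slot%04d", chroms[ci], seq_along(anchors)),
      chrom = chroms[ci], anchor = anchors, type = types,
      n_motifs_planted = n_planted, stringsAsFactors = FALSE)
    seqs[ci] <- paste(seq_v, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  tss <- do.call(rbind, tss_rows)
  contexts <- do.call(rbind, ctx_rows)
  contexts$start <- as.integer(pmax(contexts$start, 0L))
  contexts$end <- as.integer(pmin(contexts$end, chrom_len))
  swap <- contexts$end < contexts$start
  tmp <- contexts$start[swap]
  contexts$start[swap] <- contexts$end[swap]; contexts$end[swap] <- tmp
  annotation <- list(tss = tss, contexts = contexts)
  class(annotation) <- "gene_annotation"
  list(genome = genome, annotation = annotation,
       conservation = do.call(rbind, cons_rows),
       pwms_known = pwms_known, pwms_denovo = pwms_denovo,
       slots = do.call(rbind, slot_rows),
       params = list(seed = seed, n_chroms = n_chroms, chrom_len = chrom_len,
                     spacing = spacing))
}

slot_class_for <- function(class) {
  switch(class, enhancer = "enhancer", promoter = "promoter", other = "background")
}

state_for_class <- function(class, seed) {
  set.seed(seed)
  switch(class,
         enhancer = sample(c("EnhA", "Enh"), 1L, prob = c(0.7, 0.3)),
         promoter = sample(c("TssA", "Tss"), 1L, prob = c(0.7, 0.3)),
         other = sample(c("Tx", "Ins", "ReprPC", "Quies"), 1L,
                        prob = c(0.3, 0.2, 0.2, 0.3)))
}

draw_fragments_for_region <- function(n_frag, anchor, region_start, region_end,
                                      weights) {
  if (!n_frag) {
    return(data.frame(start = integer(), end = integer()))
  }
  comp <- sample.int(3L, n_frag, replace = TRUE, prob = weights)
  size <- round(stats::rnorm(n_frag, insert_mixture_means()[comp],
                             insert_mixture_sds()[comp]))
  size <- pmax(pmin(size, 800L), 20L)
  center <- round(stats::rnorm(n_frag, anchor, (region_end - region_start) / 5))
  start <- as.integer(pmax(center - size %/% 2L, 0L))
  data.frame(start = start, end = as.integer(start + size))
}

region_summit <- function(frags, region_start, region_end) {
  len <- region_end - region_start
  if (!nrow(frags)) return(list(offset = len %/% 2L, pileup = 0L))
  s <- pmax(frags$start - region_start, 0L) + 1L
  e <- pmin(frags$end - region_start, len)
  keep <- e >= s
  if (!any(keep)) return(list(offset = len %/% 2L, pileup = 0L))
  cov <- as.integer(IRanges::coverage(IRanges::IRanges(s[keep], e[keep]), width = len))
  list(offset = which.max(cov) - 1L, pileup = max(cov))
}

#' Generate one synthetic "cell type": peaks, fragments, segmentation, truth
#'
#' Regions are placed on reference slots matching their class (enhancers on
#' motif-planted slots, promoters on GC islands, "other" on background
#' slots); distinct cell types get disjoint loci by passing `exclude_slots`.
#' Fragments are drawn per region from the class profile; narrowPeak score,
#' fold change and summit are derived from the generated coverage; the
#' emitted segmentation assigns each region's slot window a state consistent
#' with its true class and fills the rest of the genome with "Quies".
#'
#' @param reference a [generate_reference()] object.
#' @param profiles per-class profiles ([class_profiles()]).
#' @param n_per_class named counts, e.g. `c(enhancer = 100, promoter = 100,
#'   other = 100)`; classes with 0 are skipped.
#' @param seed integer seed.
#' @param exclude_slots slot ids already used (for disjoint cell types).
#' @param cell_type tag recorded in the truth table.
#' @return list: `peaks` (narrowPeak schema), `fragments`, `segmentation`,
#'   `truth` (region id, interval, true class, generating parameters),
#'   `used_slots`.
#' @export
generate_celltype <- function(reference, profiles = class_profiles(),
                              n_per_class = c(enhancer = 100, promoter = 100,
                                              other = 100),
                              seed = 1L, exclude_slots = character(),
                              cell_type = "synthetic") {
  slots <- reference$slots[!reference$slots$slot_id %in% exclude_slots, , drop = FALSE]
  picked <- list()
  set.seed(child_seed(seed, 1L))
  for (cls in names(n_per_class)) {
    n <- n_per_class[[cls]]
    if (!n) next
    avail <- slots[slots$type == slot_class_for(cls), , drop = FALSE]
    if (nrow(avail) < n) {
      stop(sprintf("requested %d %s regions but only %d free %s slots",
                   n, cls, nrow(avail), slot_class_for(cls)), call. = FALSE)
    }
    sel <- avail[sample(nrow(avail), n), , drop = FALSE]
    sel$class <- cls
    picked[[cls]] <- sel
    slots <- slots[!slots$slot_id %in% sel$slot_id, , drop = FALSE]
  }
  regions <- do.call(rbind, picked)
  regions <- regions[order(regions$chrom, regions$anchor), , drop = FALSE]
  rownames(regions) <- NULL

  n_reg <- nrow(regions)
  set.seed(child_seed(seed, 2L))
  len <- as.integer(round(stats::runif(n_reg, 200, 1000)))
  regions$start <- as.integer(regions$anchor - len %/% 2L)
  regions$end <- regions$start + len
  mu <- vapply(regions$class, function(c) profiles[[c]]$frag_mean, 0)
  size <- vapply(regions$class, function(c) 1 / profiles[[c]]$frag_disp, 0)
  regions$n_frag <- stats::rnbinom(n_reg, mu = mu, size = size)

  peaks <- vector("list", n_reg); frag_list <- vector("list", n_reg)
  seg_states <- character(n_reg)
  for (i in seq_len(n_reg)) {
    set.seed(child_seed(seed, 1000L + i))
    w <- profiles[[regions$class[i]]]$insert_weights
    fr <- draw_fragments_for_region(regions$n_frag[i], regions$anchor[i],
                                    regions$start[i], regions$end[i], w)
    sm <- region_summit(fr, regions$start[i], regions$end[i])
    # 6 significant digits so emitted files round-trip losslessly
    fold <- signif(sm$pileup / 0.5 + stats::runif(1, 0, 0.5), 6)  # vs background 0.5x
    peaks[[i]] <- data.frame(
      chrom = regions$chrom[i], start = regions$start[i], end = regions$end[i],
      name = sprintf("%s_peak%05d", cell_type, i),
      peak_score = round(pmin(10 * fold, 1000)), strand = ".",
      fold_change = fold,
      neglog10_p = signif(2 + fold / 2, 6), neglog10_q = signif(1 + fold / 3, 6),
      summit_offset = sm$offset, stringsAsFactors = FALSE)
    if (nrow(fr)) frag_list[[i]] <- data.frame(chrom = regions$chrom[i], fr)
    seg_states[i] <- state_for_class(regions$class[i], child_seed(seed, 5000L + i))
  }
  peaks <- do.call(rbind, peaks)
  fragments <- do.call(rbind, frag_list)
  if (is.null(fragments)) {
    fragments <- data.frame(chrom = character(), start = integer(), end = integer())
  }
  fragments <- fragments[fragments$end > fragments$start, , drop = FALSE]
  fragments <- fragments[order(fragments$chrom, fragments$start, fragments$end), ,
                         drop = FALSE]
  rownames(fragments) <- NULL
  fragments$size <- fragments$end - fragments$start

  seg <- build_segmentation(regions, seg_states, reference)
  truth <- data.frame(region_id = peaks$name, slot_id = regions$slot_id,
                      chrom = regions$chrom, start = regions$start,
                      end = regions$end, class = regions$class,
                      state = seg_states, cell_type = cell_type,
                      n_frag = regions$n_frag, stringsAsFactors = FALSE)
  list(peaks = peaks, fragments = fragments, segmentation = seg, truth = truth,
       used_slots = regions$slot_id)
}

# Partition each chromosome: slot windows (+/- 1200 bp around the anchor) get
# the class state, everything else is "Quies".
build_segmentation <- function(regions, states, reference) {
  half <- 1200L
  rows <- list()
  for (chr in unique(reference$slots$chrom)) {
    chrom_len <- reference$params$chrom_len
    r <- regions[regions$chrom == chr, , drop = FALSE]
    st <- states[regions$chrom == chr]
    ord <- order(r$anchor)
    r <- r[ord, , drop = FALSE]; st <- st[ord]
    pos <- 0L
    for (j in seq_len(nrow(r))) {
      w_start <- max(r$anchor[j] - half, pos)
      w_end <- min(r$anchor[j] + half, chrom_len)
      if (w_start > pos) {
        rows[[length(rows) + 1L]] <- data.frame(chrom = chr, start = pos,
                                                end = w_start, state = "Quies")
      }
      rows[[length(rows) + 1L]] <- data.frame(chrom = chr, start = w_start,
                                              end = w_end, state = st[j])
      pos <- w_end
    }
    if (pos < chrom_len) {
      rows[[length(rows) + 1L]] <- data.frame(chrom = chr, start = pos,
                                              end = chrom_len, state = "Quies")
    }
  }
  seg <- do.call(rbind, rows)
  seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
  class(seg) <- c("segmentation", "data.frame")
  seg
}

#' Generate a synthetic cohort with caQTL genotype effects
#'
#' A shared region layout (consensus loci) is drawn once; each individual
#' gets their own fragment counts. At caQTL regions the negative-binomial
#' fragment-count mean scales by `effect^(dosage - 1)` where dosage counts
#' the chromatin-opening allele (so heterozygotes sit at the class baseline);
#' control variants sit in regions with no genotype effect. An individual
#' "calls a peak" at a region only when their fragment count reaches
#' `peak_min_count`; absent peaks yield no prediction downstream.
#'
#' @param reference a [generate_reference()] object.
#' @param profiles per-class profiles.
#' @param n_individuals cohort size (default 19).
#' @param n_regions named counts of shared loci per class (default 150
#'   enhancer + 150 other).
#' @param n_caqtl number of caQTL variants (placed in enhancer regions).
#' @param n_control number of no-effect control variants (also in enhancer
#'   regions, disjoint from the caQTL set).
#' @param effect accessibility fold-change per opening allele (> 0; 1 = null).
#' @param allele_freq opening-allele frequency for Hardy-Weinberg genotypes.
#' @param peak_min_count minimum fragments for an individual peak call.
#' @param seed integer seed.
#' @param base optional precomputed [generate_celltype()] result to reuse as
#'   the shared region layout; with a fixed `base`, different seeds vary only
#'   genotypes and per-individual counts, which keeps locus-level features
#'   cacheable across replicate cohorts.
#' @return list: `individuals` (named list with `peaks` and `fragments` per
#'   individual), `regions` (shared loci with true class), `segmentation`,
#'   `genotypes`, `caqtl_ids`, `control_ids` (region ids), `variant_map`,
#'   `truth` (region x individual fragment counts and peak-call flags).
#' @export
generate_cohort <- function(reference, profiles = class_profiles(),
                            n_individuals = 19L,
                            n_regions = c(enhancer = 150, other = 150),
                            n_caqtl = 40L, n_control = 40L, effect = 2,
                            allele_freq = 0.4, peak_min_count = 10L, seed = 1L,
                            base = NULL) {
  if (effect <= 0) stop("effect must be > 0", call. = FALSE)
  if (is.null(base)) {
    base <- generate_celltype(reference, profiles, n_regions,
                              seed = child_seed(seed, 21L), cell_type = "cohort")
  }
  regions <- base$truth
  if (n_caqtl + n_control > sum(regions$class == "enhancer")) {
    stop("n_caqtl + n_control exceeds the number of enhancer regions", call. = FALSE)
  }
  # locus ids inherit the layout tag so distinct cohorts cannot collide in a
  # training-locus manifest
  regions$region_id <- sub("_peak", "_locus", regions$region_id)

  set.seed(child_seed(seed, 22L))
  enh_idx <- which(regions$class == "enhancer")
  qtl_idx <- sample(enh_idx, n_caqtl)
  ctl_idx <- sample(setdiff(enh_idx, qtl_idx), n_control)
  caqtl_ids <- regions$region_id[qtl_idx]
  control_ids <- regions$region_id[ctl_idx]

  var_idx <- c(qtl_idx, ctl_idx)
  variants <- data.frame(
    id = sprintf("rs%06d", seq_along(var_idx)),
    chrom = regions$chrom[var_idx],
    pos = as.integer((regions$start[var_idx] + regions$end[var_idx]) %/% 2L),
    opening_allele = "A", stringsAsFactors = FALSE)
  inds <- sprintf("ind%02d", seq_len(n_individuals))
  set.seed(child_seed(seed, 23L))
  dosages <- matrix(stats::rbinom(length(var_idx) * n_individuals, 2L, allele_freq),
                    nrow = length(var_idx), dimnames = list(variants$id, inds))
  genotypes <- list(variants = variants, dosages = dosages)
  variant_map <- data.frame(ocr_id = regions$region_id[var_idx],
                            variant_id = variants$id, stringsAsFactors = FALSE)

  mu0 <- vapply(regions$class, function(c) profiles[[c]]$frag_mean, 0)
  disp <- vapply(regions$class, function(c) 1 / profiles[[c]]$frag_disp, 0)
  effect_row <- match(regions$region_id, variant_map$ocr_id[seq_len(n_caqtl)])

  individuals <- vector("list", n_individuals); names(individuals) <- inds
  truth_rows <- list()
  for (ii in seq_len(n_individuals)) {
    set.seed(child_seed(seed, 100L + ii))
    mu <- mu0
    has_qtl <- !is.na(effect_row)
    dos <- dosages[variant_map$variant_id[effect_row[has_qtl]], ii]
    mu[has_qtl] <- mu0[has_qtl] * effect^(dos - 1)
    n_frag <- stats::rnbinom(nrow(regions), mu = mu, size = disp)
    called <- n_frag >= peak_min_count
    peaks <- vector("list", nrow(regions)); frag_list <- vector("list", nrow(regions))
    for (i in seq_len(nrow(regions))) {
      if (!called[i]) next
      set.seed(child_seed(seed, 100000L + ii * 2000L + i))
      w <- profiles[[regions$class[i]]]$insert_weights
      fr <- draw_fragments_for_region(n_frag[i], (regions$start[i] + regions$end[i]) %/% 2L,
                                      regions$start[i], regions$end[i], w)
      sm <- region_summit(fr, regions$start[i], regions$end[i])
      fold <- signif(sm$pileup / 0.5 + stats::runif(1, 0, 0.5), 6)
      peaks[[i]] <- data.frame(
        chrom = regions$chrom[i], start = regions$start[i], end = regions$end[i],
        name = regions$region_id[i],
        peak_score = round(pmin(10 * fold, 1000)), strand = ".",
        fold_change = fold, neglog10_p = signif(2 + fold / 2, 6),
        neglog10_q = signif(1 + fold / 3, 6), summit_offset = sm$offset,
        stringsAsFactors = FALSE)
      if (nrow(fr)) frag_list[[i]] <- data.frame(chrom = regions$chrom[i], fr)
    }
    fragments <- do.call(rbind, frag_list)
    if (is.null(fragments)) {
      fragments <- data.frame(chrom = character(), start = integer(), end = integer())
    }
    fragments <- fragments[order(fragments$chrom, fragments$start, fragments$end), ,
                           drop = FALSE]
    rownames(fragments) <- NULL
    fragments$size <- fragments$end - fragments$start
    individuals[[ii]] <- list(peaks = do.call(rbind, peaks), fragments = fragments)
    truth_rows[[ii]] <- data.frame(region_id = regions$region_id,
                                   individual = inds[ii], n_frag = n_frag,
                                   peak_called = called, stringsAsFactors = FALSE)
  }
  list(individuals = individuals,
       regions = regions[, c("region_id", "chrom", "start", "end", "class", "state")],
       segmentation = base$segmentation, genotypes = genotypes,
       caqtl_ids = caqtl_ids, control_ids = control_ids,
       variant_map = variant_map, truth = do.call(rbind, truth_rows),
       params = list(seed = seed, effect = effect, allele_freq = allele_freq,
                     peak_min_count = peak_min_count))
}

#' Simulate a labeled feature matrix directly (no genome)
#'
#' Draws standard-normal features and shifts the listed informative columns
#' by a per-class effect, giving precise control over which features carry
#' signal; used for classifier and feature-importance testing where the full
#' fragment-level generator is unnecessarily heavy.
#'
#' @param n_per_class rows per class (named: enhancer/other, or any labels).
#' @param informative named numeric vector: feature name -> effect size
#'   (mean shift of the positive class, in SD units).
#' @param n_features total feature count (default 24, named by
#'   [feature_names()]; larger values append noise_<i> columns).
#' @param seed integer seed.
#' @param source source tag.
#' @return a `labeled_dataset`.
#' @export
simulate_labeled_features <- function(n_per_class = c(enhancer = 200, other = 200),
                                      informative = c(n_inserts_all = 2),
                                      n_features = 24L, seed = 1L,
                                      source = "simulated") {
  base_names <- feature_names()
  nm <- if (n_features <= length(base_names)) base_names[seq_len(n_features)] else {
    c(base_names, sprintf("noise_%d", seq_len(n_features - length(base_names))))
  }
  bad <- setdiff(names(informative), nm)
  if (length(bad)) stop(sprintf("unknown informative features: %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  set.seed(seed)
  n_tot <- sum(n_per_class)
  X <- matrix(stats::rnorm(n_tot * n_features), n_tot, n_features,
              dimnames = list(sprintf("sim_%05d", seq_len(n_tot)), nm))
  labels <- rep(names(n_per_class), n_per_class)
  pos <- labels == names(n_per_class)[1]
  for (f in names(informative)) X[pos, f] <- X[pos, f] + informative[[f]]
  ds <- list(features = X, labels = factor(labels), source = source)
  class(ds) <- "labeled_dataset"
  ds
}

#' Write a generated cell type plus its reference to a fixture directory
#'
#' Emits every file the command-line pipeline would consume: genome FASTA,
#' TSS/context annotation, conservation bedGraph, PWM library, narrowPeak,
#' fragment BED and segmentation BED, plus the truth table as TSV.
#'
#' @param reference [generate_reference()] output.
#' @param celltype [generate_celltype()] output.
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_synthetic_fixture <- function(reference, celltype, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    tss = file.path(dir, "tss.tsv"),
    contexts = file.path(dir, "contexts.bed"),
    conservation = file.path(dir, "conservation.bedGraph"),
    pwms = file.path(dir, "motifs.jaspar"),
    denovo = file.path(dir, "denovo.jaspar"),
    peaks = file.path(dir, "peaks.narrowPeak"),
    fragments = file.path(dir, "fragments.bed"),
    segmentation = file.path(dir, "segmentation.bed"),
    truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(reference$genome, paths["genome"])
  write_gene_annotation(reference$annotation, paths["tss"], paths["contexts"])
  write_conservation(reference$conservation, paths["conservation"])
  write_pwm_library(reference$pwms_known, paths["pwms"])
  write_pwm_library(reference$pwms_denovo, paths["denovo"])
  write_narrowpeak(celltype$peaks, paths["peaks"])
  write_fragments(celltype$fragments, paths["fragments"])
  write_segmentation(celltype$segmentation, paths["segmentation"])
  write_table(celltype$truth, paths["truth"])
  paths
}
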