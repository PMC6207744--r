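# Readers and writers for every external format the pipeline touches.
# Internally all coordinates are 0-based half-open; BED-family inputs need no
# shift, VCF positions (1-based) are converted at the boundary. Chromosome
# naming is taken literally: "chr1" and "1" are different sequences and any
# mismatch between files is an error, never silently harmonized.

#' Read a narrowPeak (BED6+4) peak file
#'
#' Parses MACS2-style narrowPeak records into a peak data frame. Column 5 is
#' the peak score, column 7 the fold change (signal value), columns 8/9 the
#' -log10 p/q values and column 10 the summit offset from the peak start.
#'
#' @param path path to a narrowPeak file (plain text, 10 tab-separated columns).
#' @param blacklist optional data frame of intervals (`chrom`,`start`,`end`);
#'   peaks overlapping any blacklist interval by >= 1 bp are dropped.
#' @return a data frame with columns `chrom`, `start`, `end`, `name`,
#'   `peak_score`, `strand`, `fold_change`, `neglog10_p`, `neglog10_q`,
#'   `summit_offset`, in file order.
#' @export
read_narrowpeak <- function(path, blacklist = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    name = character(), peak_score = numeric(), strand = character(),
                    fold_change = numeric(), neglog10_p = numeric(),
                    neglog10_q = numeric(), summit_offset = integer(),
                    stringsAsFactors = FALSE)
  if (!length(lines)) return(out)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 10L)
  if (length(bad)) {
    stop_parse(path, bad[1], sprintf("expected 10 tab-separated columns, found %d", nf[bad[1]]))
  }
  m <- do.call(rbind, fields)
  out <- data.frame(
    chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
    name = m[, 4], peak_score = as.numeric(m[, 5]), strand = m[, 6],
    fold_change = as.numeric(m[, 7]), neglog10_p = as.numeric(m[, 8]),
    neglog10_q = as.numeric(m[, 9]), summit_offset = as.integer(m[, 10]),
    stringsAsFactors = FALSE
  )
  check_intervals(out$chrom, out$start, out$end, "peak")
  bad <- which(out$summit_offset < 0 | out$summit_offset >= out$end - out$start)
  if (length(bad)) stop_parse(path, bad[1], "summit offset outside peak")
  bad <- which(out$fold_change < 0)
  if (length(bad)) stop_parse(path, bad[1], "negative fold change")
  if (!is.null(blacklist) && nrow(out)) {
    hits <- overlap_pairs(out$chrom, out$start, out$end,
                          blacklist$chrom, blacklist$start, blacklist$end)
    if (nrow(hits)) out <- out[-unique(hits[, 1]), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write peaks in narrowPeak format
#' @param peaks data frame as returned by [read_narrowpeak()].
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   format_sig(peaks$peak_score), peaks$strand,
                   format_sig(peaks$fold_change), format_sig(peaks$neglog10_p),
                   format_sig(peaks$neglog10_q), peaks$summit_offset)
  writeLines(lines, path)
  invisible(path)
}

#' Read Tn5 fragments from a BED or BAM file
#'
#' Each record is one paired-end Tn5 insert. BED input must have at least 3
#' columns (chrom, start, end); from BAM, one fragment is taken per
#' properly-paired template as `[leftmost start, leftmost start + |TLEN|)`,
#' using the first-in-pair record only and skipping secondary, supplementary
#' and unpaired reads. Duplicates are not removed (deduplication is assumed
#' upstream).
#'
#' @param path BED (plain text) or coordinate-sorted, indexed BAM.
#' @param region optional single-row interval list/data frame with `chrom`,
#'   `start`, `end`; only fragments overlapping it by >= 1 bp are returned.
#' @param tn5_shift apply the +4/-5 Tn5 offset to fragment ends (default off).
#' @return data frame with `chrom`, `start`, `end`, `size`.
#' @export
read_fragments <- function(path, region = NULL, tn5_shift = FALSE) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    frags <- read_fragments_bam(path, region)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      frags <- data.frame(chrom = character(), start = integer(), end = integer())
    } else {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      nf <- lengths(fields)
      bad <- which(nf < 3L)
      if (length(bad)) stop_parse(path, bad[1], "fragment BED needs >= 3 columns")
      frags <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                          start = as.integer(vapply(fields, `[`, "", 2L)),
                          end = as.integer(vapply(fields, `[`, "", 3L)),
                          stringsAsFactors = FALSE)
    }
    check_intervals(frags$chrom, frags$start, frags$end, "fragment")
    if (!is.null(region) && nrow(frags)) {
      keep <- frags$chrom == region$chrom & frags$start < region$end & frags$end > region$start
      frags <- frags[keep, , drop = FALSE]
      rownames(frags) <- NULL
    }
  }
  if (tn5_shift && nrow(frags)) {
    frags$start <- frags$start + 4L
    frags$end <- frags$end - 5L
    frags <- frags[frags$end > frags$start, , drop = FALSE]
    rownames(frags) <- NULL
  }
  frags$size <- frags$end - frags$start
  frags
}

read_fragments_bam <- function(path, region = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM requires the Rsamtools package", call. = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  what <- c("rname", "pos", "isize")
  if (!is.null(region)) {
    if (!file.exists(paste0(path, ".bai")) && !file.exists(sub("\\.bam$", ".bai", path))) {
      stop("region queries need an indexed BAM; run samtools index first", call. = FALSE)
    }
    which <- GenomicRangesWhich(region)
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, which = which)
  } else {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  }
  res <- Rsamtools::scanBam(path, param = param)
  chrom <- unlist(lapply(res, function(r) as.character(r$rname)), use.names = FALSE)
  pos <- unlist(lapply(res, function(r) r$pos), use.names = FALSE)
  isize <- unlist(lapply(res, function(r) r$isize), use.names = FALSE)
  keep <- !is.na(isize) & isize != 0L
  chrom <- chrom[keep]; pos <- pos[keep]; isize <- abs(isize[keep])
  start0 <- pmin(pos, pos + 0L) - 1L  # BAM pos is 1-based leftmost
  frags <- data.frame(chrom = chrom, start = start0, end = start0 + isize,
                      stringsAsFactors = FALSE)
  if (!is.null(region) && nrow(frags)) {
    keep <- frags$chrom == region$chrom & frags$start < region$end & frags$end > region$start
    frags <- frags[keep, , drop = FALSE]
  }
  frags <- unique(frags)
  rownames(frags) <- NULL
  frags
}

GenomicRangesWhich <- function(region) {
  IRanges::IRangesList(stats::setNames(
    list(IRanges::IRanges(region$start + 1L, region$end)), region$chrom))
}

#' Write fragments as 3-column BED
#' @param fragments data frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_fragments <- function(fragments, path) {
  writeLines(sprintf("%s\t%d\t%d", fragments$chrom, fragments$start, fragments$end), path)
  invisible(path)
}

#' Read a ChromHMM-style segmentation (BED4)
#'
#' Segmentations are genome partitions: intervals on the same chromosome must
#' not overlap. The result is sorted by chromosome then start.
#'
#' @param path BED4 file (chrom, start, end, state label).
#' @return data frame `chrom`, `start`, `end`, `state`, class `"segmentation"`.
#' @export
read_segmentation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    seg <- data.frame(chrom = character(), start = integer(), end = integer(),
                      state = character(), stringsAsFactors = FALSE)
    class(seg) <- c("segmentation", "data.frame")
    return(seg)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad)) stop_parse(path, bad[1], "segmentation BED needs 4 columns")
  seg <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                    start = as.integer(vapply(fields, `[`, "", 2L)),
                    end = as.integer(vapply(fields, `[`, "", 3L)),
                    state = vapply(fields, `[`, "", 4L),
                    stringsAsFactors = FALSE)
  check_intervals(seg$chrom, seg$start, seg$end, "segment")
  ord <- order(seg$chrom, seg$start)
  line_no <- seq_along(lines)[ord]
  seg <- seg[ord, , drop = FALSE]
  same <- seg$chrom[-1] == seg$chrom[-nrow(seg)]
  ovl <- which(same & seg$start[-1] < seg$end[-nrow(seg)])
  if (length(ovl)) {
    stop(sprintf("%s: overlapping segments (lines %d and %d): segmentations must be partitions",
                 path, line_no[ovl[1]], line_no[ovl[1] + 1L]), call. = FALSE)
  }
  rownames(seg) <- NULL
  class(seg) <- c("segmentation", "data.frame")
  seg
}

#' Write a segmentation as BED4
#' @param seg segmentation data frame.
#' @param path output path.
#' @export
write_segmentation <- function(seg, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", seg$chrom, seg$start, seg$end, seg$state), path)
  invisible(path)
}

#' Query the state at a single genomic position
#' @param seg segmentation data frame.
#' @param chrom chromosome name.
#' @param pos 0-based position.
#' @return state label, or `"unsegmented"` if no segment covers the position.
#' @export
state_at <- function(seg, chrom, pos) {
  hit <- seg$chrom == chrom & seg$start <= pos & seg$end > pos
  if (!any(hit)) return("unsegmented")
  seg$state[which(hit)[1]]
}

#' Read a PWM library (JASPAR or HOMER text)
#'
#' JASPAR blocks (`>ID name` followed by four `A|C|G|T [counts]` rows) and
#' HOMER motif files (`>consensus name log-odds-threshold` followed by one
#' row of four probabilities per position) are both accepted. Count matrices
#' are converted to column-normalized probabilities with a pseudocount of
#' 0.25 per cell; probability matrices are taken as-is.
#'
#' @param path motif file.
#' @param ctcf_ids character vector of motif identifiers to flag as CTCF.
#' @return list of PWM objects: `id`, `matrix` (4 x L, rows A,C,G,T),
#'   `is_ctcf`, `score_threshold` (log-odds cutoff or `NA`).
#' @export
read_pwm_library <- function(path, ctcf_ids = character()) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop(sprintf("%s: no motif records found", path), call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(header, "[ \t]+")[[1]]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (any(grepl("^[ACGT]\\s*\\[", body)) || any(grepl("^[ACGT][ \t]", body))) {
      # JASPAR: four labelled rows of counts
      mat <- parse_jaspar_block(body, path)
      id <- toks[1]
      thr <- NA_real_
      mat <- normalize_counts(mat, path, id)
    } else {
      # HOMER: one probability row per position
      rows <- lapply(body, function(l) as.numeric(strsplit(l, "[ \t]+")[[1]]))
      if (any(vapply(rows, length, 0L) != 4L)) {
        stop(sprintf("%s: motif %s: expected 4 probabilities per row", path, toks[1]),
             call. = FALSE)
      }
      mat <- t(do.call(rbind, rows))
      rownames(mat) <- c("A", "C", "G", "T")
      id <- if (length(toks) >= 2) toks[2] else toks[1]
      thr <- if (length(toks) >= 3) suppressWarnings(as.numeric(toks[3])) else NA_real_
      cs <- colSums(mat)
      if (any(cs <= 0)) {
        stop(sprintf("%s: motif %s: column of all zeros", path, id), call. = FALSE)
      }
      mat <- sweep(mat, 2, cs, "/")
    }
    if (ncol(mat) < 4L) {
      stop(sprintf("%s: motif %s: length %d < 4", path, id, ncol(mat)), call. = FALSE)
    }
    pwms[[i]] <- list(id = id, matrix = mat, is_ctcf = id %in% ctcf_ids,
                      score_threshold = thr)
  }
  pwms
}

parse_jaspar_block <- function(body, path) {
  mat <- matrix(NA_real_, 4, 0)
  rows <- list()
  for (l in body) {
    base <- substr(l, 1, 1)
    rest <- substring(l, 2)
    nums <- regmatches(rest, gregexpr("[0-9.eE+-]+", rest))[[1]]
    rows[[base]] <- as.numeric(nums)
  }
  if (!all(c("A", "C", "G", "T") %in% names(rows))) {
    stop(sprintf("%s: JASPAR block missing one of A/C/G/T rows", path), call. = FALSE)
  }
  L <- unique(vapply(rows[c("A", "C", "G", "T")], length, 0L))
  if (length(L) != 1L) stop(sprintf("%s: ragged JASPAR rows", path), call. = FALSE)
  mat <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  mat
}

normalize_counts <- function(mat, path, id) {
  cs <- colSums(mat)
  if (any(cs == 0)) {
    stop(sprintf("%s: motif %s: column of all zeros", path, id), call. = FALSE)
  }
  if (max(cs) <= 1 + 1e-3) {
    # already probabilities (e.g. written by write_pwm_library): no pseudocount
    return(sweep(mat, 2, cs, "/"))
  }
  mat <- mat + 0.25
  sweep(mat, 2, colSums(mat), "/")
}

#' Write a PWM library in JASPAR probability format
#' @param pwms list of PWM objects.
#' @param path output path.
#' @export
write_pwm_library <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format_sig(p$matrix[b, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a genotype table
#'
#' TSV input: header `id chrom pos opening_allele <sample...>`, one variant
#' per row, dosages in {0,1,2,NA} counting copies of the chromatin-opening
#' allele. Minimal VCF input (`.vcf`): CHROM POS ID REF ALT ... GT fields,
#' with the opening allele given in an `OA=` INFO tag; VCF positions
#' (1-based) are converted to 0-based internally.
#'
#' @param path TSV or VCF file.
#' @return list with `variants` (data frame: `id`, `chrom`, `pos` (0-based),
#'   `opening_allele`) and `dosages` (variants x samples integer matrix).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) return(read_genotypes_vcf(path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "opening_allele")
  if (!all(need %in% names(tab))) {
    stop(sprintf("%s: genotype TSV must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  samples <- setdiff(names(tab), need)
  dos <- as.matrix(tab[, samples, drop = FALSE])
  mode(dos) <- "integer"
  bad <- which(!is.na(dos) & !(dos %in% 0:2))
  if (length(bad)) {
    stop(sprintf("%s: dosage outside {0,1,2,NA} at variant %s",
                 path, tab$id[(bad[1] - 1L) %% nrow(dos) + 1L]), call. = FALSE)
  }
  rownames(dos) <- tab$id
  list(variants = data.frame(id = tab$id, chrom = tab$chrom, pos = as.integer(tab$pos),
                             opening_allele = tab$opening_allele, stringsAsFactors = FALSE),
       dosages = dos)
}

read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop(sprintf("%s: no #CHROM header line", path), call. = FALSE)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body) & !grepl("^#", body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- length(fields)
  variants <- data.frame(id = character(n), chrom = character(n), pos = integer(n),
                         opening_allele = character(n), stringsAsFactors = FALSE)
  dos <- matrix(NA_integer_, n, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    f <- fields[[i]]
    variants$chrom[i] <- f[1]
    variants$pos[i] <- as.integer(f[2]) - 1L  # VCF is 1-based
    variants$id[i] <- f[3]
    info <- f[8]
    oa <- sub(".*OA=([^;]+).*", "\\1", info)
    if (identical(oa, info)) {
      stop(sprintf("%s: variant %s: missing OA= opening-allele INFO tag", path, f[3]),
           call. = FALSE)
    }
    variants$opening_allele[i] <- oa
    opening_is_alt <- oa == f[5]
    gts <- sub(":.*", "", f[-(1:9)])
    alleles <- strsplit(gts, "[/|]")
    dos[i, ] <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_integer_)
      alt_count <- sum(a != "0")
      as.integer(if (opening_is_alt) alt_count else length(a) - alt_count)
    }, 0L)
  }
  rownames(dos) <- variants$id
  list(variants = variants, dosages = dos)
}

#' Write a genotype table as TSV
#' @param genotypes list as returned by [read_genotypes()].
#' @param path output path.
#' @export
write_genotypes <- function(genotypes, path) {
  tab <- cbind(genotypes$variants, as.data.frame(genotypes$dosages))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-base conservation track (bedGraph)
#' @param path bedGraph file (chrom, start, end, score). `.bw`/`.bigWig`
#'   input is accepted when the rtracklayer package is available.
#' @return data frame `chrom`, `start`, `end`, `score`.
#' @export
read_conservation <- function(path) {
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("bigWig input requires the rtracklayer package", call. = FALSE)
    }
    gr <- rtracklayer::import(path)
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      score = gr$score, stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "score"))
  check_intervals(tab$chrom, tab$start, tab$end, "conservation interval")
  tab
}

#' Write a conservation track as bedGraph
#' @param track data frame `chrom`, `start`, `end`, `score`.
#' @param path output path.
#' @export
write_conservation <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     format_sig(track$score)), path)
  invisible(path)
}

#' Read a TSS / gene annotation table
#'
#' TSV schema: `chrom`, `pos` (0-based TSS position), `strand`, `gene_id`,
#' `gene_type` for TSS rows, plus optional genomic-context rows in a second
#' file read by [read_contexts()].
#'
#' @param tss_path TSS TSV.
#' @param context_path optional context BED4 (chrom, start, end, label:
#'   promoter-TSS/exon/intron/TTS/UTR).
#' @return list with `tss` and `contexts` data frames (class `gene_annotation`).
#' @export
read_gene_annotation <- function(tss_path, context_path = NULL) {
  tss <- utils::read.delim(tss_path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "gene_id", "gene_type")
  if (!all(need %in% names(tss))) {
    stop(sprintf("%s: TSS table must have columns %s", tss_path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  contexts <- NULL
  if (!is.null(context_path)) {
    contexts <- utils::read.table(context_path, sep = "\t", stringsAsFactors = FALSE,
                                  col.names = c("chrom", "start", "end", "label"))
    check_intervals(contexts$chrom, contexts$start, contexts$end, "context")
  }
  ann <- list(tss = tss, contexts = contexts)
  class(ann) <- "gene_annotation"
  ann
}

#' Write a TSS annotation table
#' @param annotation `gene_annotation` object or its `tss` data frame.
#' @param tss_path output TSS TSV path.
#' @param context_path optional output context BED path.
#' @export
write_gene_annotation <- function(annotation, tss_path, context_path = NULL) {
  tss <- if (inherits(annotation, "gene_annotation")) annotation$tss else annotation
  utils::write.table(tss, tss_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(context_path) && !is.null(annotation$contexts)) {
    ctx <- annotation$contexts
    writeLines(sprintf("%s\t%d\t%d\t%s", ctx$chrom, ctx$start, ctx$end, ctx$label),
               context_path)
  }
  invisible(tss_path)
}

#' Write tabular records as TSV (floats at 6 significant digits)
#'
#' @param rows data frame.
#' @param path output path.
#' @return the path, invisibly. Round-trips through [read_table_tsv()]
#'   losslessly at 6 significant digits.
#' @export
write_table <- function(rows, path) {
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_sig(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path TSV path.
#' @return data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Fetch a genome subsequence (0-based half-open coordinates)
#' @param genome a named `Biostrings::DNAStringSet` (or path to a FASTA file).
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return uppercase character sequence.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  if (!chrom %in% names(genome)) {
    stop(sprintf("chromosome %s not in genome (have: %s)", chrom,
                 paste(names(genome), collapse = ", ")), call. = FALSE)
  }
  chrom_len <- length(genome[[chrom]])
  if (end > chrom_len) {
    stop(sprintf("interval %s:[%d,%d) beyond chromosome end (%d)", chrom, start, end,
                 chrom_len), call. = FALSE)
  }
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end)))
}

#' Load a FASTA genome
#' @param path FASTA file.
#' @return named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*", "", names(genome))
  genome
}
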