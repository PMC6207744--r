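# Internal helpers shared across modules.

#' Derive a reproducible child seed
#'
#' All randomness in the package flows from a single user seed; submodules
#' receive deterministic child seeds so any sub-fixture can be regenerated in
#' isolation. The derivation is a simple multiplicative hash kept below 2^31.
#'
#' @param seed integer master seed.
#' @param index integer stream index (>= 0).
#' @return an integer usable with [set.seed()].
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  # 2^31 - 1 is prime (Mersenne), giving well-mixed, collision-poor streams
  as.integer((abs(seed) * 48271 + index * 16807 + 12345) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Validate a set of genomic intervals (0-based half-open)
#' @noRd
check_intervals <- function(chrom, start, end, what = "interval") {
  bad <- which(is.na(chrom) | !nzchar(chrom))
  if (length(bad)) stop(sprintf("%s %d: empty chromosome name", what, bad[1]), call. = FALSE)
  bad <- which(start < 0)
  if (length(bad)) stop(sprintf("%s %d: negative start", what, bad[1]), call. = FALSE)
  bad <- which(end <= start)
  if (length(bad)) {
    stop(sprintf("%s %d: end (%d) <= start (%d)", what, bad[1], end[bad[1]], start[bad[1]]),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Convert 0-based half-open intervals to an IRanges (1-based closed) object.
as_iranges0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# Overlap of two 0-based half-open interval sets, grouped by chromosome.
# Returns a two-column matrix of (query index, subject index) pairs.
overlap_pairs <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- vector("list", 0L)
  for (chr in unique(q_chrom)) {
    qi <- which(q_chrom == chr)
    si <- which(s_chrom == chr)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(as_iranges0(q_start[qi], q_end[qi]),
                                  as_iranges0(s_start[si], s_end[si]))
    if (length(hits)) {
      out[[length(out) + 1L]] <- cbind(qi[S4Vectors::queryHits(hits)],
                                       si[S4Vectors::subjectHits(hits)])
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 2L))
  do.call(rbind, out)
}

# Significant-digit formatting used by write_table(); 6 s.f., plain notation.
format_sig <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(signif(x, digits), digits = digits, format = "g"))
}
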