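#' Trim the 3' sequencing adapter from one read
#'
#' Scans the read left to right for the leftmost position at which a prefix
#' of the adapter matches the remainder of the read (or its suffix, when the
#' read ends inside the adapter) with at least `min_overlap` aligned bases
#' and a mismatch fraction of at most `max_mismatch_rate`. Everything from
#' that position on is removed. Reads shorter than `min_length` after
#' trimming are flagged as discarded.
#'
#' @param sequence read sequence (ACGTN).
#' @param adapter adapter sequence, default the Illumina small-RNA adapter
#'   `TCGTATGCCGTCTTCTGCTTGT`.
#' @param min_overlap minimum aligned adapter bases for a hit (default 6).
#' @param max_mismatch_rate maximum mismatches per aligned base (default 0.1).
#' @param min_length minimum kept length after trimming (default 18).
#' @return list with `trimmed` (sequence prefix kept), `trimmed_length`,
#'   `adapter_found` and `kept`.
#' @export
trim_adapter <- function(sequence,
                         adapter = "TCGTATGCCGTCTTCTGCTTGT",
                         min_overlap = 6L, max_mismatch_rate = 0.1,
                         min_length = 18L) {
  stopifnot(nchar(adapter) >= 1, min_length >= 1)
  assert_dna(sequence, "read")
  assert_dna(adapter, "adapter", allow_n = FALSE)
  L <- nchar(sequence)
  alen <- nchar(adapter)
  cut <- L + 1L
  if (L >= min_overlap) {
    rseq <- charToRaw(sequence)
    radp <- charToRaw(adapter)
    for (i in seq_len(L - min_overlap + 1L)) {
      ov <- min(alen, L - i + 1L)
      mm <- sum(rseq[i:(i + ov - 1L)] != radp[seq_len(ov)])
      if (mm <= max_mismatch_rate * ov) {
        cut <- i
        break
      }
    }
  }
  found <- cut <= L
  trimmed <- if (found) substr(sequence, 1L, cut - 1L) else sequence
  list(trimmed = trimmed, trimmed_length = nchar(trimmed),
       adapter_found = found, kept = nchar(trimmed) >= min_length)
}

#' Trim the adapter from a batch of reads
#'
#' Vectorised batch engine with the same semantics as [trim_adapter()]:
#' internal full-length adapter occurrences are located with
#' [Biostrings::vmatchPattern()] under the per-window mismatch allowance,
#' partial adapter prefixes at the read end with
#' [Biostrings::trimLRPatterns()], and the leftmost qualifying hit wins.
#'
#' @param reads data.frame with `read_id` and `sequence` (quality optional),
#'   or a character vector of sequences.
#' @inheritParams trim_adapter
#' @return data.table: read_id, sequence, trimmed, trimmed_length,
#'   adapter_found, kept.
#' @export
trim_reads <- function(reads,
                       adapter = "TCGTATGCCGTCTTCTGCTTGT",
                       min_overlap = 6L, max_mismatch_rate = 0.1,
                       min_length = 18L) {
  if (is.character(reads))
    reads <- data.table::data.table(
      read_id = sprintf("read%d", seq_along(reads)), sequence = reads)
  seqs <- reads$sequence
  assert_dna(seqs, "read")
  n <- length(seqs)
  alen <- nchar(adapter)
  out <- data.table::data.table(read_id = reads$read_id, sequence = seqs)
  if (n == 0L) {
    out[, `:=`(trimmed = character(0), trimmed_length = integer(0),
               adapter_found = logical(0), kept = logical(0))]
    return(out[])
  }
  dss <- Biostrings::DNAStringSet(seqs)

  # internal full-adapter occurrences (leftmost start per read)
  full_mm <- floor(max_mismatch_rate * alen)
  hits <- Biostrings::vmatchPattern(adapter, dss, max.mismatch = full_mm)
  first_full <- vapply(Biostrings::startIndex(hits), function(s)
    if (is.null(s)) NA_integer_ else min(s), integer(1))

  # partial adapter prefix at the read end; overlaps below min_overlap are
  # disabled with a negative allowance
  allow <- floor(max_mismatch_rate * seq_len(alen))
  if (min_overlap > 1L) allow[seq_len(min(min_overlap - 1L, alen))] <- -1
  kept_rng <- Biostrings::trimLRPatterns(Rpattern = adapter, subject = dss,
                                         max.Rmismatch = allow, ranges = TRUE)
  suffix_cut <- ifelse(IRanges::end(kept_rng) < nchar(seqs),
                       IRanges::end(kept_rng) + 1L, NA_integer_)

  cut <- pmin(first_full, suffix_cut, na.rm = TRUE)
  found <- !is.na(cut)
  trimmed <- seqs
  trimmed[found] <- substr(seqs[found], 1L, cut[found] - 1L)
  out[, trimmed := trimmed]
  out[, trimmed_length := nchar(trimmed)]
  out[, adapter_found := found]
  out[, kept := trimmed_length >= min_length]
  out[]
}

#' Read-length histogram of kept trimmed reads
#'
#' @param trimmed a [trim_reads()] result (or any data.frame with
#'   `trimmed_length` and `kept`).
#' @param range lengths reported individually; shorter/longer kept reads go
#'   into `"<18"` / `">26"` bins.
#' @return named integer vector of counts; sums to the number of kept reads.
#' @export
length_histogram <- function(trimmed, range = c(18L, 26L)) {
  len <- trimmed$trimmed_length[trimmed$kept]
  if (!length(len)) return(stats::setNames(integer(0), character(0)))
  bins <- as.character(seq(range[1], range[2]))
  lab <- ifelse(len < range[1], paste0("<", range[1]),
                ifelse(len > range[2], paste0(">", range[2]),
                       as.character(len)))
  tab <- table(factor(lab, levels = c(paste0("<", range[1]), bins,
                                      paste0(">", range[2]))))
  out <- stats::setNames(as.integer(tab), names(tab))
  out[out > 0]
}

#' Library size N
#'
#' The number of reads kept after adapter trimming and the minimum-length
#' filter. This pre-mapping definition of N is the denominator of all CPM
#' values downstream; reads longer than 26 nt still count in N even though
#' the assignment length rule excludes them from miRNA counting.
#'
#' @param trimmed a [trim_reads()] result.
#' @return integer N.
#' @export
library_size <- function(trimmed) {
  sum(trimmed$kept)
}
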