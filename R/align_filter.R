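#' Exhaustive toy aligner
#'
#' Reports, for every read, every ungapped placement on either strand of the
#' genome with at most `max_mismatches` substitutions. Exhaustive by
#' construction (a sliding position-by-position scan), it stands in for an
#' external all-alignments aligner at desk scale.
#'
#' @param reads named character vector of read sequences (names are read
#'   ids), or a data.frame with `read_id` and `seq`.
#' @param genome named character vector of contig sequences.
#' @param max_mismatches maximum substitutions per placement.
#' @return alignment data.table: read_id, reference, strand, start0
#'   (0-based half-open), seq (read orientation), mismatches.
#' @export
toy_align <- function(reads, genome, max_mismatches = 0L) {
  stopifnot(max_mismatches >= 0)
  if (is.data.frame(reads)) reads <- stats::setNames(reads$seq, reads$read_id)
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  graw <- lapply(genome, charToRaw)
  res <- vector("list", 0L)
  uniq <- !duplicated(reads)
  hit_cache <- new.env(parent = emptyenv())

  scan_one <- function(seq) {
    key <- seq
    if (!is.null(hit_cache[[key]])) return(hit_cache[[key]])
    out <- list()
    for (ctg in names(genome)) {
      g <- graw[[ctg]]
      N <- length(g)
      for (strand in c("+", "-")) {
        s <- if (strand == "+") seq else revcomp(seq)
        r <- charToRaw(s)
        L <- length(r)
        if (L > N) next
        P <- N - L + 1L
        mm <- integer(P)
        for (j in seq_len(L)) {
          mm <- mm + (g[j:(j + P - 1L)] != r[j])
        }
        pos <- which(mm <= max_mismatches)
        if (length(pos)) {
          out[[length(out) + 1L]] <- data.table::data.table(
            reference = ctg, strand = strand, start0 = pos - 1L,
            mismatches = mm[pos])
        }
      }
    }
    val <- if (length(out)) data.table::rbindlist(out) else
      data.table::data.table(reference = character(0), strand = character(0),
                             start0 = integer(0), mismatches = integer(0))
    hit_cache[[key]] <- val
    val
  }

  res <- lapply(seq_along(reads), function(i) {
    hits <- scan_one(reads[[i]])
    if (!nrow(hits)) return(NULL)
    data.table::data.table(read_id = names(reads)[i],
                           reference = hits$reference, strand = hits$strand,
                           start0 = hits$start0, seq = reads[[i]],
                           mismatches = hits$mismatches)
  })
  out <- data.table::rbindlist(res)
  if (!nrow(out))
    out <- data.table::data.table(read_id = character(0),
                                  reference = character(0),
                                  strand = character(0), start0 = integer(0),
                                  seq = character(0), mismatches = integer(0))
  data.table::setorder(out, read_id, reference, start0, strand)
  out[]
}

#' Mismatch count of a SAM record from its NM or MD tag
#'
#' Returns `NM` when present, otherwise the number of substituted reference
#' bases parsed from the `MD` string (single reference letters; `^`-prefixed
#' runs are deletions and, like any gapped record, are rejected upstream).
#' Records carrying neither tag are unscorable (`NA`).
#'
#' @param nm value of the `NM:i:` tag, or `NA`.
#' @param md value of the `MD:Z:` tag, or `NA`.
#' @return integer mismatch count, or `NA_integer_` if unscorable.
#' @export
count_mismatches <- function(nm = NA, md = NA) {
  if (!is.na(nm) && nzchar(nm)) return(as.integer(nm))
  if (is.na(md) || !nzchar(md)) return(NA_integer_)
  if (grepl("\\^", md))
    stop("MD tag '", md, "' contains a deletion; gapped records are not ",
         "supported", call. = FALSE)
  sum(gregexpr("[ACGTN]", md)[[1]] > 0L)
}

#' Retain only minimum-mismatch alignments per read
#'
#' For each read, the minimum mismatch count over all its reported
#' alignments defines its best stratum; exactly the alignments at that
#' stratum are retained. Identical placements (same read, reference, strand
#' and start) are collapsed to one, with the number collapsed recorded in
#' the `"deduplicated"` attribute.
#'
#' @param alignments alignment data.frame (all alignments of a read
#'   presented together).
#' @return filtered alignment data.table (attribute `deduplicated` gives the
#'   number of duplicate placements dropped).
#' @export
min_mismatch_filter <- function(alignments) {
  aln <- data.table::as.data.table(alignments)
  if (!nrow(aln)) {
    data.table::setattr(aln, "deduplicated", 0L)
    return(aln[])
  }
  n0 <- nrow(aln)
  aln <- unique(aln, by = c("read_id", "reference", "strand", "start0"))
  ndup <- n0 - nrow(aln)
  aln[, .__kmin := min(mismatches), by = read_id]
  out <- aln[mismatches == .__kmin][, .__kmin := NULL]
  data.table::setattr(out, "deduplicated", ndup)
  out[]
}
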