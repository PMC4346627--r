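#' Assign retained tags to mature miRNAs by the 5' start window
#'
#' A tag of length 18-26 nt is assigned to every mature miRNA on the same
#' chromosome and strand whose annotated 5' start lies within `window`
#' nucleotides of the tag's strand-aware 5' start (closed window, default
#' +/- 3). The offset is reported in transcript orientation: positive when
#' the tag 5' end lies downstream (inside) of the mature 5' end. Tags of
#' other lengths are not assigned. Identically named annotation records
#' (the same mature annotated at several loci) yield one assignment per
#' (read, locus) but are collapsed by name before counting.
#'
#' @param alignments alignment data.frame (post [min_mismatch_filter()]).
#' @param annotation annotation data.frame from [read_annotation()] or a
#'   `mirtail_reference`.
#' @param window half-width of the closed 5' start window (default 3).
#' @param len_range inclusive tag length range admitted (default 18-26).
#' @return assignment data.table: read_id, mirna_name, offset5, tag_length,
#'   seq, n_assignments (per read), weight (1 / n_assignments).
#' @export
assign_tags <- function(alignments, annotation, window = 3L,
                        len_range = c(18L, 26L)) {
  if (inherits(annotation, "mirtail_reference"))
    annotation <- annotation$annotation
  aln <- data.table::as.data.table(alignments)
  ann <- data.table::as.data.table(annotation)
  empty <- data.table::data.table(
    read_id = character(0), mirna_name = character(0), offset5 = integer(0),
    tag_length = integer(0), seq = character(0), n_assignments = integer(0),
    weight = numeric(0))
  if (!nrow(aln) || !nrow(ann)) return(empty)

  aln <- aln[, list(read_id, reference, strand, start0, seq,
                    tag_length = nchar(seq))]
  aln <- aln[tag_length >= len_range[1] & tag_length <= len_range[2]]
  if (!nrow(aln)) return(empty)
  # strand-aware genomic 5' coordinate of the tag
  aln[, tag5 := ifelse(strand == "+", start0, start0 + tag_length - 1L)]

  hits <- merge(aln,
                ann[, list(mirna_name = name, reference = chr, strand, five0)],
                by = c("reference", "strand"), allow.cartesian = TRUE)
  if (!nrow(hits)) return(empty)
  hits[, offset5 := ifelse(strand == "+", tag5 - five0, five0 - tag5)]
  hits <- hits[abs(offset5) <= window]
  if (!nrow(hits)) return(empty)
  hits <- unique(hits[, list(read_id, mirna_name, offset5, tag_length, seq)])
  hits[, n_assignments := .N, by = read_id]
  hits[, weight := 1 / n_assignments]
  data.table::setorder(hits, read_id, mirna_name)
  hits[]
}

#' Raw and CPM-normalised count table
#'
#' Counts assigned tags per mature miRNA and normalises by the library size:
#' `cpm = n * 1e6 / N`. A read with several retained assignments
#' contributes total weight 1, split equally across them (`weighting =
#' "fractional"`); `weighting = "unique"` counts only uniquely assigned
#' reads.
#'
#' @param assignments an [assign_tags()] result.
#' @param N library size from [library_size()] (kept reads, pre-mapping).
#' @param sample sample label stored in the table.
#' @param weighting `"fractional"` (default) or `"unique"`.
#' @return count data.table: mirna_name, sample, n, N, cpm.
#' @export
build_count_table <- function(assignments, N, sample = "sample1",
                              weighting = c("fractional", "unique")) {
  weighting <- match.arg(weighting)
  a <- data.table::as.data.table(assignments)
  if (nrow(a) && N <= 0)
    stop("library size N must be positive when assignments exist",
         call. = FALSE)
  if (weighting == "unique") a <- a[n_assignments == 1L]
  tab <- a[, list(n = sum(weight)), by = mirna_name]
  tab[, `:=`(sample = sample, N = as.integer(N), cpm = n * 1e6 / N)]
  data.table::setcolorder(tab, c("mirna_name", "sample", "n", "N", "cpm"))
  data.table::setorder(tab, mirna_name)
  tab[]
}

#' Per-miRNA CPM ratio between two conditions
#'
#' @param table1 count table of the reference condition (denominator).
#' @param table2 count table of the comparison condition (numerator).
#' @return data.table: mirna_name, cpm_1, cpm_2, ratio (NA and
#'   `defined = FALSE` when the denominator CPM is 0).
#' @export
expression_compare <- function(table1, table2) {
  t1 <- data.table::as.data.table(table1)[, list(mirna_name, cpm_1 = cpm)]
  t2 <- data.table::as.data.table(table2)[, list(mirna_name, cpm_2 = cpm)]
  out <- merge(t1, t2, by = "mirna_name", all = TRUE)
  out[is.na(cpm_1), cpm_1 := 0]
  out[is.na(cpm_2), cpm_2 := 0]
  out[, defined := cpm_1 > 0]
  out[, ratio := ifelse(defined, cpm_2 / cpm_1, NA_real_)]
  data.table::setorder(out, mirna_name)
  out[]
}
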