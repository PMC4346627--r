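#' Write the toy reference to disk
#'
#' Writes the genome as FASTA, the mature annotation as GFF3 (1-based,
#' closed intervals, `Name=` attribute) and the mature sequences as FASTA.
#'
#' @param reference a [build_toy_reference()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "mirtail_reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome_fa <- file.path(dir, "genome.fa")
  gff3 <- file.path(dir, "mirnas.gff3")
  mature_fa <- file.path(dir, "mature.fa")

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference$genome), genome_fa)

  ann <- reference$annotation
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chr,
    ranges = IRanges::IRanges(start = ann$start0 + 1L, end = ann$end0),
    strand = ann$strand)
  gr$type <- "miRNA"
  gr$Name <- ann$name
  gr$ID <- ann$name
  rtracklayer::export(gr, gff3, format = "gff3")

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(ann$mature_seq, ann$name)),
    mature_fa)

  invisible(c(genome = genome_fa, annotation = gff3, mature = mature_fa))
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  stats::setNames(as.character(dss), names(dss))
}

#' Read a miRBase-style mature annotation (GFF3) against a genome
#'
#' Converts 1-based closed GFF3 intervals to the package's internal 0-based
#' half-open convention, derives the genomic 5' coordinate from the strand,
#' and extracts from the genome the mature sequence plus the +1 downstream
#' base needed for templated/non-templated classification. An annotation
#' chromosome missing from the genome is a configuration error.
#'
#' @param path GFF3 file with a `Name` attribute per mature miRNA.
#' @param genome named character vector (from [read_genome()]) or FASTA path.
#' @return annotation data.frame (name, chr, strand, start0, end0, five0,
#'   length, mature_seq, ext_seq, plus_one_base).
#' @export
read_annotation <- function(path, genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome(genome)
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- if (!is.null(gr$Name)) gr$Name else gr$ID
  if (is.null(nm)) stop("GFF3 records lack Name/ID attributes", call. = FALSE)
  ann <- data.frame(name = as.character(nm),
                    chr = as.character(GenomicRanges::seqnames(gr)),
                    strand = as.character(GenomicRanges::strand(gr)),
                    start0 = GenomicRanges::start(gr) - 1L,
                    end0 = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (any(!ann$strand %in% c("+", "-")))
    stop("annotation records must be stranded", call. = FALSE)
  ann$length <- ann$end0 - ann$start0
  ann$five0 <- ifelse(ann$strand == "+", ann$start0, ann$end0 - 1L)
  annotate_context(ann, genome)
}

#' Write reads as FASTQ (Phred+33)
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(stats::setNames(reads$sequence,
                                                  reads$read_id))
  qual <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ path.
#' @return data.table with read_id, sequence, quality.
#' @export
read_fastq <- function(path) {
  q <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.table::data.table(
    read_id = sub("\\s.*$", "", names(q)),
    sequence = as.character(q),
    quality = as.character(S4Vectors::mcols(q)$qualities))
}

#' Write alignments as a SAM text file
#'
#' Minus-strand alignments are stored reverse-complemented with flag 16 set,
#' per the SAM convention; mismatch counts go into the `NM` tag.
#'
#' @param alignments alignment data.frame (read orientation `seq`).
#' @param genome named character vector of contigs (for `@SQ` headers).
#' @param path output path.
#' @export
write_sam <- function(alignments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  seq_fwd <- alignments$seq
  minus <- alignments$strand == "-"
  if (any(minus)) seq_fwd[minus] <- revcomp(seq_fwd[minus])
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                 alignments$read_id, flag, alignments$reference,
                 alignments$start0 + 1L, nchar(alignments$seq), seq_fwd,
                 alignments$mismatches)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM text file into an alignment table
#'
#' Parses mapped, ungapped records. Mismatch counts come from the `NM` tag
#' when present, otherwise from the `MD` tag ([count_mismatches()]).
#' Indel-containing records (I/D/N in CIGAR) are dropped with a count, as
#' are records carrying neither `NM` nor `MD` (unscorable).
#'
#' @param path SAM file.
#' @return alignment data.table (seq in read orientation) with attributes
#'   `dropped_indel` and `dropped_unscorable`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- data.table::data.table(
    read_id = character(0), reference = character(0), strand = character(0),
    start0 = integer(0), seq = character(0), mismatches = integer(0))
  if (!length(lines)) {
    data.table::setattr(empty, "dropped_indel", 0L)
    data.table::setattr(empty, "dropped_unscorable", 0L)
    return(empty)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  f <- f[mapped]; flag <- flag[mapped]
  cigar <- vapply(f, `[`, character(1), 6L)
  gapped <- grepl("[IDNSHP]", cigar)
  n_indel <- sum(gapped)
  f <- f[!gapped]; flag <- flag[!gapped]

  get_tag <- function(x, tag) {
    if (length(x) < 12L) return(NA_character_)
    hit <- x[-(1:11)][startsWith(x[-(1:11)], tag)]
    if (!length(hit)) NA_character_ else sub(tag, "", hit[1], fixed = TRUE)
  }
  nm <- vapply(f, get_tag, character(1), tag = "NM:i:")
  md <- vapply(f, get_tag, character(1), tag = "MD:Z:")
  mism <- mapply(count_mismatches, nm = nm, md = md,
                 SIMPLIFY = TRUE, USE.NAMES = FALSE)
  unscorable <- is.na(mism)
  n_unsc <- sum(unscorable)
  f <- f[!unscorable]; flag <- flag[!unscorable]; mism <- mism[!unscorable]

  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  seq_fwd <- vapply(f, `[`, character(1), 10L)
  seq_read <- seq_fwd
  minus <- strand == "-"
  if (any(minus)) seq_read[minus] <- revcomp(seq_fwd[minus])
  out <- data.table::data.table(
    read_id = vapply(f, `[`, character(1), 1L),
    reference = vapply(f, `[`, character(1), 3L),
    strand = strand,
    start0 = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
    seq = seq_read,
    mismatches = as.integer(mism))
  data.table::setattr(out, "dropped_indel", n_indel)
  data.table::setattr(out, "dropped_unscorable", n_unsc)
  out
}

#' Write a data frame as a tab-separated file
#' @param x data.frame.
#' @param path output path.
#' @param comments optional character vector written as leading `# ` lines.
#' @export
write_tsv <- function(x, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
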