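#' Simulation configuration for the toy small-RNA experiment
#'
#' Builds and validates the configuration object consumed by
#' [build_toy_reference()] and [simulate_reads()]. The generator emulates a
#' two-condition small-RNA library: per-miRNA abundances, 5' start offsets in
#' \[-3, +3\], +1 nt 3' tails that are either templated (the appended base
#' matches the genome immediately downstream of the mature 3' end) or
#' non-templated (A/C/G/U differing from that genome base), sequencing
#' errors, a ligated 3' sequencing adapter, and optional rRNA decoy contigs.
#'
#' @param n_mirnas number of mature miRNA loci to place on the toy genome.
#' @param genome_length length (nt) of the main toy chromosome. Must be large
#'   enough to hold all loci without overlap.
#' @param conditions character vector of condition labels (two by default).
#' @param mean_abundance expected read count per miRNA and condition. A
#'   scalar, a vector of length `n_mirnas`, or an
#'   `n_mirnas x length(conditions)` matrix.
#' @param tail_probs probabilities of the 3'-end classes
#'   `none`, `templated`, `A`, `C`, `G`, `U` (RNA labels; the generator
#'   appends the corresponding DNA base). Either a named numeric vector used
#'   for every miRNA and condition, a named list with one vector per
#'   condition, or a list of `n_mirnas x 6` matrices per condition. Each
#'   6-class distribution must sum to 1.
#' @param offset_probs named probabilities over 5' offsets `-3 ... 3`.
#' @param error_rate per-read probability of carrying one random substitution
#'   (see the package vignette for the rationale of a per-read rather than
#'   per-base rate).
#' @param adapter 3' sequencing adapter appended to every insert.
#' @param decoy_fraction expected fraction of reads originating from rRNA
#'   decoy contigs rather than miRNA loci.
#' @param mature_len_range inclusive range of mature miRNA lengths; the
#'   default \[20, 23\] keeps tag lengths within \[18, 26\] after offsets and
#'   +1 tails.
#' @param seed integer seed; the single source of randomness for a run.
#'   Per-miRNA sub-streams are derived deterministically so adding miRNAs
#'   does not perturb existing ones.
#' @return an object of class `mirtail_sim_config`.
#' @export
sim_config <- function(n_mirnas = 20,
                       genome_length = 20000,
                       conditions = c("wt", "mut"),
                       mean_abundance = 1000,
                       tail_probs = c(none = 0.80, templated = 0.02,
                                      A = 0.07, C = 0.01, G = 0.01, U = 0.09),
                       offset_probs = c(`-3` = 0.01, `-2` = 0.02, `-1` = 0.07,
                                        `0` = 0.80, `1` = 0.07, `2` = 0.02,
                                        `3` = 0.01),
                       error_rate = 0,
                       adapter = "TCGTATGCCGTCTTCTGCTTGT",
                       decoy_fraction = 0,
                       mature_len_range = c(20L, 23L),
                       seed = 1L) {
  stopifnot(n_mirnas >= 1, genome_length >= 1, length(conditions) >= 1)
  n_cond <- length(conditions)

  abund <- mean_abundance
  if (is.null(dim(abund))) {
    if (length(abund) == 1L) abund <- rep(abund, n_mirnas)
    if (length(abund) != n_mirnas)
      stop("mean_abundance must be scalar, length n_mirnas, or a matrix",
           call. = FALSE)
    abund <- matrix(abund, nrow = n_mirnas, ncol = n_cond)
  }
  if (!all(dim(abund) == c(n_mirnas, n_cond)) || any(abund <= 0))
    stop("mean_abundance matrix must be n_mirnas x n_conditions, positive",
         call. = FALSE)
  colnames(abund) <- conditions

  classes <- c("none", "templated", "A", "C", "G", "U")
  norm_tail <- function(tp) {
    if (is.null(dim(tp))) {
      if (!all(classes %in% names(tp)))
        stop("tail_probs must name the classes ", paste(classes, collapse = ", "),
             call. = FALSE)
      tp <- matrix(rep(tp[classes], each = n_mirnas), nrow = n_mirnas,
                   dimnames = list(NULL, classes))
    } else {
      tp <- tp[, classes, drop = FALSE]
      if (nrow(tp) != n_mirnas)
        stop("per-miRNA tail_probs matrix must have n_mirnas rows", call. = FALSE)
    }
    if (any(tp < 0) || any(tp > 1))
      stop("tail probabilities must lie in [0, 1]", call. = FALSE)
    bad <- abs(rowSums(tp) - 1) > 1e-8
    if (any(bad))
      stop("tail-class probabilities must sum to 1 (miRNA row ",
           which(bad)[1], " sums to ", rowSums(tp)[which(bad)[1]], ")",
           call. = FALSE)
    tp
  }
  if (!is.list(tail_probs)) {
    tail_probs <- stats::setNames(rep(list(tail_probs), n_cond), conditions)
  }
  if (!all(conditions %in% names(tail_probs)))
    stop("tail_probs list must be named by condition", call. = FALSE)
  tail_probs <- lapply(tail_probs[conditions], norm_tail)

  off_names <- as.character(-3:3)
  if (!all(off_names %in% names(offset_probs)))
    stop("offset_probs must be named '-3' ... '3'", call. = FALSE)
  offset_probs <- offset_probs[off_names]
  if (any(offset_probs < 0) || abs(sum(offset_probs) - 1) > 1e-8)
    stop("offset probabilities must be non-negative and sum to 1", call. = FALSE)

  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must lie in [0, 1)", call. = FALSE)
  if (decoy_fraction < 0 || decoy_fraction >= 1)
    stop("decoy_fraction must lie in [0, 1)", call. = FALSE)
  assert_dna(adapter, "adapter", allow_n = FALSE)
  stopifnot(length(mature_len_range) == 2,
            mature_len_range[1] >= 18, mature_len_range[2] <= 26,
            mature_len_range[1] <= mature_len_range[2])

  structure(list(n_mirnas = as.integer(n_mirnas),
                 genome_length = as.integer(genome_length),
                 conditions = conditions,
                 mean_abundance = abund,
                 tail_probs = tail_probs,
                 offset_probs = offset_probs,
                 error_rate = error_rate,
                 adapter = adapter,
                 decoy_fraction = decoy_fraction,
                 mature_len_range = as.integer(mature_len_range),
                 seed = as.integer(seed)),
            class = "mirtail_sim_config")
}

# Mature-sequence / +1-base context for an annotation table.  ext_seq is the
# transcript-orientation genomic sequence spanning 5' offsets -3..0, the
# mature body, and one downstream base (the base that decides "templated").
annotate_context <- function(ann, genome) {
  missing_chr <- setdiff(unique(ann$chr), names(genome))
  if (length(missing_chr))
    stop("annotation chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  n <- nrow(ann)
  mature <- character(n); ext <- character(n)
  for (i in seq_len(n)) {
    g <- genome[[ann$chr[i]]]
    len <- ann$length[i]
    if (ann$strand[i] == "+") {
      s <- ann$start0[i]
      if (s < 3L || s + len + 1L > nchar(g))
        stop("locus ", ann$name[i], " too close to a contig edge", call. = FALSE)
      mature[i] <- substr(g, s + 1L, s + len)
      ext[i] <- substr(g, s - 2L, s + len + 1L)
    } else {
      s <- ann$start0[i]
      if (s < 1L || s + len + 3L > nchar(g))
        stop("locus ", ann$name[i], " too close to a contig edge", call. = FALSE)
      mature[i] <- revcomp(substr(g, s + 1L, s + len))
      ext[i] <- revcomp(substr(g, s, s + len + 3L))
    }
  }
  ann$mature_seq <- mature
  ann$ext_seq <- ext
  ann$plus_one_base <- substr(ext, ann$length + 4L, ann$length + 4L)
  ann
}

#' Build a toy genome and miRBase-style mature-miRNA annotation
#'
#' Places `n_mirnas` non-overlapping mature miRNA loci on a random genome,
#' alternating strands, and records for each locus the mature sequence and
#' the genome base immediately downstream of the mature 3' end (which
#' determines which +1 tail nucleotide is templated). Mature sequences are
#' embedded directly in the genome; no precursor hairpin is modelled because
#' nothing downstream of the annotation needs one.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `mirtail_reference`: a list with `genome`
#'   (named character vector of contig sequences), `annotation` (data.frame
#'   with 0-based half-open coordinates, mature sequence, and +1 context)
#'   and the originating `config`.
#' @export
build_toy_reference <- function(config) {
  stopifnot(inherits(config, "mirtail_sim_config"))
  set.seed(substream_seed(config$seed, 0L, salt = 1L))

  n <- config$n_mirnas
  L <- config$genome_length
  max_len <- config$mature_len_range[2]
  slot <- (L - 8L) %/% n
  if (slot < max_len + 12L)
    stop("configuration error: genome_length ", L,
         " cannot hold ", n, " non-overlapping loci", call. = FALSE)

  genome <- c(chr1 = random_dna(1, L))
  if (config$decoy_fraction > 0) {
    genome <- c(genome, rRNA_18S = random_dna(1, 600L),
                rRNA_28S = random_dna(1, 800L))
  }

  lens <- sample(seq(config$mature_len_range[1], config$mature_len_range[2]),
                 n, replace = TRUE)
  strands <- rep(c("+", "-"), length.out = n)
  starts <- integer(n)
  for (i in seq_len(n)) {
    lo <- 4L + (i - 1L) * slot
    hi <- lo + slot - lens[i] - 8L
    starts[i] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  }
  ann <- data.frame(name = sprintf("mir-%03d", seq_len(n)),
                    chr = "chr1",
                    strand = strands,
                    start0 = starts,
                    end0 = starts + lens,
                    length = lens,
                    stringsAsFactors = FALSE)
  ann$five0 <- ifelse(ann$strand == "+", ann$start0, ann$end0 - 1L)
  ann <- annotate_context(ann, genome)

  structure(list(genome = genome, annotation = ann, config = config),
            class = "mirtail_reference")
}

#' Simulate two-condition small-RNA read sets with ground truth
#'
#' For each condition and miRNA, draws a Poisson read count around the
#' configured mean, then per read a 5' offset, a 3'-end class, and (with
#' probability `error_rate`) one random substitution. Each insert gets the
#' sequencing adapter appended. A non-templated class whose DNA base happens
#' to equal the genome +1 base is recorded as `templated` in the truth table
#' (the two are indistinguishable by definition). Optional rRNA decoy reads
#' are added at the configured fraction of the library.
#'
#' @param reference a [build_toy_reference()] result.
#' @param config the same [sim_config()]; defaults to the one stored in
#'   `reference`.
#' @return an object of class `mirtail_sim`: list with `reads` (data.table:
#'   read_id, condition, sequence incl. adapter, quality) and `truth`
#'   (data.table with per-read miRNA of origin, offset, tail class, insert
#'   sequence, injected error position, true placement and mismatch count).
#' @export
simulate_reads <- function(reference, config = reference$config) {
  stopifnot(inherits(reference, "mirtail_reference"),
            inherits(config, "mirtail_sim_config"))
  ann <- reference$annotation
  genome <- reference$genome
  classes <- c("none", "templated", "A", "C", "G", "U")

  per_mirna <- function(i, cond, cond_idx) {
    set.seed(substream_seed(config$seed, i, salt = 100L + cond_idx))
    count <- stats::rpois(1L, config$mean_abundance[i, cond])
    if (count == 0L) return(NULL)
    len <- ann$length[i]
    ext <- ann$ext_seq[i]
    plus1 <- ann$plus_one_base[i]

    off <- sample(-3:3, count, replace = TRUE, prob = config$offset_probs)
    cls <- sample(classes, count, replace = TRUE,
                  prob = config$tail_probs[[cond]][i, ])
    # an NTA draw equal to the templated base IS templated
    cls[cls %in% c("A", "C", "G", "U") &
          to_dna_base(cls) == plus1] <- "templated"

    bodies <- substring(ext, 4L + (-3:3), 3L + len)   # one per offset
    tail_base <- character(count)
    tail_base[cls == "templated"] <- plus1
    nta <- cls %in% c("A", "C", "G", "U")
    tail_base[nta] <- to_dna_base(cls[nta])
    insert <- paste0(bodies[off + 4L], tail_base)
    mism <- as.integer(nta)

    err_pos <- rep(NA_integer_, count)
    if (config$error_rate > 0) {
      hit <- which(stats::runif(count) < config$error_rate)
      for (j in hit) {
        p <- sample.int(nchar(insert[j]), 1L)
        old <- substr(insert[j], p, p)
        substr(insert[j], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
        err_pos[j] <- p - 1L
        ctx <- paste0(bodies[off[j] + 4L],
                      if (nchar(tail_base[j])) plus1 else "")
        mism[j] <- hamming(insert[j], ctx)
      }
    }

    ilen <- nchar(insert)
    if (ann$strand[i] == "+") {
      aln_start0 <- ann$five0[i] + off
    } else {
      aln_start0 <- ann$five0[i] - off - ilen + 1L
    }
    data.table::data.table(
      read_id = sprintf("%s_%s_r%05d", cond, ann$name[i], seq_len(count)),
      condition = cond, origin = "mirna", mirna_name = ann$name[i],
      offset5 = off, tail_class = cls, insert_seq = insert,
      insert_len = ilen, error_pos = err_pos,
      chrom = ann$chr[i], strand = ann$strand[i],
      aln_start0 = aln_start0, mismatches = mism)
  }

  truth <- data.table::rbindlist(
    lapply(seq_along(config$conditions), function(ci) {
      cond <- config$conditions[ci]
      data.table::rbindlist(
        lapply(seq_len(config$n_mirnas), per_mirna, cond = cond,
               cond_idx = ci))
    }))

  if (config$decoy_fraction > 0) {
    decoys <- grep("^rRNA", names(genome), value = TRUE)
    dec <- data.table::rbindlist(lapply(seq_along(config$conditions),
                                        function(ci) {
      cond <- config$conditions[ci]
      set.seed(substream_seed(config$seed, 0L, salt = 500L + ci))
      t_mirna <- sum(truth$condition == cond)
      planned <- round(t_mirna / (1 - config$decoy_fraction))
      n_dec <- stats::rbinom(1L, planned, config$decoy_fraction)
      if (n_dec == 0L) return(NULL)
      contig <- sample(decoys, n_dec, replace = TRUE)
      len <- sample(18:26, n_dec, replace = TRUE)
      strand <- sample(c("+", "-"), n_dec, replace = TRUE)
      start0 <- vapply(seq_len(n_dec), function(j)
        sample.int(nchar(genome[[contig[j]]]) - len[j], 1L) - 1L, integer(1))
      fwd <- substring(genome[contig], start0 + 1L, start0 + len)
      insert <- ifelse(strand == "+", fwd, revcomp(fwd))
      data.table::data.table(
        read_id = sprintf("%s_decoy_r%05d", cond, seq_len(n_dec)),
        condition = cond, origin = "decoy", mirna_name = NA_character_,
        offset5 = NA_integer_, tail_class = NA_character_,
        insert_seq = insert, insert_len = len, error_pos = NA_integer_,
        chrom = contig, strand = strand, aln_start0 = start0,
        mismatches = 0L)
    }))
    truth <- data.table::rbindlist(list(truth, dec))
  }

  reads <- truth[, list(read_id = read_id, condition = condition,
                        sequence = paste0(insert_seq, config$adapter))]
  reads[, quality := strrep("I", nchar(sequence))]
  structure(list(reads = reads, truth = truth, config = config,
                 reference = reference),
            class = "mirtail_sim")
}

#' Emit SAM-style alignments for simulated reads
#'
#' Produces one alignment per read at its true placement and, optionally,
#' every additional placement with at most `max_mismatches` substitutions
#' found by the exhaustive [toy_align()] scan (the desk-scale stand-in for
#' an external all-alignments aligner).
#'
#' @param sim a [simulate_reads()] result.
#' @param all_hits also report all other qualifying placements.
#' @param max_mismatches mismatch cap for the exhaustive scan.
#' @return alignment data.table (read_id, reference, strand, start0,
#'   seq in read orientation, mismatches).
#' @export
emit_sam <- function(sim, all_hits = FALSE, max_mismatches = 3L) {
  stopifnot(inherits(sim, "mirtail_sim"))
  aln <- sim$truth[, list(read_id = read_id, reference = chrom,
                          strand = strand, start0 = aln_start0,
                          seq = insert_seq, mismatches = mismatches)]
  if (all_hits) {
    reads <- stats::setNames(sim$truth$insert_seq, sim$truth$read_id)
    extra <- toy_align(reads, sim$reference$genome, max_mismatches)
    aln <- unique(data.table::rbindlist(list(aln, extra)))
  }
  data.table::setorder(aln, read_id, reference, start0, strand)
  aln[]
}
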