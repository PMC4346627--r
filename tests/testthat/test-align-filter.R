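# Independent exhaustive oracle for ungapped alignment, built on
# Biostrings pattern matching rather than the package's byte scan.
oracle_align <- function(seqs, genome, max_mm) {
  out <- list()
  for (ctg in names(genome)) {
    subject <- Biostrings::DNAString(genome[[ctg]])
    for (id in names(seqs)) {
      for (strand in c("+", "-")) {
        s <- if (strand == "+") seqs[[id]] else revcomp(seqs[[id]])
        hits <- Biostrings::matchPattern(s, subject, max.mismatch = max_mm,
                                         with.indels = FALSE)
        if (!length(hits)) next
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(s), subject,
                                          starting.at = BiocGenerics::start(hits),
                                          with.indels = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          read_id = id, reference = ctg, strand = strand,
          start0 = BiocGenerics::start(hits) - 1L, seq = seqs[[id]],
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$read_id, res$reference, res$start0, res$strand), ]
}

test_that("toy aligner equals an independent exhaustive scan", {
  set.seed(101)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 10000,
                                  replace = TRUE), collapse = ""))
  # half the reads are genuine genome substrings (some reverse-complemented,
  # some mutated), half random
  seqs <- character(200)
  for (i in 1:200) {
    len <- sample(18:26, 1)
    if (i <= 100) {
      s0 <- sample(10000 - len, 1)
      s <- substr(genome[[1]], s0, s0 + len - 1)
      if (i %% 2 == 0) s <- revcomp(s)
      if (i %% 3 == 0) {
        p <- sample(len, 1)
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
    } else {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    }
    seqs[i] <- s
  }
  names(seqs) <- sprintf("r%03d", 1:200)

  got <- as.data.frame(toy_align(seqs, genome, max_mismatches = 2L))
  want <- oracle_align(seqs, genome, max_mm = 2L)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("unique and duplicated substrings align the expected number of times", {
  genome <- c(chr1 = paste0("TTTTTTTTTT", "GACGGATCAGCCGCAAGCGGAA",
                            "TTTTTTTTTT"))
  one <- toy_align(c(r = "GACGGATCAGCCGCAAGCGGAA"), genome, 0L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$start0, 10L)
  expect_equal(one$mismatches, 0L)
  # a read longer than every contig simply does not align
  none <- toy_align(c(r = strrep("ACGT", 20)), genome, 3L)
  expect_equal(nrow(none), 0L)
})

test_that("mismatch counts come from NM, then MD, else unscorable", {
  expect_equal(count_mismatches(nm = "0"), 0L)
  expect_equal(count_mismatches(nm = "3"), 3L)
  expect_equal(count_mismatches(md = "10A11"), 1L)
  expect_equal(count_mismatches(md = "22"), 0L)
  expect_equal(count_mismatches(md = "0A4C3G1"), 3L)
  expect_true(is.na(count_mismatches()))
  expect_error(count_mismatches(md = "5^AC10"), "deletion")
})

test_that("minimum-mismatch retention keeps exactly the best stratum", {
  aln <- data.frame(
    read_id = c("a", "a", "a", "b", "b", "b", "c"),
    reference = "chr1", strand = "+",
    start0 = c(0L, 50L, 100L, 10L, 20L, 30L, 5L),
    seq = "ACGTACGTACGTACGTAC",
    mismatches = c(0L, 0L, 2L, 1L, 1L, 1L, 3L))
  kept <- min_mismatch_filter(aln)
  expect_equal(sum(kept$read_id == "a"), 2L)
  expect_true(all(kept$mismatches[kept$read_id == "a"] == 0L))
  expect_equal(sum(kept$read_id == "b"), 3L)
  expect_equal(sum(kept$read_id == "c"), 1L)

  # duplicated placements are collapsed and counted
  dup <- rbind(aln, aln[1, ])
  kept2 <- min_mismatch_filter(dup)
  expect_equal(attr(kept2, "deduplicated"), 1L)
  expect_equal(nrow(kept2), nrow(kept))
})

test_that("retention equals a group-by-then-min recomputation on random input", {
  set.seed(55)
  n <- 500
  aln <- data.frame(
    read_id = sprintf("r%02d", sample(40, n, replace = TRUE)),
    reference = sample(c("chr1", "chr2"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    start0 = sample(1000L, n, replace = TRUE),
    seq = "ACGTACGTACGTACGTACGTAC",
    mismatches = sample(0:3, n, replace = TRUE))
  aln <- aln[!duplicated(aln[c("read_id", "reference", "strand", "start0")]), ]
  kept <- as.data.frame(min_mismatch_filter(aln))

  kmin <- tapply(aln$mismatches, aln$read_id, min)
  want <- aln[aln$mismatches == kmin[aln$read_id], ]
  key <- function(d) sort(do.call(paste, d[c("read_id", "reference",
                                             "strand", "start0",
                                             "mismatches")]))
  expect_identical(key(kept), key(want))
  # every surviving read sits at a single mismatch level
  expect_true(all(tapply(kept$mismatches, kept$read_id,
                         function(x) length(unique(x))) == 1L))
})

test_that("exact alignments pass the filter unchanged and truth survives", {
  cfg <- small_config(seed = 31)
  ref <- build_toy_reference(cfg)
  sim <- simulate_reads(ref)
  aln <- emit_sam(sim, all_hits = TRUE, max_mismatches = 0L)
  kept <- min_mismatch_filter(aln)
  expect_equal(nrow(kept), nrow(unique(aln)))
  # error-free data: every read's true locus survives
  truth_key <- paste(sim$truth$read_id, sim$truth$chrom, sim$truth$strand,
                     sim$truth$aln_start0)
  kept_key <- paste(kept$read_id, kept$reference, kept$strand, kept$start0)
  expect_true(all(truth_key %in% kept_key))
})

test_that("SAM round-trip preserves alignments and rejects gapped records", {
  cfg <- small_config(seed = 37)
  ref <- build_toy_reference(cfg)
  sim <- simulate_reads(ref)
  aln <- emit_sam(sim)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, ref$genome, path)
  back <- read_sam(path)
  expect_equal(as.data.frame(back), as.data.frame(aln),
               ignore_attr = c("dropped_indel", "dropped_unscorable"))

  # gapped and unscorable records are dropped with counts
  lines <- readLines(path)
  lines <- c(lines,
             "gap1\t0\tchr1\t5\t255\t10M2D10M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*\tNM:i:2",
             "bare1\t0\tchr1\t5\t255\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*")
  writeLines(lines, path)
  back2 <- read_sam(path)
  expect_equal(attr(back2, "dropped_indel"), 1L)
  expect_equal(attr(back2, "dropped_unscorable"), 1L)
  expect_equal(nrow(back2), nrow(aln))
})
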