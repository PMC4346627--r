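#' @importFrom stats rpois rbinom runif median quantile setNames
#' @importFrom utils write.table read.delim head
#' @import data.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# RNA-space label for a DNA-space base (reads are sequenced as cDNA).
to_rna_base <- function(base) ifelse(base == "T", "U", base)
to_dna_base <- function(base) ifelse(base == "U", "T", base)

#' Reverse-complement a character vector of DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' keeps plain character vectors as the working currency of the pipeline.
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic sub-stream seed derivation: one pseudo-random stream per run,
# with per-unit sub-streams so adding units does not perturb existing ones.
# Kept strictly below 2^31 - 1 (R integer range).
substream_seed <- function(seed, index, salt = 0L) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + as.numeric(index) * 69621 + as.numeric(salt) * 16807 + 1) %% m
  as.integer(x)
}

# Uniform random DNA string(s).
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-%s characters (first offender: '%s')",
                 what, if (allow_n) "ACGTN" else "ACGT",
                 x[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}
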