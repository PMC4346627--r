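# Shared fixtures for the test suite: small simulation configs and the
# map from classifier labels back to generator truth labels.

CLASS_TO_TRUTH <- c(exact_mature = "none", templated_extension = "templated",
                    nta_A = "A", nta_C = "C", nta_G = "G", nta_U = "U")

small_config <- function(seed = 11, ...) {
  args <- list(n_mirnas = 6, genome_length = 2500, mean_abundance = 300,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Tail-class matrix where only "none" and "U" occur, optionally with one
# planted miRNA whose U probability differs: the clean two-class design for
# uridylation parameter-recovery checks.
u_only_tails <- function(n_mirnas, p_u, planted = NULL, planted_p_u = p_u) {
  m <- matrix(0, n_mirnas, 6,
              dimnames = list(NULL, c("none", "templated", "A", "C", "G", "U")))
  m[, "U"] <- p_u
  if (!is.null(planted)) m[planted, "U"] <- planted_p_u
  m[, "none"] <- 1 - m[, "U"]
  m
}

# Truth-vs-classifier agreement over classified tags: the truth table never
# contains "other", so an "other" call counts as disagreement.
classification_agreement <- function(classified, truth) {
  tr <- truth[match(classified$read_id, truth$read_id), ]
  mapped <- unname(CLASS_TO_TRUTH[as.character(classified$tag_class)])
  mean(!is.na(mapped) & mapped == tr$tail_class)
}

# Downstream pipeline from simulated alignments (the SAM-ingestion path,
# skipping FASTQ trimming): filter -> assign -> classify -> profiles.
sim_profiles <- function(ref, sim) {
  aln <- emit_sam(sim)
  filt <- min_mismatch_filter(aln)
  lapply(split(seq_len(nrow(filt)), sub("_.*$", "", filt$read_id)),
         function(idx) {
           asg <- assign_tags(filt[idx, ], ref$annotation)
           cls <- classify_assignments(asg, ref$annotation)
           tailing_table(cls, ref$annotation)
         })
}
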