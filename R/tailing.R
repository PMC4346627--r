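TAG_CLASSES <- c("exact_mature", "templated_extension",
                 "nta_A", "nta_C", "nta_G", "nta_U", "other")

#' Classify the 3' end of assigned tags for one mature miRNA
#'
#' A tag equal to the mature sequence is `exact_mature`. A tag one
#' nucleotide longer whose body equals the mature sequence is a
#' `templated_extension` when its last base equals the genome base
#' immediately downstream of the mature 3' end, otherwise `nta_<base>`
#' (DNA `T` reported as RNA `U`). Everything else - internal mismatches,
#' shorter tags, tails of two or more nucleotides - is `other`.
#'
#' @param seqs character vector of tag sequences (DNA space).
#' @param mature_seq the annotated mature sequence.
#' @param plus_one_base genome base (DNA) at mature 3' + 1, transcript
#'   orientation.
#' @return factor with levels `r paste(TAG_CLASSES, collapse=", ")`.
#' @export
classify_tags <- function(seqs, mature_seq, plus_one_base) {
  len <- nchar(mature_seq)
  tl <- nchar(seqs)
  cls <- rep("other", length(seqs))
  cls[tl == len & seqs == mature_seq] <- "exact_mature"
  plus1 <- tl == len + 1L & substr(seqs, 1L, len) == mature_seq
  if (any(plus1)) {
    last <- substr(seqs[plus1], len + 1L, len + 1L)
    cls[plus1] <- ifelse(last == plus_one_base, "templated_extension",
                         paste0("nta_", to_rna_base(last)))
  }
  factor(cls, levels = TAG_CLASSES)
}

#' Classify all assigned tags against their miRNAs
#'
#' Applies [classify_tags()] per miRNA. By default only tags with canonical
#' 5' start (offset 0) are classified, because a +1 tag is recognised by
#' being identical to the genomic mature sequence except its last base;
#' `offsets = "any"` admits 5'-shifted tags for exploratory use (their body
#' is then compared against the correspondingly shifted genomic sequence).
#'
#' @param assignments an [assign_tags()] result.
#' @param annotation annotation data.frame (or `mirtail_reference`).
#' @param offsets `"zero"` (default) or `"any"`.
#' @return the assignments table restricted to classified tags, with a
#'   `tag_class` factor column added.
#' @export
classify_assignments <- function(assignments, annotation,
                                 offsets = c("zero", "any")) {
  offsets <- match.arg(offsets)
  if (inherits(annotation, "mirtail_reference"))
    annotation <- annotation$annotation
  a <- data.table::as.data.table(assignments)
  if (offsets == "zero") a <- a[offset5 == 0L]
  if (!nrow(a)) {
    a[, tag_class := factor(character(0), levels = TAG_CLASSES)]
    return(a[])
  }
  ann <- data.table::as.data.table(annotation)
  a[, tag_class := {
    i <- match(.BY$mirna_name, ann$name)
    if (is.na(i)) stop("unknown miRNA in assignments: ", .BY$mirna_name,
                       call. = FALSE)
    off <- .BY$offset5
    # reference body for this (miRNA, offset): genomic sequence from the
    # shifted 5' start to the mature 3' end, from the stored context
    body <- substr(ann$ext_seq[i], 4L + off, 3L + ann$length[i])
    as.character(classify_tags(seq, body, ann$plus_one_base[i]))
  }, by = list(mirna_name, offset5)]
  a[, tag_class := factor(tag_class, levels = TAG_CLASSES)]
  a[]
}

#' Tailing profile from tag-class counts
#'
#' Computes the per-nucleotide non-templated addition (NTA) percentages for
#' one miRNA in one condition. Each observable NTA percentage is
#' `tail_count * 100 / (m + sum of non-templated tail counts)`: the
#' templated extension class is excluded from both numerator and
#' denominator, and the nucleotide equal to the genome +1 base has no NTA
#' class at all (a tail of that base is templated by definition, so its
#' percentage is `NA`). `mono_U_pct` is the U percentage under this formula;
#' `mono_U_pct_mature` is the alternative u/m ratio (mono-uridylated per
#' exactly matching mature tag), reported for transparency.
#'
#' @param counts named counts for the classes `exact_mature`,
#'   `templated_extension`, `nta_A`, `nta_C`, `nta_G`, `nta_U` (missing
#'   names count as 0; an `other` count is carried through).
#' @param plus_one_base genome +1 base (DNA) of the miRNA.
#' @return one-row data.table: m, a, c, g, u, templated, other, pct_A,
#'   pct_C, pct_G, pct_U, mono_U_pct, mono_U_pct_mature, denominator,
#'   defined.
#' @export
tailing_profile <- function(counts, plus_one_base) {
  get <- function(k) if (k %in% names(counts)) as.numeric(counts[[k]]) else 0
  m <- get("exact_mature")
  tails <- c(A = get("nta_A"), C = get("nta_C"), G = get("nta_G"),
             U = get("nta_U"))
  templated <- get("templated_extension")
  other <- get("other")
  observable <- setdiff(names(tails), to_rna_base(plus_one_base))
  denom <- m + sum(tails[observable])
  defined <- denom > 0
  pct <- stats::setNames(rep(NA_real_, 4), names(tails))
  if (defined) pct[observable] <- tails[observable] * 100 / denom
  mono_u <- if ("U" %in% observable) pct[["U"]] else NA_real_
  mono_u_mat <- if (m > 0 && "U" %in% observable)
    tails[["U"]] * 100 / m else NA_real_
  data.table::data.table(
    m = m, a = tails[["A"]], c = tails[["C"]], g = tails[["G"]],
    u = tails[["U"]], templated = templated, other = other,
    pct_A = pct[["A"]], pct_C = pct[["C"]], pct_G = pct[["G"]],
    pct_U = pct[["U"]], mono_U_pct = mono_u,
    mono_U_pct_mature = mono_u_mat,
    denominator = denom, defined = defined)
}

#' Tailing profiles for all miRNAs in one condition
#'
#' @param classified a [classify_assignments()] result.
#' @param annotation annotation data.frame (or `mirtail_reference`); supplies
#'   the +1 base per miRNA and the full miRNA list (miRNAs without
#'   classified tags get an undefined profile).
#' @param condition condition label stored in the table.
#' @return data.table with one row per miRNA: mirna_name, condition, the
#'   [tailing_profile()] columns.
#' @export
tailing_table <- function(classified, annotation, condition = "sample1") {
  if (inherits(annotation, "mirtail_reference"))
    annotation <- annotation$annotation
  cl <- data.table::as.data.table(classified)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    nm <- annotation$name[i]
    counts <- table(cl[mirna_name == nm, tag_class])
    prof <- tailing_profile(counts, annotation$plus_one_base[i])
    data.table::data.table(mirna_name = nm, condition = condition, prof)
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, mirna_name)
  out[]
}

#' Cross-miRNA distribution of +1 NTA percentages per nucleotide
#'
#' Summarises, per condition and nucleotide, the distribution across miRNAs
#' of the +1-position non-templated addition percentage (median and first /
#' third quartiles), mirroring a per-nucleotide box summary of tailing
#' composition. Only defined profiles contribute.
#'
#' @param profiles one or more [tailing_table()] results (row-bound).
#' @param min_tags minimum profile denominator to include a miRNA.
#' @return data.table: condition, nucleotide, n, q1, median, q3.
#' @export
plus_one_composition <- function(profiles, min_tags = 1L) {
  p <- data.table::as.data.table(profiles)
  p <- p[defined == TRUE & denominator >= min_tags]
  long <- data.table::melt(
    p[, list(mirna_name, condition, pct_A, pct_C, pct_G, pct_U)],
    id.vars = c("mirna_name", "condition"),
    variable.name = "nucleotide", value.name = "pct")
  long[, nucleotide := sub("pct_", "", nucleotide)]
  long <- long[!is.na(pct)]
  out <- long[, list(n = .N,
                     q1 = stats::quantile(pct, 0.25, names = FALSE),
                     median = stats::median(pct),
                     q3 = stats::quantile(pct, 0.75, names = FALSE)),
              by = list(condition, nucleotide)]
  data.table::setorder(out, condition, nucleotide)
  out[]
}
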