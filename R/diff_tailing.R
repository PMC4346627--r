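#' Per-miRNA change in mono-uridylation between two conditions
#'
#' The primary change statistic is the percentage-point difference
#' `delta_points = pct_mut - pct_wt` (mono-uridylation percentages are
#' reported next to absolute percentages, so point differences are the
#' natural scale); the relative change `rel_change = (pct_mut - pct_wt) /
#' pct_wt` is also emitted for transparency. A miRNA whose profile is
#' undefined in either condition is marked `analysed = FALSE`.
#'
#' @param profiles_wt [tailing_table()] for the reference condition.
#' @param profiles_mut [tailing_table()] for the comparison condition.
#' @param variant `"formula"` uses the NTA-denominator mono-U percentage
#'   (default); `"mature"` uses the per-exactly-matching-mature variant.
#' @return data.table: mirna_name, pct_wt, pct_mut, delta_points,
#'   rel_change, tags_wt, tags_mut, analysed.
#' @export
uridylation_change <- function(profiles_wt, profiles_mut,
                               variant = c("formula", "mature")) {
  variant <- match.arg(variant)
  col <- if (variant == "formula") "mono_U_pct" else "mono_U_pct_mature"
  pick <- function(p, suf) {
    p <- data.table::as.data.table(p)
    out <- p[, list(mirna_name,
                    pct = p[[col]],
                    tags = denominator,
                    ok = defined & !is.na(p[[col]]))]
    data.table::setnames(out, c("pct", "tags", "ok"),
                         paste0(c("pct_", "tags_", "ok_"), suf))
    out
  }
  out <- merge(pick(profiles_wt, "wt"), pick(profiles_mut, "mut"),
               by = "mirna_name", all = TRUE)
  out[is.na(ok_wt), ok_wt := FALSE]
  out[is.na(ok_mut), ok_mut := FALSE]
  out[, analysed := ok_wt & ok_mut]
  out[, delta_points := ifelse(analysed, pct_mut - pct_wt, NA_real_)]
  out[, rel_change := ifelse(analysed & pct_wt > 0,
                             (pct_mut - pct_wt) / pct_wt, NA_real_)]
  out[, c("ok_wt", "ok_mut") := NULL]
  data.table::setcolorder(out, c("mirna_name", "pct_wt", "pct_mut",
                                 "delta_points", "rel_change",
                                 "tags_wt", "tags_mut", "analysed"))
  out[]
}

#' Rank miRNAs by uridylation change and call top-quartile decreases
#'
#' Restricts the analysis to miRNAs with at least `min_tags` contributing
#' tags (mature + observable tails) in both conditions, ranks ascending by
#' `delta_points` (most decreased = rank 1, ties broken by greater total tag
#' count then by name), and flags the top quartile of decreased uridylation
#' (`rank <= ceiling(n_analysed / 4)`).
#'
#' @param changes a [uridylation_change()] result.
#' @param min_tags minimum per-condition tag support (default 10).
#' @return the table restricted to analysed miRNAs, with rank and
#'   `in_top_quartile_decrease`; attribute `n_analysed` records the count.
#' @export
rank_and_quartile <- function(changes, min_tags = 10L) {
  ch <- data.table::as.data.table(changes)
  ch <- ch[analysed == TRUE & tags_wt >= min_tags & tags_mut >= min_tags]
  n <- nrow(ch)
  if (n == 0L) {
    warning("no miRNA passed the min_tags filter; empty ranking")
    ch[, `:=`(rank = integer(0), in_top_quartile_decrease = logical(0))]
    data.table::setattr(ch, "n_analysed", 0L)
    return(ch[])
  }
  ord <- order(ch$delta_points, -(ch$tags_wt + ch$tags_mut), ch$mirna_name)
  ch <- ch[ord]
  ch[, rank := seq_len(n)]
  ch[, in_top_quartile_decrease := rank <= ceiling(n / 4)]
  data.table::setattr(ch, "n_analysed", n)
  ch[]
}

#' Intersect uridylation decreases with expression changes
#'
#' Flags miRNAs that are both in the top quartile of decreased uridylation
#' and above an expression fold-change threshold (accumulating in the
#' comparison condition).
#'
#' @param ranked a [rank_and_quartile()] result.
#' @param expression an [expression_compare()] result.
#' @param fold_threshold minimum CPM ratio to call accumulation (default 2).
#' @return the ranked table with `cpm_ratio` and logical `accumulating` and
#'   `joint_hit` columns.
#' @export
intersect_with_expression <- function(ranked, expression,
                                      fold_threshold = 2) {
  r <- data.table::as.data.table(ranked)
  e <- data.table::as.data.table(expression)[, list(mirna_name,
                                                    cpm_ratio = ratio)]
  out <- merge(r, e, by = "mirna_name", all.x = TRUE, sort = FALSE)
  out[, accumulating := !is.na(cpm_ratio) & cpm_ratio >= fold_threshold]
  out[, joint_hit := in_top_quartile_decrease & accumulating]
  data.table::setorder(out, rank)
  out[]
}
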