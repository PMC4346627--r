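mk_profile <- function(mirna, pct_u, tags = 1000, condition = "x") {
  u <- round(tags * pct_u / 100)
  cbind(mirna_name = mirna, condition = condition,
        tailing_profile(c(exact_mature = tags - u, nta_U = u), "A"))
}

mk_changes <- function(deltas, tags = 1000) {
  wt <- data.table::rbindlist(lapply(seq_along(deltas), function(i)
    mk_profile(sprintf("m%02d", i), 10, tags)))
  mut <- data.table::rbindlist(lapply(seq_along(deltas), function(i)
    mk_profile(sprintf("m%02d", i), 10 + deltas[i], tags)))
  uridylation_change(wt, mut)
}

test_that("uridylation change is a percentage-point difference", {
  ch <- uridylation_change(mk_profile("m", 10), mk_profile("m", 6))
  expect_equal(ch$delta_points, -4)
  expect_equal(ch$rel_change, -0.4)
  expect_true(ch$analysed)

  same <- uridylation_change(mk_profile("m", 7.5), mk_profile("m", 7.5))
  expect_equal(same$delta_points, 0)

  # an undefined profile in either condition marks the miRNA not analysed
  empty <- cbind(mirna_name = "m", condition = "x",
                 tailing_profile(c(exact_mature = 0), "A"))
  bad <- uridylation_change(mk_profile("m", 10), empty)
  expect_false(bad$analysed)
  expect_true(is.na(bad$delta_points))
})

test_that("ranking orders by decrease with deterministic tie-breaks", {
  ch <- mk_changes(c(-5, -1, 0, 2))
  rk <- rank_and_quartile(ch, min_tags = 10)
  expect_equal(rk$rank, 1:4)
  expect_equal(rk$mirna_name, sprintf("m%02d", 1:4))
  expect_equal(rk$in_top_quartile_decrease, c(TRUE, FALSE, FALSE, FALSE))

  # ties: greater total tag support first, then name
  wt <- rbind(mk_profile("mB", 10, 2000), mk_profile("mA", 10, 1000),
              mk_profile("mC", 10, 1000))
  mut <- rbind(mk_profile("mB", 8, 2000), mk_profile("mA", 8, 1000),
               mk_profile("mC", 8, 1000))
  rk2 <- rank_and_quartile(uridylation_change(wt, mut), min_tags = 10)
  expect_equal(rk2$mirna_name, c("mB", "mA", "mC"))
})

test_that("quartile size is ceiling(n/4)", {
  rk8 <- rank_and_quartile(mk_changes(seq(-4, 3)), min_tags = 1)
  expect_equal(sum(rk8$in_top_quartile_decrease), 2L)

  rk364 <- rank_and_quartile(mk_changes(seq(-5, 5, length.out = 364)),
                             min_tags = 1)
  expect_equal(attr(rk364, "n_analysed"), 364L)
  expect_equal(sum(rk364$in_top_quartile_decrease), 91L)
  expect_true(all(rk364$rank[rk364$in_top_quartile_decrease] <= 91))
})

test_that("negating every delta reverses the ranking exactly", {
  set.seed(79)
  deltas <- sample(seq(-6, 6, by = 0.05), 17)   # distinct, count-exact
  rk <- rank_and_quartile(mk_changes(deltas, tags = 10000), min_tags = 1)
  rk_neg <- rank_and_quartile(mk_changes(-deltas, tags = 10000),
                              min_tags = 1)
  expect_equal(rk_neg$rank[match(rk$mirna_name, rk_neg$mirna_name)],
               nrow(rk) + 1L - rk$rank)
})

test_that("the min_tags filter defines the analysed set", {
  wt <- rbind(mk_profile("deep", 10, 500), mk_profile("shallow", 10, 5))
  mut <- rbind(mk_profile("deep", 6, 500), mk_profile("shallow", 2, 5))
  rk <- rank_and_quartile(uridylation_change(wt, mut), min_tags = 10)
  expect_equal(attr(rk, "n_analysed"), 1L)
  expect_equal(rk$mirna_name, "deep")
  expect_warning(rank_and_quartile(uridylation_change(wt, mut),
                                   min_tags = 1e6),
                 "empty ranking")
})

test_that("joint decreased-and-accumulating calls come from both tables", {
  expect_equal(nrow(intersect_with_expression(
    rank_and_quartile(mk_changes(-4), min_tags = 1)[0, ],
    expression_compare(data.frame(mirna_name = character(0),
                                  cpm = numeric(0)),
                       data.frame(mirna_name = character(0),
                                  cpm = numeric(0))))), 0L)

  rk <- rank_and_quartile(mk_changes(c(-4, -3, 0, 1, 2, 3, 4, 5)),
                          min_tags = 1)
  expr <- expression_compare(
    data.frame(mirna_name = sprintf("m%02d", 1:8), cpm = 100),
    data.frame(mirna_name = sprintf("m%02d", 1:8),
               cpm = c(400, 100, 400, 100, 100, 100, 100, 100)))
  out <- intersect_with_expression(rk, expr, fold_threshold = 2)
  expect_equal(out$mirna_name[out$joint_hit], "m01")
  expect_true(out$accumulating[out$mirna_name == "m03"])
  expect_false(out$joint_hit[out$mirna_name == "m03"])
})

test_that("planted joint hits are recovered end to end", {
  # three miRNAs planted with both decreased uridylation and higher
  # abundance in the mutant; they and only they are flagged
  n <- 16
  ref <- build_toy_reference(sim_config(n_mirnas = n, genome_length = 8000,
                                        seed = 83))
  # plant on loci where a U tail is observable (+1 genome base not T)
  idx <- head(which(ref$annotation$plus_one_base != "T"), 3)
  tails_wt <- u_only_tails(n, 0.10)
  tails_mut <- u_only_tails(n, 0.10)
  tails_mut[idx, "U"] <- 0.04
  tails_mut[, "none"] <- 1 - tails_mut[, "U"]
  abund <- cbind(wt = rep(3000, n), mut = rep(3000, n))
  abund[idx, "mut"] <- 12000
  cfg <- sim_config(n_mirnas = n, genome_length = 8000,
                    mean_abundance = abund,
                    tail_probs = list(wt = tails_wt, mut = tails_mut),
                    seed = 83)
  sim <- simulate_reads(ref, cfg)
  profs <- sim_profiles(ref, sim)
  asg_n <- function(cond) {
    tr <- trim_reads(sim$reads[sim$reads$condition == cond, ],
                     adapter = cfg$adapter)
    library_size(tr)
  }
  counts <- lapply(names(profs), function(cond) {
    aln <- emit_sam(sim)
    filt <- min_mismatch_filter(aln[grepl(paste0("^", cond, "_"),
                                          aln$read_id), ])
    build_count_table(assign_tags(filt, ref$annotation), asg_n(cond),
                      sample = cond)
  })
  names(counts) <- names(profs)
  expr <- expression_compare(counts$wt, counts$mut)
  ranked <- rank_and_quartile(
    uridylation_change(profs$wt, profs$mut), min_tags = 10)
  out <- intersect_with_expression(ranked, expr, fold_threshold = 2)
  planted <- ref$annotation$name[idx]
  expect_gte(attr(ranked, "n_analysed"), 12)
  expect_setequal(out$mirna_name[out$joint_hit], planted)
})
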