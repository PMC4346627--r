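#' Validate a pipeline run configuration
#'
#' Checks ranges, probability sums, adapter alphabet and (for file-based
#' runs) path existence. Problems are returned, never raised, so a caller
#' can report all of them at once.
#'
#' @param config a named list; see [run_all()] for the recognised fields.
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

  window <- config$window %||% 3L
  if (!num1(window) || window < 0) add("window must be a non-negative number")
  min_length <- config$min_length %||% 18L
  if (!num1(min_length) || min_length < 1) add("min_length must be >= 1")
  max_mm <- config$max_mismatches %||% 3L
  if (!num1(max_mm) || max_mm < 0) add("max_mismatches must be >= 0")
  min_tags <- config$min_tags %||% 10L
  if (!num1(min_tags) || min_tags < 0) add("min_tags must be >= 0")
  adapter <- config$adapter %||% "TCGTATGCCGTCTTCTGCTTGT"
  if (!grepl("^[ACGT]+$", adapter))
    add("adapter must be a non-empty ACGT string")
  wmode <- config$weighting %||% "fractional"
  if (!wmode %in% c("fractional", "unique"))
    add("weighting must be 'fractional' or 'unique'")
  variant <- config$variant %||% "formula"
  if (!variant %in% c("formula", "mature"))
    add("variant must be 'formula' or 'mature'")
  seed <- config$seed %||% 1L
  if (!num1(seed)) add("seed must be a single number")

  if (!is.null(config$simulate)) {
    ok <- tryCatch({ do.call(sim_config, config$simulate); TRUE },
                   error = function(e) { add(conditionMessage(e)); FALSE })
  } else {
    for (p in c("genome", "annotation")) {
      if (is.null(config[[p]])) add(sprintf("missing required path: %s", p))
      else if (!file.exists(config[[p]]))
        add(sprintf("%s path does not exist: %s", p, config[[p]]))
    }
    smp <- config$samples
    if (is.null(smp) || !length(smp)) add("no samples configured")
    for (nm in names(smp)) {
      if (is.null(smp[[nm]]$fastq) && is.null(smp[[nm]]$sam))
        add(sprintf("sample %s needs a fastq or sam path", nm))
      for (p in c(smp[[nm]]$fastq, smp[[nm]]$sam))
        if (!is.null(p) && !file.exists(p))
          add(sprintf("sample %s path does not exist: %s", nm, p))
    }
  }
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full tailing pipeline
#'
#' Orchestrates simulate (or load) -> trim -> align/ingest -> minimum-
#' mismatch filter -> assign/count -> 3'-tail classification -> condition
#' comparison, writing every intermediate as plain text plus a JSON manifest
#' (parameters, input checksums, per-stage record counts) sufficient to
#' re-run the analysis bit-identically.
#'
#' Recognised config fields: either `simulate` (a list of [sim_config()]
#' arguments) or `genome`, `annotation` and `samples` (named list; per
#' sample a `fastq` or `sam` path); plus the optional parameters `adapter`,
#' `min_length`, `window`, `max_mismatches`, `weighting`, `min_tags`,
#' `variant`, `all_hits`, `seed`.
#'
#' @param config named list, or the path of a YAML file holding one.
#' @param outdir output directory.
#' @return the run manifest (named list), invisibly; all tables are written
#'   under `outdir`.
#' @export
run_all <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  adapter <- config$adapter %||% "TCGTATGCCGTCTTCTGCTTGT"
  min_length <- as.integer(config$min_length %||% 18L)
  window <- as.integer(config$window %||% 3L)
  max_mm <- as.integer(config$max_mismatches %||% 3L)
  weighting <- config$weighting %||% "fractional"
  min_tags <- as.integer(config$min_tags %||% 10L)
  variant <- config$variant %||% "formula"
  manifest <- list(package_version = as.character(utils::packageVersion("mirtail")),
                   parameters = list(adapter = adapter,
                                     min_length = min_length, window = window,
                                     max_mismatches = max_mm,
                                     weighting = weighting,
                                     min_tags = min_tags, variant = variant),
                   stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  if (!is.null(config$simulate)) {
    simargs <- config$simulate
    if (!is.null(config$seed) && is.null(simargs$seed))
      simargs$seed <- config$seed
    scfg <- do.call(sim_config, simargs)
    ref <- build_toy_reference(scfg)
    paths <- write_reference(ref, file.path(outdir, "reference"))
    sim <- simulate_reads(ref)
    write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
    samples <- split(seq_len(nrow(sim$reads)),
                     sim$reads$condition)[scfg$conditions]
    sample_input <- lapply(names(samples), function(cond) {
      fq <- file.path(outdir, sprintf("reads_%s.fastq", cond))
      write_fastq(sim$reads[samples[[cond]]], fq)
      sam <- file.path(outdir, sprintf("aln_%s.sam", cond))
      aln <- emit_sam(sim, all_hits = isTRUE(config$all_hits),
                      max_mismatches = max_mm)
      write_sam(aln[aln$read_id %in% sim$reads$read_id[samples[[cond]]], ],
                ref$genome, sam)
      list(fastq = fq, sam = sam)
    })
    names(sample_input) <- names(samples)
    genome <- ref$genome
    annotation <- ref$annotation
    manifest$inputs <- list(
      mode = "simulated", seed = scfg$seed,
      reference = as.list(stats::setNames(
        file.path("reference", basename(paths)), names(paths))))
    log_stage("simulate", reads = nrow(sim$reads),
              mirnas = nrow(annotation))
  } else {
    genome <- read_genome(config$genome)
    annotation <- read_annotation(config$annotation, genome)
    sample_input <- config$samples
    manifest$inputs <- list(
      mode = "files",
      checksums = as.list(tools::md5sum(unlist(c(config$genome,
                                                 config$annotation,
                                                 lapply(config$samples,
                                                        unlist))))))
  }

  per_sample <- lapply(names(sample_input), function(cond) {
    inp <- sample_input[[cond]]
    if (!is.null(inp$fastq)) {
      raw <- read_fastq(inp$fastq)
      trimmed <- trim_reads(raw, adapter = adapter, min_length = min_length)
      N <- library_size(trimmed)
      write_tsv(trimmed, file.path(outdir, sprintf("trimmed_%s.tsv", cond)))
      hist <- length_histogram(trimmed)
      write_tsv(data.frame(length = names(hist), count = as.integer(hist)),
                file.path(outdir, sprintf("lengths_%s.tsv", cond)))
      log_stage(paste0("trim_", cond), reads_in = nrow(raw),
                reads_kept = N)
    } else {
      trimmed <- NULL
      N <- NA_integer_
    }
    if (!is.null(inp$sam)) {
      aln <- read_sam(inp$sam)
    } else {
      kept <- trimmed[trimmed$kept, ]
      aln <- toy_align(stats::setNames(kept$trimmed, kept$read_id), genome,
                       max_mismatches = max_mm)
    }
    if (is.na(N)) N <- length(unique(aln$read_id))
    filt <- min_mismatch_filter(aln)
    # reads mapping best to rRNA decoys are excluded from assignment but
    # stay in N
    decoy_reads <- unique(filt$read_id[grepl("^rRNA", filt$reference)])
    filt_mirna <- filt[!filt$read_id %in% decoy_reads, ]
    write_sam(filt, genome, file.path(outdir, sprintf("filtered_%s.sam", cond)))
    log_stage(paste0("filter_", cond), alignments_in = nrow(aln),
              alignments_retained = nrow(filt),
              duplicates_collapsed = attr(filt, "deduplicated"),
              indel_records_dropped = attr(aln, "dropped_indel") %||% 0L,
              unscorable_records = attr(aln, "dropped_unscorable") %||% 0L,
              decoy_reads_excluded = length(decoy_reads))

    asg <- assign_tags(filt_mirna, annotation, window = window)
    write_tsv(asg, file.path(outdir, sprintf("assignments_%s.tsv", cond)))
    counts <- build_count_table(asg, N, sample = cond, weighting = weighting)
    write_tsv(counts, file.path(outdir, sprintf("counts_%s.tsv", cond)),
              comments = sprintf("N=%d weighting=%s", N, weighting))
    cls <- classify_assignments(asg, annotation)
    prof <- tailing_table(cls, annotation, condition = cond)
    write_tsv(prof, file.path(outdir, sprintf("tailing_%s.tsv", cond)))
    log_stage(paste0("quantify_", cond), N = N, assigned = nrow(asg),
              classified = nrow(cls))
    list(counts = counts, profiles = prof)
  })
  names(per_sample) <- names(sample_input)

  result <- list(manifest = NULL, samples = per_sample)
  if (length(per_sample) >= 2L) {
    c1 <- names(per_sample)[1]; c2 <- names(per_sample)[2]
    expr <- expression_compare(per_sample[[c1]]$counts,
                               per_sample[[c2]]$counts)
    write_tsv(expr, file.path(outdir, "expression_ratio.tsv"))
    ch <- uridylation_change(per_sample[[c1]]$profiles,
                             per_sample[[c2]]$profiles, variant = variant)
    ranked <- rank_and_quartile(ch, min_tags = min_tags)
    ranked_out <- intersect_with_expression(ranked, expr)
    write_tsv(ranked_out, file.path(outdir, "uridylation_ranked.tsv"),
              comments = sprintf("min_tags=%d variant=%s n_analysed=%d",
                                 min_tags, variant,
                                 attr(ranked, "n_analysed")))
    log_stage("diff", n_analysed = attr(ranked, "n_analysed"),
              top_quartile = sum(ranked$in_top_quartile_decrease))
    result$expression <- expr
    result$ranked <- ranked_out
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}

#' In-memory pipeline on simulated data
#'
#' Runs trim -> true-placement alignments -> minimum-mismatch filter ->
#' assignment -> classification -> tailing profiles -> ranking entirely in
#' memory for a simulation, without file round-trips. This is the engine
#' behind large property checks; [run_all()] is the file-based equivalent.
#'
#' @param config a [sim_config()] object.
#' @param all_hits report all qualifying placements (slow; desk scale only)
#'   instead of the true placement per read.
#' @param min_tags passed to [rank_and_quartile()].
#' @param weighting passed to [build_count_table()].
#' @return list: reference, sim, per-condition `trimmed`, `assignments`,
#'   `classified`, `counts`, `profiles`; plus `expression`, `changes`,
#'   `ranked`.
#' @export
run_sim_pipeline <- function(config, all_hits = FALSE, min_tags = 10L,
                             weighting = "fractional") {
  ref <- build_toy_reference(config)
  sim <- simulate_reads(ref)
  aln_all <- emit_sam(sim, all_hits = all_hits)
  conds <- config$conditions
  reads_by_cond <- split(sim$reads, sim$reads$condition)

  per <- lapply(conds, function(cond) {
    rd <- reads_by_cond[[cond]]
    trimmed <- trim_reads(rd, adapter = config$adapter)
    N <- library_size(trimmed)
    keep_ids <- trimmed$read_id[trimmed$kept]
    aln <- aln_all[aln_all$read_id %in% keep_ids, ]
    filt <- min_mismatch_filter(aln)
    decoy_reads <- unique(filt$read_id[grepl("^rRNA", filt$reference)])
    filt <- filt[!filt$read_id %in% decoy_reads, ]
    asg <- assign_tags(filt, ref$annotation)
    counts <- build_count_table(asg, N, sample = cond, weighting = weighting)
    cls <- classify_assignments(asg, ref$annotation)
    prof <- tailing_table(cls, ref$annotation, condition = cond)
    list(N = N, trimmed = trimmed, assignments = asg, classified = cls,
         counts = counts, profiles = prof)
  })
  names(per) <- conds

  out <- list(reference = ref, sim = sim, samples = per)
  if (length(conds) >= 2L) {
    out$expression <- expression_compare(per[[1]]$counts, per[[2]]$counts)
    out$changes <- uridylation_change(per[[1]]$profiles, per[[2]]$profiles)
    out$ranked <- rank_and_quartile(out$changes, min_tags = min_tags)
  }
  out
}
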