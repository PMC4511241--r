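## End-to-end orchestration: QC -> anchors -> junction calling -> merged
## aggregation -> quantification -> formation features, with a run report.

#' Exon-model length per gene
#'
#' Length of the union of a gene's exons across its transcripts, in bp.
#'
#' @param models a `gene_models` table.
#' @return named numeric vector of lengths.
#' @export
gene_lengths <- function(models) {
  gr <- GenomicRanges::GRanges(models$chrom,
                               IRanges::IRanges(models$start + 1L,
                                                models$end))
  by_gene <- split(gr, models$gene_id)
  vapply(as.list(by_gene), function(g)
    sum(IRanges::width(GenomicRanges::reduce(g))), numeric(1))
}

#' Pipeline configuration
#'
#' Bundles all stage parameters; defaults are the published thresholds
#' (25-bp anchors, 100 kb span, 2 junction reads, RC length 25, word size
#' 11).
#'
#' @param genome_fa path to the genome FASTA.
#' @param gtf path to the gene-model GTF.
#' @param samples named list: sample id -> c(fastq1, fastq2).
#' @param out_dir output directory.
#' @param qc a [qc_config()].
#' @param max_span,min_support,max_mismatch,max_hits caller thresholds.
#' @param scoring an [rc_scoring()] for the RC feature search.
#' @param ercc_tsv optional ERCC table path (id, known_copies, length).
#' @param repeats_bed optional repeat-track BED4 path.
#' @param mate_filter apply the mate-consistency filter.
#' @param seed integer seed for any sampling the stages perform.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fa, gtf, samples, out_dir = NULL,
                            qc = qc_config(), max_span = 1e5,
                            min_support = 2L, max_mismatch = 2L,
                            max_hits = 10L, scoring = rc_scoring(),
                            ercc_tsv = NULL, repeats_bed = NULL,
                            mate_filter = TRUE, seed = 1L) {
  structure(list(genome_fa = genome_fa, gtf = gtf, samples = samples,
                 out_dir = out_dir, qc = qc, max_span = max_span,
                 min_support = as.integer(min_support),
                 max_mismatch = as.integer(max_mismatch),
                 max_hits = as.integer(max_hits), scoring = scoring,
                 ercc_tsv = ercc_tsv, repeats_bed = repeats_bed,
                 mate_filter = mate_filter, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full circRNA pipeline
#'
#' Executes QC, anchor-based junction calling per sample, merged
#' aggregation across samples, expression quantification (gene FPKM,
#' junction reads per million, host-normalised circRNA abundance, optional
#' ERCC absolute copy numbers) and formation features, writing artifacts
#' and a run report when `out_dir` is set. Outputs are identical for
#' identical config and seed.
#'
#' @param config a [pipeline_config()].
#' @return list with `calls` (merged), `per_sample_calls`, `quant`,
#'   `features`, `report`.
#' @export
run_pipeline <- function(config) {
  for (f in c(config$genome_fa, config$gtf,
              unlist(config$samples, use.names = FALSE),
              config$ercc_tsv, config$repeats_bed)) {
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
  }
  set.seed(config$seed)
  genome <- read_fasta(config$genome_fa)
  models <- read_gtf(config$gtf)
  ercc <- if (!is.null(config$ercc_tsv)) read_ercc_table(config$ercc_tsv)
  repeats <- if (!is.null(config$repeats_bed)) read_repeat_bed(config$repeats_bed)

  glen <- gene_lengths(models)
  per_sample_calls <- list()
  evidence <- list()
  counts <- list()
  totals <- c()
  report <- list(parameters = config[c("max_span", "min_support",
                                       "max_mismatch", "max_hits",
                                       "mate_filter", "seed")])
  for (sid in names(config$samples)) {
    fq <- config$samples[[sid]]
    r1 <- read_fastq(fq[1L], mate = 1L)
    r2 <- read_fastq(fq[2L], mate = 2L)
    qc <- qc_pairs(r1, r2, config$qc)
    res <- call_circrnas(qc$reads1, qc$reads2, genome, models,
                         sample_id = sid, max_span = config$max_span,
                         min_support = config$min_support,
                         max_mismatch = config$max_mismatch,
                         max_hits = config$max_hits,
                         mate_filter = config$mate_filter)
    per_sample_calls[[sid]] <- res$calls
    evidence[[sid]] <- res$evidence
    cnt <- count_gene_fragments(qc$reads1, genome, models,
                                max_hits = config$max_hits)
    counts[[sid]] <- cnt$counts
    totals[sid] <- cnt$total
    report[[paste0("sample_", sid)]] <-
      c(raw_pairs = nrow(r1), qc_pairs = nrow(qc$reads1), res$stage_counts)
  }

  ## merged calling across all cells
  all_evidence <- do.call(rbind, Filter(Negate(is.null), evidence))
  merged <- aggregate_calls(all_evidence, min_support = config$min_support)

  ## quantification
  count_mat <- do.call(cbind, counts)
  quant <- list(gene_counts = count_mat, total_fragments = totals)
  grand_total <- sum(totals)
  quant$gene_fpkm <- apply(count_mat, 2L, function(cl)
    fpkm(cl, glen[rownames(count_mat)], sum(cl)))
  if (nrow(merged)) {
    merged$junction_rpm <- junction_rpm(merged$junction_reads, grand_total)
    pooled_fpkm <- fpkm(rowSums(count_mat), glen[rownames(count_mat)],
                        grand_total)
    merged$host_fpkm <- pooled_fpkm[merged$gene_id]
    merged$host_normalized <- host_normalized(merged$junction_reads,
                                              merged$host_fpkm,
                                              pseudocount = 1)
  }
  if (!is.null(ercc)) {
    pooled <- rowSums(count_mat)
    obs <- pooled[ercc$id]
    obs[is.na(obs)] <- 0
    spikes <- data.frame(id = ercc$id, known_copies = ercc$known_copies,
                         fpkm = fpkm(obs, ercc$length, grand_total))
    quant$ercc_calibration <- ercc_calibrate(spikes)
    pooled_gene_fpkm <- fpkm(pooled, glen[names(pooled)], grand_total)
    keep <- !(names(pooled) %in% ercc$id)
    ac <- absolute_copies(pooled_gene_fpkm[keep], quant$ercc_calibration)
    quant$gene_copies <- stats::setNames(ac$copies, names(pooled)[keep])
    quant$total_mrna_copies <- ac$total
    if (nrow(merged)) {
      circ_len <- vapply(seq_len(nrow(merged)), function(i) {
        exons <- transcript_exons(models, merged$transcript_id[i])
        blk <- exons$start >= merged$acceptor_start[i] &
          exons$end <= merged$donor_end[i]
        sum(exons$end[blk] - exons$start[blk])
      }, numeric(1))
      circ_fpkm <- fpkm(merged$junction_reads, circ_len, grand_total)
      cc <- absolute_copies(circ_fpkm, quant$ercc_calibration)
      merged$copies <- cc$copies
      quant$total_circ_copies <- cc$total
    }
  }

  feats <- if (nrow(merged))
    circ_features(merged, models, genome, repeats, config$scoring)
  else NULL

  report$merged_calls <- nrow(merged)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_circ_bed(merged, file.path(config$out_dir, "calls_merged.bed"))
    for (sid in names(per_sample_calls))
      write_circ_bed(per_sample_calls[[sid]],
                     file.path(config$out_dir,
                               paste0("calls_", sid, ".bed")))
    utils::write.table(
      data.frame(gene_id = rownames(count_mat), count_mat,
                 check.names = FALSE),
      file.path(config$out_dir, "gene_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(feats))
      utils::write.table(feats, file.path(config$out_dir, "features.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    rep_lines <- utils::capture.output(utils::str(report, give.attr = FALSE))
    writeLines(rep_lines, file.path(config$out_dir, "report.txt"))
  }

  list(calls = merged, per_sample_calls = per_sample_calls, quant = quant,
       features = feats, report = report)
}
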