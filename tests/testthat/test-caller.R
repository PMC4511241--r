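test_that("candidate pairing requires reversed order, same chrom/strand, bounded span", {
  hh <- function(start, chrom = "chr1", strand = "+")
    data.frame(read_id = "r", chrom = chrom, start = start, strand = strand,
               stringsAsFactors = FALSE)
  ## reversed order on +: tail upstream of head
  expect_equal(nrow(pair_candidates(hh(10000L), hh(5000L))), 1L)
  ## colinear order: the non-circular case
  expect_equal(nrow(pair_candidates(hh(5000L), hh(10000L))), 0L)
  ## different chromosomes (trans-splicing-like)
  expect_equal(nrow(pair_candidates(hh(10000L), hh(5000L, chrom = "chr2"))), 0L)
  ## different strands
  expect_equal(nrow(pair_candidates(hh(10000L), hh(5000L, strand = "-"))), 0L)
  ## span beyond the default 100 kb limit
  expect_equal(nrow(pair_candidates(hh(150000L), hh(0L))), 0L)
  expect_equal(nrow(pair_candidates(hh(150000L), hh(0L), max_span = 2e5)), 1L)
  ## reversed order on minus strand flips the inequality
  expect_equal(nrow(pair_candidates(hh(5000L, strand = "-"),
                                    hh(10000L, strand = "-"))), 1L)
})

test_that("a junction read over exons 2-3 resolves to exact boundaries", {
  loc <- toy_locus()
  rseq <- junction_read(loc$genome, loc$models, "gA_t1", 2L, 3L, k = 40L)
  ap <- extract_anchor_pairs(mk_reads("r1", rseq))$anchors
  hh <- align_anchor(ap$head, loc$genome)
  th <- align_anchor(ap$tail, loc$genome)
  hh$read_id <- th$read_id <- "r1"
  cand <- pair_candidates(hh, th)
  expect_equal(nrow(cand), 1L)
  call <- resolve_junction(cand, rseq, loc$genome, loc$models)
  expect_equal(call$acceptor_start, 2500)
  expect_equal(call$donor_end, 4500)
  expect_equal(call$transcript_id, "gA_t1")
  expect_equal(c(call$i_up, call$i_down), c(2L, 3L))
})

test_that("junction reads on a minus-strand transcript resolve too", {
  loc <- toy_locus()
  rseq <- junction_read(loc$genome, loc$models, "gB_t1", 1L, 2L, k = 30L)
  for (r in list(rseq, revcomp(rseq))) {
    ap <- extract_anchor_pairs(mk_reads("r1", r))$anchors
    hh <- align_anchor(ap$head, loc$genome)
    th <- align_anchor(ap$tail, loc$genome)
    hh$read_id <- th$read_id <- "r1"
    cand <- pair_candidates(hh, th)
    expect_equal(nrow(cand), 1L)
    call <- resolve_junction(cand, r, loc$genome, loc$models)
    ## exons 1-2 in transcript order = genomic (18000,18350) + (21000,21400)
    expect_equal(call$acceptor_start, 18000)
    expect_equal(call$donor_end, 21400)
    expect_equal(call$strand, "-")
  }
})

test_that("a breakpoint inside an exon (not at a boundary) does not resolve", {
  loc <- toy_locus()
  exons <- transcript_exons(loc$models, "gA_t1")
  ## donor end shifted 3 bp into exon 3: sequence ends off-boundary
  S <- spliced_seq(loc$genome, exons[2:3, ])
  Soff <- substring(S, 1L, nchar(S) - 3L)
  k <- 40L
  rseq <- paste0(substring(Soff, nchar(Soff) - k + 1L, nchar(Soff)),
                 substring(Soff, 1L, 100L - k))
  ap <- extract_anchor_pairs(mk_reads("r1", rseq))$anchors
  hh <- align_anchor(ap$head, loc$genome)
  th <- align_anchor(ap$tail, loc$genome)
  hh$read_id <- th$read_id <- "r1"
  cand <- pair_candidates(hh, th)
  if (nrow(cand)) {
    expect_null(resolve_junction(cand[1L, ], rseq, loc$genome, loc$models))
  } else succeed()
})

test_that("reads joining exons of two different genes do not resolve", {
  loc <- toy_locus()
  exA <- transcript_exons(loc$models, "gA_t1")
  exB <- transcript_exons(loc$models, "gB_t1")
  ## donor part from gB (downstream), acceptor from gA (upstream)
  k <- 40L
  rseq <- paste0(substring(loc$genome[["chr1"]], exB$end[1L] - k + 1L,
                           exB$end[1L]),
                 substring(loc$genome[["chr1"]], exA$start[1L] + 1L,
                           exA$start[1L] + 100L - k))
  cand <- data.frame(read_id = "r1", chrom = "chr1", strand = "+",
                     head_start = exB$end[1L] - k, tail_start = exA$start[1L] +
                       (100L - k) - 25L, span = 25000L,
                     stringsAsFactors = FALSE)
  expect_null(resolve_junction(cand, rseq, loc$genome, loc$models))
})

test_that("mate consistency requires the mate inside the circle span", {
  call <- data.frame(chrom = "chr1", acceptor_start = 2500L,
                     donor_end = 4500L, stringsAsFactors = FALSE)
  expect_true(mate_consistent(call, list(chrom = "chr1", start = 3000L,
                                         end = 3100L)))
  expect_false(mate_consistent(call, list(chrom = "chr1", start = 1e6,
                                          end = 1e6 + 100L)))
  expect_false(mate_consistent(call, list(chrom = "chr2", start = 3000L,
                                          end = 3100L)))
  expect_true(mate_consistent(call, NULL))  # unmapped mate: non-informative
})

test_that("place_mate finds mates on the circle and rejects distant mates", {
  loc <- toy_locus()
  call <- data.frame(chrom = "chr1", acceptor_start = 2500L,
                     donor_end = 4500L, transcript_id = "gA_t1",
                     i_up = 2L, i_down = 3L, stringsAsFactors = FALSE)
  exons <- transcript_exons(loc$models, "gA_t1")
  S <- spliced_seq(loc$genome, exons[2:3, ])
  ## a mate crossing the back-splice itself (rotation of the circle)
  mate_circ <- paste0(substring(S, nchar(S) - 49L, nchar(S)),
                      substring(S, 1L, 50L))
  pm <- place_mate(revcomp(mate_circ), call, loc$genome, loc$models)
  expect_true(mate_consistent(call, pm))
  ## a mate from the other gene
  mate_far <- substring(loc$genome[["chr1"]], 15001L, 15100L)
  pm2 <- place_mate(mate_far, call, loc$genome, loc$models)
  expect_false(mate_consistent(call, pm2))
})

test_that("aggregation counts fragments once and applies the support threshold", {
  one <- function(read_id, sample = "s1", mate = 1L)
    data.frame(chrom = "chr1", acceptor_start = 100L, donor_end = 900L,
               strand = "+", gene_id = "g", transcript_id = "t",
               i_up = 1L, i_down = 2L, split = 40L, read_id = read_id,
               mate = mate, sample = sample, stringsAsFactors = FALSE)
  ## three supporting fragments
  calls <- aggregate_calls(rbind(one("a"), one("b"), one("c")))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$junction_reads, 3L)
  ## both mates of one fragment span the junction: counted once
  calls2 <- aggregate_calls(rbind(one("a", mate = 1L), one("a", mate = 2L),
                                  one("b")))
  expect_equal(calls2$junction_reads, 2L)
  ## a singleton is absent at min_support 2, present at 1
  expect_equal(nrow(aggregate_calls(one("a"), min_support = 2L)), 0L)
  expect_equal(nrow(aggregate_calls(one("a"), min_support = 1L)), 1L)
  ## per-cell absent, merged present
  percell <- rbind(one("a", sample = "cell1"), one("b", sample = "cell2"))
  expect_equal(nrow(aggregate_calls(percell[1L, ], min_support = 2L)), 0L)
  merged <- aggregate_calls(percell, min_support = 2L)
  expect_equal(merged$junction_reads, 2L)
  expect_equal(merged$n_samples, 2L)
})

test_that("caller recovers planted circles exactly on error-free simulation", {
  sim <- default_sim()
  res <- call_circrnas(sim$reads1, sim$reads2, sim$genome, sim$models)
  truth <- sim$truth$circ_truth
  expected <- truth[truth$recoverable_junction_reads >= 2L, ]
  key <- function(df) sort(paste(df$chrom, df$acceptor_start, df$donor_end))
  expect_identical(key(res$calls), key(expected))  # precision = recall = 1
  ## support counts match the truth table
  m <- merge(res$calls, truth,
             by = c("chrom", "acceptor_start", "donor_end"))
  expect_equal(m$junction_reads, m$recoverable_junction_reads)
})

test_that("every reported junction sequence occurs in its supporting reads", {
  sim <- default_sim()
  res <- call_circrnas(sim$reads1, sim$reads2, sim$genome, sim$models)
  all_seq <- c(sim$reads1$seq, sim$reads2$seq)
  for (i in seq_len(nrow(res$calls))) {
    cl <- res$calls[i, ]
    exons <- transcript_exons(sim$models, cl$transcript_id)
    blk <- exons$start >= cl$acceptor_start & exons$end <= cl$donor_end
    S <- spliced_seq(sim$genome, exons[blk, , drop = FALSE])
    jk <- paste0(substring(S, nchar(S) - 24L, nchar(S)),
                 substring(S, 1L, 25L))
    n <- sum(grepl(jk, all_seq, fixed = TRUE) |
               grepl(revcomp(jk), all_seq, fixed = TRUE))
    expect_gte(n, cl$junction_reads)
  }
})

test_that("calls are invariant to read-order permutation", {
  sim <- default_sim()
  res1 <- call_circrnas(sim$reads1, sim$reads2, sim$genome, sim$models)
  set.seed(99)
  perm <- sample.int(nrow(sim$reads1))
  res2 <- call_circrnas(sim$reads1[perm, ], sim$reads2[perm, ],
                        sim$genome, sim$models)
  expect_equal(res1$calls, res2$calls)
})

test_that("trans-splicing decoys and pure linear libraries give zero calls", {
  sim <- simulate_dataset(sim_config(seed = 13L, n_circ = 0L,
                                     n_trans_decoys = 25L, n_qc_fail = 0L,
                                     linear_depth = 30, ercc = NULL))
  res <- call_circrnas(sim$reads1, sim$reads2, sim$genome, sim$models)
  expect_equal(nrow(res$calls), 0L)
})

test_that("stage counts decrease monotonically through the filter cascade", {
  sim <- default_sim()
  res <- call_circrnas(sim$reads1, sim$reads2, sim$genome, sim$models)
  sc <- res$stage_counts
  expect_true(all(diff(sc[c("candidate_reads", "resolved_reads",
                            "mate_consistent_reads")]) <= 0))
  expect_lte(sc[["supported_calls"]], sc[["mate_consistent_reads"]])
})

test_that("caller works from ingested SAM anchor alignments", {
  loc <- toy_locus()
  rseq <- junction_read(loc$genome, loc$models, "gA_t1", 2L, 3L, k = 40L)
  reads1 <- mk_reads(c("j1", "j2"), c(rseq, rseq), mate = 1L)
  exons <- transcript_exons(loc$models, "gA_t1")
  S <- spliced_seq(loc$genome, exons[2:3, ])
  mate <- revcomp(substring(S, 1L, 100L))
  reads2 <- mk_reads(c("j1", "j2"), c(mate, mate), mate = 2L)
  ## anchor placements as an external aligner would report them
  ap <- extract_anchor_pairs(rbind(reads1, reads2))$anchors
  rows <- list()
  for (i in seq_len(nrow(ap))) {
    for (w in c("head", "tail")) {
      h <- align_anchor(ap[[w]][i], loc$genome)
      if (nrow(h) == 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = paste0(ap$read_id[i], "/", ap$mate[i]),
          which = w, chrom = h$chrom, start = h$start, strand = h$strand,
          n_mismatch = 0L, stringsAsFactors = FALSE)
    }
  }
  sam_hits <- do.call(rbind, rows)
  res <- call_circrnas(reads1, reads2, loc$genome, loc$models,
                       sam_hits = sam_hits)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$acceptor_start, 2500)
  expect_equal(res$calls$donor_end, 4500)
})
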