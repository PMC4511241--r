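# Shared fixtures and independent oracles for the test suite.

# reverse complement written independently of the package
rc_oracle_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# A hand-laid locus: one 5-exon plus-strand transcript and one 3-exon
# minus-strand transcript on a seeded 30 kb chromosome.
toy_locus <- function(seed = 7L) {
  set.seed(seed)
  genome <- c(chr1 = rand_seq(30000))
  models <- as_gene_models(data.frame(
    chrom = "chr1",
    start = c(1000, 2500, 4200, 6000, 8000,  15000, 18000, 21000),
    end   = c(1300, 2800, 4500, 6350, 8300,  15400, 18350, 21400),
    strand = c(rep("+", 5), rep("-", 3)),
    gene_id = c(rep("gA", 5), rep("gB", 3)),
    transcript_id = c(rep("gA_t1", 5), rep("gB_t1", 3)),
    stringsAsFactors = FALSE
  ))
  list(genome = genome, models = models)
}

# Build a back-splice junction read from exon block i..j (transcript order)
# of a transcript: k bases from the donor side followed by L - k from the
# acceptor side.
junction_read <- function(genome, models, transcript_id, i, j, k, L = 100L) {
  exons <- transcript_exons(models, transcript_id)
  S <- spliced_seq(genome, exons[i:j, , drop = FALSE])
  nS <- nchar(S)
  paste0(substring(S, nS - k + 1L, nS), substring(S, 1L, L - k))
}

mk_reads <- function(ids, seqs, mate = 1L, qual_char = "I") {
  data.frame(read_id = ids, seq = seqs,
             qual = strrep(qual_char, nchar(seqs)),
             mate = as.integer(mate), stringsAsFactors = FALSE)
}

# Independent all-offset brute-force scan used as the aligner oracle.
brute_force_anchor_scan <- function(seq, genome) {
  k <- nchar(seq)
  hits <- list()
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    n <- nchar(g)
    if (n < k) next
    offs <- substring(g, 1:(n - k + 1L), k:n)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else rc_oracle_str(seq)
      at <- which(offs == q)
      if (length(at)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = at - 1L, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# Full-DP local alignment oracle for the RC finder, built on
# Biostrings::pairwiseAlignment with the same scoring and the same greedy
# mask-and-repeat reporting protocol (engine differs, protocol identical).
rc_finder_oracle <- function(up_seq, down_seq, scoring = rc_scoring()) {
  mat <- matrix(scoring$mismatch, 5, 5,
                dimnames = list(c("A", "C", "G", "T", "N"),
                                c("A", "C", "G", "T", "N")))
  diag(mat) <- scoring$match
  mat["N", "N"] <- scoring$mismatch
  subject <- rc_oracle_str(up_seq)
  query <- down_seq
  up_len <- nchar(up_seq)
  floor_score <- scoring$word_size * scoring$match
  out <- list()
  for (iter in seq_len(scoring$max_pairs)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    sc <- Biostrings::score(pa)
    if (sc < floor_score) break
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    cols_p <- strsplit(ap, "", fixed = TRUE)[[1L]]
    cols_s <- strsplit(as_, "", fixed = TRUE)[[1L]]
    is_match <- cols_p == cols_s & cols_p %in% c("A", "C", "G", "T")
    runs <- rle(is_match)
    max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    aln_len <- length(cols_p)
    qs <- IRanges::start(Biostrings::pattern(pa))
    qe <- IRanges::end(Biostrings::pattern(pa))
    ss <- IRanges::start(Biostrings::subject(pa))
    se <- IRanges::end(Biostrings::subject(pa))
    if (aln_len >= scoring$min_len && max_run >= scoring$word_size) {
      out[[length(out) + 1L]] <- data.frame(
        up_start = up_len - se + 1L, up_end = up_len - ss + 1L,
        down_start = qs, down_end = qe, aln_len = aln_len, score = sc,
        max_match_run = max_run)
    }
    substr(query, qs, qe) <- strrep("N", qe - qs + 1L)
    substr(subject, ss, se) <- strrep("N", se - ss + 1L)
  }
  if (!length(out)) {
    return(data.frame(up_start = integer(0), up_end = integer(0),
                      down_start = integer(0), down_end = integer(0),
                      aln_len = integer(0), score = numeric(0),
                      max_match_run = integer(0)))
  }
  do.call(rbind, out)
}

# Agreement between two sets of reported RC alignments: same count, same
# scores, and mutually overlapping footprints. Exact endpoints are not
# compared because local-alignment optima need not be unique (equal-score
# flank extensions shift endpoints without changing the alignment found).
rc_sets_agree <- function(mine, oracle) {
  n_o <- if (is.null(oracle)) 0L else nrow(oracle)
  if (nrow(mine) != n_o) return(FALSE)
  if (n_o == 0L) return(TRUE)
  mine <- mine[order(mine$score, mine$up_start), , drop = FALSE]
  oracle <- oracle[order(oracle$score, oracle$up_start), , drop = FALSE]
  all(mine$score == oracle$score) &&
    all(pmax(mine$up_start, oracle$up_start) <=
          pmin(mine$up_end, oracle$up_end)) &&
    all(pmax(mine$down_start, oracle$down_start) <=
          pmin(mine$down_end, oracle$down_end))
}

# One default simulated dataset shared across test files (built once per
# test file that asks for it).
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(seed = 1L, ercc = NULL,
                                            n_qc_fail = 0L,
                                            n_trans_decoys = 10L,
                                            linear_depth = 20))
    cache
  }
})
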