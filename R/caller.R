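## Back-splice junction calling.
##
## A read spanning a back-splice junction carries, 5' to 3', the end of a
## downstream exon (the donor) followed by the start of an upstream exon
## (the acceptor) of the same transcript: the two exon termini appear in
## reversed genomic order. The caller therefore (1) pairs head/tail anchor
## hits on the same chromosome and strand in reversed order within a bounded
## span, (2) resolves each candidate against annotated exon boundaries,
## requiring an exon pair of a single transcript whose circularised sequence
## explains the whole read with a split exactly at the boundaries, (3)
## checks that the mate falls within the circle span, and (4) aggregates
## per-read junctions into calls with a minimum junction-read support.

#' Pair head/tail anchor hits into candidate junctions
#'
#' A candidate requires both anchors of one read on the same chromosome and
#' strand, in reversed genomic order (on a plus-strand placement the read
#' prefix maps downstream of the read suffix: `tail_start < head_start`;
#' on a minus-strand placement the inequality flips), with the outermost
#' span below `max_span`.
#'
#' @param head_hits,tail_hits data.frames of anchor placements for the head
#'   and tail anchors, with columns `read_id`, `chrom`, `start`, `strand`.
#' @param max_span maximum genomic span in bp (default 100 kb).
#' @param anchor_len anchor length in bp.
#' @return data.frame of candidates: `read_id`, `chrom`, `strand`,
#'   `head_start`, `tail_start`, `span`.
#' @export
pair_candidates <- function(head_hits, tail_hits, max_span = 1e5,
                            anchor_len = ANCHOR_LEN) {
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), head_start = integer(0),
                      tail_start = integer(0), span = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(head_hits) == 0L || nrow(tail_hits) == 0L) return(empty)
  m <- merge(
    data.frame(read_id = head_hits$read_id, chrom = head_hits$chrom,
               strand = head_hits$strand, head_start = head_hits$start,
               stringsAsFactors = FALSE),
    data.frame(read_id = tail_hits$read_id, chrom = tail_hits$chrom,
               strand = tail_hits$strand, tail_start = tail_hits$start,
               stringsAsFactors = FALSE),
    by = c("read_id", "chrom", "strand")
  )
  if (nrow(m) == 0L) return(empty)
  reversed <- ifelse(m$strand == "+",
                     m$tail_start < m$head_start,
                     m$head_start < m$tail_start)
  span <- pmax(m$head_start, m$tail_start) + anchor_len -
    pmin(m$head_start, m$tail_start)
  keep <- reversed & span < max_span
  out <- m[keep, c("read_id", "chrom", "strand", "head_start", "tail_start"),
           drop = FALSE]
  out$span <- span[keep]
  rownames(out) <- NULL
  out
}

## Per-transcript summary used to shortlist transcripts for a candidate.
tx_index <- function(models) {
  idx <- attr(models, "tx_index")
  if (!is.null(idx)) return(idx)
  tid <- unique(models$transcript_id)
  first <- match(tid, models$transcript_id)
  idx <- data.frame(
    transcript_id = tid,
    gene_id = models$gene_id[first],
    chrom = models$chrom[first],
    strand = models$strand[first],
    start = vapply(tid, function(t) min(models$start[models$transcript_id == t]),
                   numeric(1)),
    end = vapply(tid, function(t) max(models$end[models$transcript_id == t]),
                 numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(idx) <- NULL
  idx
}

## Count mismatches between two equal-length strings.
str_mismatches <- function(a, b) {
  if (a == b) return(0L)
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Resolve a candidate junction against annotated exon boundaries
#'
#' Searches transcripts overlapping both anchor hits for an exon pair
#' (indices i <= j in transcript order, both exons of one transcript) such
#' that the read splits at the back-splice: its 5' part ends exactly at the
#' donor boundary of exon j and its 3' part starts exactly at the acceptor
#' boundary of exon i, with at most `max_mismatch` substitutions over the
#' whole read. Both read orientations are tried (unstranded protocol).
#' Single-exon circles (i == j) are allowed. A read explained by more than
#' one distinct junction is dropped as ambiguous.
#'
#' @param cand one-row candidate from [pair_candidates()].
#' @param read_seq the full read sequence.
#' @param genome named character vector of chromosome sequences.
#' @param models a `gene_models` table.
#' @param max_mismatch substitution budget over the full split read.
#' @return one-row data.frame call (`chrom`, `acceptor_start`, `donor_end`,
#'   `strand`, `gene_id`, `transcript_id`, `i_up`, `i_down`, `split`), or
#'   `NULL` if no transcript explains the read or the read is ambiguous.
#' @export
resolve_junction <- function(cand, read_seq, genome, models,
                             max_mismatch = 2L) {
  idx <- tx_index(models)
  lo <- min(cand$head_start, cand$tail_start)
  hi <- max(cand$head_start, cand$tail_start) + ANCHOR_LEN
  tx <- idx[idx$chrom == cand$chrom & idx$start <= lo & idx$end >= hi, ,
            drop = FALSE]
  if (nrow(tx) == 0L) return(NULL)
  L <- nchar(read_seq)
  orientations <- unique(c(read_seq, revcomp(read_seq)))
  found <- list()
  for (ti in seq_len(nrow(tx))) {
    exons <- transcript_exons(models, tx$transcript_id[ti])
    n <- nrow(exons)
    for (i in seq_len(n)) {
      for (j in i:n) {
        block <- exons[i:j, , drop = FALSE]
        bspan_lo <- min(block$start)
        bspan_hi <- max(block$end)
        if (bspan_lo > lo || bspan_hi < hi) next  # anchors outside block
        S <- spliced_seq(genome, block)
        nS <- nchar(S)
        for (r in orientations) {
          for (k in seq_len(L - 1L)) {
            if (k > nS || (L - k) > nS) next
            jseq <- paste0(substring(S, nS - k + 1L, nS),
                           substring(S, 1L, L - k))
            if (str_mismatches(r, jseq) <= max_mismatch) {
              found[[length(found) + 1L]] <- data.frame(
                chrom = cand$chrom, acceptor_start = bspan_lo,
                donor_end = bspan_hi, strand = exons$strand[1L],
                gene_id = tx$gene_id[ti],
                transcript_id = tx$transcript_id[ti],
                i_up = i, i_down = j, split = k,
                stringsAsFactors = FALSE)
              break  # one split suffices per (block, orientation)
            }
          }
        }
      }
    }
  }
  if (!length(found)) return(NULL)
  calls <- do.call(rbind, found)
  key <- paste(calls$chrom, calls$acceptor_start, calls$donor_end)
  if (length(unique(key)) > 1L) return(NULL)  # ambiguous read
  calls[1L, , drop = FALSE]
}

#' Mate-consistency check for a resolved junction read
#'
#' The mate of a junction read must come from inside the circle: it passes
#' if it is unmapped (non-informative) or maps within the circle span
#' `[acceptor_start, donor_end]` on the call's chromosome.
#'
#' @param call one-row call from [resolve_junction()].
#' @param mate_interval `NULL` for an unmapped mate, else a list/one-row
#'   data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return logical.
#' @export
mate_consistent <- function(call, mate_interval) {
  if (is.null(mate_interval)) return(TRUE)
  mate_interval$chrom == call$chrom &&
    mate_interval$start >= call$acceptor_start &&
    mate_interval$end <= call$donor_end
}

#' Place a mate read relative to a circRNA call
#'
#' First tries to place the mate on the circularised exon-block sequence
#' (its rotations, both orientations); a circle placement is inside the span
#' by construction. Otherwise places the mate's head anchor on the genome.
#' Returns `NULL` when the mate cannot be placed (unmapped).
#'
#' @param mate_seq the mate's sequence.
#' @param call one-row call from [resolve_junction()].
#' @param genome named character vector of chromosome sequences.
#' @param models a `gene_models` table.
#' @param max_hits multimap cap for the fallback genome placement.
#' @return list with `chrom`, `start`, `end`, or `NULL` if unplaced.
#' @export
place_mate <- function(mate_seq, call, genome, models, max_hits = 10L) {
  exons <- transcript_exons(models, call$transcript_id)
  block <- exons[call$i_up:call$i_down, , drop = FALSE]
  S <- spliced_seq(genome, block)
  S2 <- paste0(S, S)  # rotations of the circle
  for (q in unique(c(mate_seq, revcomp(mate_seq)))) {
    if (nchar(q) <= nchar(S2) && grepl(q, S2, fixed = TRUE)) {
      return(list(chrom = call$chrom, start = call$acceptor_start,
                  end = call$donor_end))
    }
  }
  head_anchor <- substring(mate_seq, 1L, ANCHOR_LEN)
  if (nchar(head_anchor) < ANCHOR_LEN) return(NULL)
  hits <- align_anchor(head_anchor, genome, max_mismatch = 0L,
                       max_hits = max_hits)
  if (nrow(hits) == 0L) return(NULL)
  ## prefer a placement compatible with the call, otherwise report the first
  inside <- hits$chrom == call$chrom & hits$start >= call$acceptor_start &
    (hits$start + ANCHOR_LEN) <= call$donor_end
  h <- if (any(inside)) hits[which(inside)[1L], ] else hits[1L, ]
  list(chrom = h$chrom, start = h$start, end = h$start + nchar(mate_seq))
}

#' Aggregate per-read junctions into supported circRNA calls
#'
#' Groups identical junctions (chromosome, acceptor start, donor end,
#' strand); `junction_reads` counts supporting fragments, a fragment being
#' counted once even when both of its mates span the junction. Groups below
#' `min_support` are not reported. Per-sample support is recorded so that
#' several cells can be merged into one calling run.
#'
#' @param per_read data.frame of per-read calls with columns `read_id`
#'   (fragment identifier shared by the two mates), `sample`, and the call
#'   columns of [resolve_junction()].
#' @param min_support minimum junction reads per reported call (default 2).
#' @return data.frame of calls sorted by coordinates, with `junction_reads`,
#'   `n_samples` and `samples` (comma-separated ids).
#' @export
aggregate_calls <- function(per_read, min_support = 2L) {
  empty <- data.frame(chrom = character(0), acceptor_start = integer(0),
                      donor_end = integer(0), strand = character(0),
                      gene_id = character(0), transcript_id = character(0),
                      junction_reads = integer(0), n_samples = integer(0),
                      samples = character(0), stringsAsFactors = FALSE)
  if (is.null(per_read) || nrow(per_read) == 0L) return(empty)
  if (is.null(per_read$sample)) per_read$sample <- "sample1"
  key <- paste(per_read$chrom, per_read$acceptor_start, per_read$donor_end,
               per_read$strand, sep = "\r")
  ## one fragment supports a junction once
  frag <- !duplicated(paste(key, per_read$sample, per_read$read_id))
  pr <- per_read[frag, , drop = FALSE]
  key <- key[frag]
  groups <- split(seq_len(nrow(pr)), key)
  rows <- lapply(groups, function(ii) {
    g <- pr[ii, , drop = FALSE]
    data.frame(chrom = g$chrom[1L], acceptor_start = g$acceptor_start[1L],
               donor_end = g$donor_end[1L], strand = g$strand[1L],
               gene_id = g$gene_id[1L], transcript_id = g$transcript_id[1L],
               junction_reads = nrow(g),
               n_samples = length(unique(g$sample)),
               samples = paste(sort(unique(g$sample)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  calls <- calls[calls$junction_reads >= min_support, , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$acceptor_start, calls$donor_end), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Call circRNAs from paired-end reads
#'
#' Runs the full caller on QC-passed read pairs: anchor extraction and
#' placement (built-in matcher or ingested SAM hits), reversed-order
#' candidate pairing, resolution against annotated exon boundaries of a
#' single transcript, mate-consistency filtering and support aggregation.
#'
#' @param reads1,reads2 row-matched read tables (from [read_fastq()] or the
#'   simulator), already quality-filtered.
#' @param genome named character vector of chromosome sequences.
#' @param models a `gene_models` table.
#' @param sample_id sample label recorded in the calls.
#' @param max_span maximum junction span in bp (default 100 kb).
#' @param min_support minimum junction reads per reported call.
#' @param max_mismatch substitution budget for split-read verification.
#' @param anchor_mismatch substitution budget for anchor placement.
#' @param max_hits anchor multimap cap.
#' @param min_read_len anchor-extraction length cutoff.
#' @param mate_filter apply the mate-consistency filter (default TRUE).
#' @param dedupe drop duplicate fragments with identical junction, split
#'   offset and mate placement (default FALSE).
#' @param sam_hits optional data.frame from [ingest_sam()] replacing the
#'   built-in anchor matcher.
#' @return list with `calls` (aggregated), `evidence` (per-read calls) and
#'   `stage_counts` (named counts through the filter cascade).
#' @export
call_circrnas <- function(reads1, reads2, genome, models,
                          sample_id = "sample1",
                          max_span = 1e5, min_support = 2L,
                          max_mismatch = 2L, anchor_mismatch = 0L,
                          max_hits = 10L, min_read_len = 60L,
                          mate_filter = TRUE, dedupe = FALSE,
                          sam_hits = NULL) {
  reads <- rbind(reads1, reads2)
  mate_of <- stats::setNames(
    c(reads2$seq, reads1$seq),
    paste0(c(reads1$read_id, reads2$read_id), "/", c(reads1$mate, reads2$mate))
  )
  stage <- c(input_pairs = nrow(reads1))

  ap <- extract_anchor_pairs(reads, min_len = min_read_len)
  anchors <- ap$anchors
  stage["anchored_reads"] <- nrow(anchors)

  if (is.null(sam_hits)) {
    useq <- unique(c(anchors$head, anchors$tail))
    hits <- align_anchor_batch(useq, genome, max_mismatch = anchor_mismatch,
                               max_hits = max_hits)
    hit_of <- function(which_seq) {
      i <- match(which_seq, useq)
      sel <- hits[hits$anchor %in% i, , drop = FALSE]
      ## expand back to reads sharing the same anchor sequence
      out <- merge(data.frame(anchor = i,
                              row = seq_along(which_seq)),
                   sel, by = "anchor")
      out
    }
    hh <- hit_of(paste0(anchors$head))
    th <- hit_of(paste0(anchors$tail))
    head_hits <- data.frame(read_id = paste0(anchors$read_id, "/",
                                             anchors$mate)[hh$row],
                            chrom = hh$chrom, start = hh$start,
                            strand = hh$strand, stringsAsFactors = FALSE)
    tail_hits <- data.frame(read_id = paste0(anchors$read_id, "/",
                                             anchors$mate)[th$row],
                            chrom = th$chrom, start = th$start,
                            strand = th$strand, stringsAsFactors = FALSE)
  } else {
    head_hits <- sam_hits[sam_hits$which == "head",
                          c("read_id", "chrom", "start", "strand")]
    tail_hits <- sam_hits[sam_hits$which == "tail",
                          c("read_id", "chrom", "start", "strand")]
  }

  cands <- pair_candidates(head_hits, tail_hits, max_span = max_span)
  stage["candidate_reads"] <- length(unique(cands$read_id))

  seq_of <- stats::setNames(reads$seq, paste0(reads$read_id, "/", reads$mate))
  resolved <- list()
  for (rid in unique(cands$read_id)) {
    rc <- cands[cands$read_id == rid, , drop = FALSE]
    rseq <- seq_of[[rid]]
    calls_r <- list()
    for (ci in seq_len(nrow(rc))) {
      cl <- resolve_junction(rc[ci, ], rseq, genome, models,
                             max_mismatch = max_mismatch)
      if (!is.null(cl)) calls_r[[length(calls_r) + 1L]] <- cl
    }
    if (!length(calls_r)) next
    cr <- unique(do.call(rbind, calls_r))
    ## distinct junctions from different candidate placements: ambiguous
    if (length(unique(paste(cr$chrom, cr$acceptor_start, cr$donor_end))) > 1L)
      next
    cl <- cr[1L, , drop = FALSE]
    cl$read_id <- sub("/[12]$", "", rid)
    cl$mate <- as.integer(sub("^.*/", "", rid))
    resolved[[length(resolved) + 1L]] <- cl
  }
  per_read <- if (length(resolved)) do.call(rbind, resolved) else NULL
  stage["resolved_reads"] <- if (is.null(per_read)) 0L else nrow(per_read)

  if (!is.null(per_read) && mate_filter) {
    ok <- vapply(seq_len(nrow(per_read)), function(i) {
      cl <- per_read[i, ]
      mseq <- mate_of[[paste0(cl$read_id, "/", cl$mate)]]
      if (is.null(mseq) || is.na(mseq)) return(TRUE)
      mate_consistent(cl, place_mate(mseq, cl, genome, models,
                                     max_hits = max_hits))
    }, logical(1))
    per_read <- per_read[ok, , drop = FALSE]
  }
  stage["mate_consistent_reads"] <- if (is.null(per_read)) 0L else nrow(per_read)

  if (!is.null(per_read) && dedupe && nrow(per_read)) {
    per_read <- per_read[!duplicated(
      paste(per_read$chrom, per_read$acceptor_start, per_read$donor_end,
            per_read$split)), , drop = FALSE]
  }
  if (!is.null(per_read)) per_read$sample <- sample_id

  calls <- aggregate_calls(per_read, min_support = min_support)
  stage["supported_calls"] <- nrow(calls)

  list(calls = calls, evidence = per_read, stage_counts = stage)
}
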