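## Anchor extraction and placement.
##
## Each sufficiently long read contributes a pair of 25-bp "anchors" (its
## first and last 25 bases). Anchors are placed on the genome as ungapped
## fixed-length hits on either strand, either by the built-in matcher (toy
## genomes) or by ingesting alignments produced by an external aligner (SAM).

ANCHOR_LEN <- 25L

#' Extract 25-bp anchor pairs from read termini
#'
#' Reads shorter than `min_len` are skipped (and counted): with a 60-bp
#' minimum, head and tail anchors are separated by at least 10 bp.
#'
#' @param reads data.frame of reads (from [read_fastq()]).
#' @param min_len minimum read length for anchor extraction.
#' @return list with `anchors`: data.frame of `read_id`, `head`, `tail`,
#'   `read_len`, `mate`; and `n_skipped`: number of too-short reads.
#' @export
extract_anchor_pairs <- function(reads, min_len = 60L) {
  len <- nchar(reads$seq)
  ok <- len >= min_len
  kept <- reads[ok, , drop = FALSE]
  klen <- len[ok]
  anchors <- data.frame(
    read_id = kept$read_id,
    head = substring(kept$seq, 1L, ANCHOR_LEN),
    tail = substring(kept$seq, klen - ANCHOR_LEN + 1L, klen),
    read_len = klen,
    mate = if (nrow(kept)) kept$mate else integer(0),
    stringsAsFactors = FALSE
  )
  list(anchors = anchors, n_skipped = sum(!ok))
}

#' Place one anchor sequence on a genome
#'
#' Reports every ungapped placement of the 25-bp anchor with at most
#' `max_mismatch` substitutions, on either strand (the protocol is
#' unstranded, so minus-strand placements match the reverse complement).
#' An anchor with more than `max_hits` placements is discarded as
#' multimapping-ambiguous (empty result).
#'
#' @param seq anchor sequence (character scalar).
#' @param genome named character vector of chromosome sequences.
#' @param max_mismatch maximum substitutions (0 = exact).
#' @param max_hits multimapping cap; more placements discard the anchor.
#' @return data.frame with `chrom`, `start` (0-based), `strand`,
#'   `n_mismatch`; zero rows if unplaced or ambiguous.
#' @export
align_anchor <- function(seq, genome, max_mismatch = 0L, max_hits = 10L) {
  hits <- align_anchor_batch(seq, genome, max_mismatch, max_hits)
  hits$anchor <- NULL
  hits
}

## Batch placement of many anchor sequences; returns one data.frame with an
## `anchor` column indexing into `seqs`. The multimap cap applies per anchor.
align_anchor_batch <- function(seqs, genome, max_mismatch = 0L,
                               max_hits = 10L) {
  empty <- data.frame(anchor = integer(0), chrom = character(0),
                      start = integer(0), strand = character(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)
  queries <- list(`+` = seqs, `-` = revcomp(seqs))
  out <- list()
  for (strand in names(queries)) {
    q <- queries[[strand]]
    searchable <- !grepl("N", q, fixed = TRUE)
    for (chrom in names(genome)) {
      subject <- Biostrings::DNAString(genome[[chrom]])
      if (max_mismatch == 0L && sum(searchable) > 1L) {
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(q[searchable]))
        mi <- Biostrings::matchPDict(pd, subject)
        n_per <- S4Vectors::elementNROWS(mi)
        idx <- rep(which(searchable), n_per)
        if (length(idx)) {
          out[[length(out) + 1L]] <- data.frame(
            anchor = idx, chrom = chrom,
            start = IRanges::start(unlist(mi)) - 1L,
            strand = strand, n_mismatch = 0L, stringsAsFactors = FALSE)
        }
      } else {
        for (i in which(searchable)) {
          m <- Biostrings::matchPattern(q[i], subject,
                                        max.mismatch = max_mismatch)
          if (length(m)) {
            nmm <- vapply(as.character(m), function(s) {
              sum(strsplit(s, "")[[1L]] != strsplit(q[i], "")[[1L]])
            }, integer(1), USE.NAMES = FALSE)
            out[[length(out) + 1L]] <- data.frame(
              anchor = i, chrom = chrom, start = IRanges::start(m) - 1L,
              strand = strand, n_mismatch = nmm, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  ## multimap cap: an anchor exceeding max_hits placements is ambiguous
  n_hits <- table(hits$anchor)
  ambiguous <- as.integer(names(n_hits)[n_hits > max_hits])
  hits <- hits[!(hits$anchor %in% ambiguous), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Ingest anchor alignments from a SAM file
#'
#' Records must be named `<read_id>/head` or `<read_id>/tail` (the two
#' conceptual anchor files). Unmapped records (FLAG 0x4) are skipped;
#' secondary alignments are kept.
#'
#' @param path path to a SAM file (with header).
#' @return data.frame with `read_id`, `which` (head/tail), `chrom`, `start`
#'   (0-based), `strand`, `n_mismatch` (NA when the aligner does not report
#'   it).
#' @export
ingest_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !bitwAnd(rec$flag, 4L)
  qname <- rec$qname[mapped]
  ok <- grepl("/(head|tail)$", qname)
  if (!all(ok))
    stop("SAM record name not of the form <read_id>/head or <read_id>/tail: ",
         qname[!ok][1L], call. = FALSE)
  data.frame(
    read_id = sub("/(head|tail)$", "", qname),
    which = sub("^.*/", "", qname),
    chrom = as.character(rec$rname[mapped]),
    start = rec$pos[mapped] - 1L,
    strand = ifelse(bitwAnd(rec$flag[mapped], 16L) > 0L, "-", "+"),
    n_mismatch = NA_integer_,
    stringsAsFactors = FALSE
  )
}
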