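## circRNA formation-feature analysis: flanking introns, repeat density,
## reverse-complementary (RC) sequence pairs between the flanking introns,
## and the summed distance of the nearest RC pair to the splice sites.
##
## Orientation convention for intron sequences: the upstream intron is
## extracted 5'-to-3' in transcript orientation so that its LAST base abuts
## the acceptor splice site; the downstream intron so that its FIRST base
## abuts the donor splice site. RC pairs are local alignments between the
## downstream intron (query) and the reverse complement of the upstream
## intron (subject), blastn-style.

#' RC-search scoring parameters
#'
#' Defaults follow the blastn parameterisation used for intron RC analysis:
#' word size 11, reward +2, penalty -3, gap open 5, gap extend 2; aligned
#' length at least 25 is reported.
#'
#' @param word_size exact-match seed length.
#' @param match,mismatch match reward and mismatch penalty (penalty given
#'   as a negative number).
#' @param gap_open,gap_extend gap penalties (positive); a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param min_len minimum aligned length reported (inclusive).
#' @param max_pairs cap on reported non-overlapping alignments.
#' @param max_dp_cells cell budget below which the search runs exact
#'   full-matrix dynamic programming; larger problems fall back to
#'   seed-windowed alignment around each shared word (blastn-style).
#' @param seed_window half-width in bp of the window cut around a seed
#'   cluster for the large-problem path.
#' @return list of class `rc_scoring`.
#' @export
rc_scoring <- function(word_size = 11L, match = 2, mismatch = -3,
                       gap_open = 5, gap_extend = 2, min_len = 25L,
                       max_pairs = 50L, max_dp_cells = 4.5e6,
                       seed_window = 500L) {
  structure(list(word_size = as.integer(word_size), match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_len = as.integer(min_len),
                 max_pairs = as.integer(max_pairs),
                 max_dp_cells = max_dp_cells,
                 seed_window = as.integer(seed_window)),
            class = "rc_scoring")
}

## Do two sequences share an exact k-mer?
shares_kmer <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(FALSE)
  ka <- unique(substring(a, 1:(na - k + 1L), k:na))
  kb <- unique(substring(b, 1:(nb - k + 1L), k:nb))
  ka <- ka[!grepl("N", ka, fixed = TRUE)]
  any(ka %in% kb)
}

## All (query_pos, subject_pos) pairs sharing an exact k-mer, capped.
seed_positions <- function(query, subject, k, cap = 2000L) {
  nq <- nchar(query); ns <- nchar(subject)
  if (nq < k || ns < k) return(NULL)
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  sk <- substring(subject, 1:(ns - k + 1L), k:ns)
  common <- setdiff(intersect(qk, sk), qk[grepl("N", qk, fixed = TRUE)])
  if (!length(common)) return(NULL)
  out <- list()
  for (w in common) {
    qp <- which(qk == w); sp <- which(sk == w)
    out[[length(out) + 1L]] <- expand.grid(q = qp, s = sp)
  }
  seeds <- do.call(rbind, out)
  if (nrow(seeds) > cap) seeds <- seeds[seq_len(cap), ]
  seeds
}

## Greedy exact search on (query, subject): repeated best local alignment
## with footprint masking; reports alignments meeting the length and
## perfect-core criteria. Coordinates are within the given strings.
greedy_rc_dp <- function(query, subject, scoring) {
  floor_score <- scoring$word_size * scoring$match
  out <- list()
  for (iter in seq_len(scoring$max_pairs)) {
    al <- .sw_local_align(query, subject, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend)
    if (al$score < floor_score) break
    if (al$aln_len >= scoring$min_len &&
        al$max_match_run >= scoring$word_size) {
      out[[length(out) + 1L]] <- data.frame(
        q_start = al$q_start, q_end = al$q_end, s_start = al$s_start,
        s_end = al$s_end, aln_len = al$aln_len, score = al$score,
        max_match_run = al$max_match_run)
    }
    substr(query, al$q_start, al$q_end) <-
      strrep("N", al$q_end - al$q_start + 1L)
    substr(subject, al$s_start, al$s_end) <-
      strrep("N", al$s_end - al$s_start + 1L)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## Seed-windowed search for problems above the DP cell budget: cluster
## shared-word seeds by diagonal, align a window around each cluster, pool
## and keep non-overlapping alignments by descending score.
windowed_rc_dp <- function(query, subject, scoring) {
  seeds <- seed_positions(query, subject, scoring$word_size)
  if (is.null(seeds)) return(NULL)
  seeds$diag <- seeds$q - seeds$s
  seeds <- seeds[order(seeds$diag, seeds$q), ]
  ## cluster: same stretch of diagonals, nearby query positions
  cl <- cumsum(c(TRUE, diff(seeds$diag) > 60L | diff(seeds$q) > 400L))
  pad <- scoring$seed_window
  found <- list()
  for (grp in split(seeds, cl)) {
    qlo <- max(1L, min(grp$q) - pad)
    qhi <- min(nchar(query), max(grp$q) + scoring$word_size + pad)
    slo <- max(1L, min(grp$s) - pad)
    shi <- min(nchar(subject), max(grp$s) + scoring$word_size + pad)
    hits <- greedy_rc_dp(substring(query, qlo, qhi),
                         substring(subject, slo, shi), scoring)
    if (!is.null(hits)) {
      hits$q_start <- hits$q_start + qlo - 1L
      hits$q_end <- hits$q_end + qlo - 1L
      hits$s_start <- hits$s_start + slo - 1L
      hits$s_end <- hits$s_end + slo - 1L
      found[[length(found) + 1L]] <- hits
    }
  }
  if (!length(found)) return(NULL)
  pool <- do.call(rbind, found)
  ## overlapping windows can rediscover an alignment: keep non-overlapping
  ## footprints by descending score
  pool <- pool[order(-pool$score, pool$q_start), ]
  keep <- rep(TRUE, nrow(pool))
  for (i in seq_len(nrow(pool))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(pool)) > i)
    if (!length(later)) break
    ovl <- pmin(pool$q_end[later], pool$q_end[i]) -
      pmax(pool$q_start[later], pool$q_start[i]) >= 0 |
      pmin(pool$s_end[later], pool$s_end[i]) -
      pmax(pool$s_start[later], pool$s_start[i]) >= 0
    keep[later[ovl]] <- FALSE
  }
  pool <- pool[keep, , drop = FALSE]
  if (nrow(pool) > scoring$max_pairs)
    pool <- pool[seq_len(scoring$max_pairs), , drop = FALSE]
  pool
}

#' Find reverse-complementary sequence pairs between two flanking introns
#'
#' Searches for local alignments between the downstream intron and the
#' reverse complement of the upstream intron under the configured scoring,
#' gated on an exact `word_size`-mer seed (alignments lacking a perfect
#' seed-length core are not reported, mirroring seeded search). The single
#' best alignment is taken, its footprint masked, and the search repeated,
#' yielding non-overlapping pairs with aligned length at least `min_len`.
#' Problems within `max_dp_cells` run this greedy search over the full
#' dynamic-programming matrix (exact); larger intron pairs are searched in
#' windows around each cluster of shared seed words.
#'
#' @param up_seq upstream intron sequence, transcript orientation (its last
#'   base abuts the acceptor splice site).
#' @param down_seq downstream intron sequence, transcript orientation (its
#'   first base abuts the donor splice site).
#' @param scoring an [rc_scoring()].
#' @return data.frame with one row per RC pair: `up_start`, `up_end`
#'   (1-based inclusive, in `up_seq`), `down_start`, `down_end` (in
#'   `down_seq`), `aln_len`, `score`, `max_match_run`.
#' @export
find_rc_pairs <- function(up_seq, down_seq, scoring = rc_scoring()) {
  empty <- data.frame(up_start = integer(0), up_end = integer(0),
                      down_start = integer(0), down_end = integer(0),
                      aln_len = integer(0), score = numeric(0),
                      max_match_run = integer(0))
  stopifnot_named("intron sequences must be non-empty" =
                    nchar(up_seq) > 0L && nchar(down_seq) > 0L)
  subject <- revcomp(up_seq)   # blastn: upstream intron as subject
  query <- down_seq
  up_len <- nchar(up_seq)
  if (!shares_kmer(query, subject, scoring$word_size)) return(empty)
  n_cells <- as.numeric(nchar(query)) * nchar(subject)
  hits <- if (n_cells <= scoring$max_dp_cells)
    greedy_rc_dp(query, subject, scoring)
  else
    windowed_rc_dp(query, subject, scoring)
  if (is.null(hits)) return(empty)
  pairs <- data.frame(
    up_start = up_len - hits$s_end + 1L,
    up_end = up_len - hits$s_start + 1L,
    down_start = hits$q_start, down_end = hits$q_end,
    aln_len = hits$aln_len, score = hits$score,
    max_match_run = hits$max_match_run)
  rownames(pairs) <- NULL
  pairs
}

#' Flanking introns of a circRNA call
#'
#' Identifies the intron immediately upstream (transcript order) of the
#' circle's acceptor exon and immediately downstream of its donor exon —
#' the two introns removed by the back-splice — plus the lengths of all
#' other introns of the same transcript. A flank is absent (NULL) when the
#' circle starts at the transcript's first exon or ends at its last.
#'
#' @param call one-row call (needs `chrom`, `acceptor_start`, `donor_end`,
#'   `transcript_id`).
#' @param models a `gene_models` table.
#' @return list of class `flanking_introns`: `upstream`, `downstream` (each
#'   NULL or a list with `chrom`, `start`, `end` (0-based half-open),
#'   `length`, `strand`), `other_lengths`, `i_up`, `i_down`, `n_exons`.
#' @export
flanking_introns <- function(call, models) {
  exons <- transcript_exons(models, call$transcript_id)
  n <- nrow(exons)
  in_block <- exons$start >= call$acceptor_start & exons$end <= call$donor_end
  if (!any(in_block))
    stop("call does not match exons of transcript ", call$transcript_id,
         call. = FALSE)
  i_up <- min(which(in_block))
  i_down <- max(which(in_block))
  strand <- exons$strand[1L]
  intron_at <- function(t) {  # intron between transcript-order exons t, t+1
    if (strand == "+") {
      s <- exons$end[t]; e <- exons$start[t + 1L]
    } else {
      s <- exons$end[t + 1L]; e <- exons$start[t]
    }
    list(chrom = exons$chrom[1L], start = s, end = e, length = e - s,
         strand = strand)
  }
  introns <- if (n > 1L) lapply(seq_len(n - 1L), intron_at) else list()
  upstream <- if (i_up > 1L) introns[[i_up - 1L]] else NULL
  downstream <- if (i_down < n) introns[[i_down]] else NULL
  flank_idx <- c(if (i_up > 1L) i_up - 1L, if (i_down < n) i_down)
  other <- setdiff(seq_along(introns), flank_idx)
  structure(list(upstream = upstream, downstream = downstream,
                 other_lengths = vapply(introns[other], `[[`, numeric(1),
                                        "length"),
                 i_up = i_up, i_down = i_down, n_exons = n),
            class = "flanking_introns")
}

## Extract a flanking intron's sequence in transcript orientation.
intron_seq <- function(genome, intron) {
  s <- substring(genome[[intron$chrom]], intron$start + 1L, intron$end)
  if (intron$strand == "-") s <- revcomp(s)
  s
}

## Map a 1-based segment of an intron sequence (transcript orientation)
## back to a 0-based half-open genomic interval.
intron_seg_to_genomic <- function(intron, seg_start, seg_end) {
  if (intron$strand == "+") {
    c(start = intron$start + seg_start - 1L, end = intron$start + seg_end)
  } else {
    c(start = intron$end - seg_end, end = intron$end - seg_start + 1L)
  }
}

#' Find RC pairs between the flanking introns of a circRNA call
#'
#' Convenience wrapper: extracts the two flanking intron sequences in
#' transcript orientation, runs [find_rc_pairs()], and attaches genomic
#' coordinates to each segment.
#'
#' @param call one-row circRNA call.
#' @param models a `gene_models` table.
#' @param genome named character vector of chromosome sequences.
#' @param scoring an [rc_scoring()].
#' @return list with `pairs` (RC pairs, plus genomic `up_gstart`/`up_gend`/
#'   `down_gstart`/`down_gend`), `flanks` (the [flanking_introns()] result),
#'   or pairs with zero rows when a flank is absent.
#' @export
call_rc_pairs <- function(call, models, genome, scoring = rc_scoring()) {
  fl <- flanking_introns(call, models)
  empty <- find_rc_pairs("ACGT", "TTTT", scoring)[0, ]
  if (is.null(fl$upstream) || is.null(fl$downstream))
    return(list(pairs = empty, flanks = fl))
  up <- intron_seq(genome, fl$upstream)
  down <- intron_seq(genome, fl$downstream)
  pairs <- find_rc_pairs(up, down, scoring)
  if (nrow(pairs)) {
    gu <- t(vapply(seq_len(nrow(pairs)), function(i) {
      intron_seg_to_genomic(fl$upstream, pairs$up_start[i], pairs$up_end[i])
    }, numeric(2)))
    gd <- t(vapply(seq_len(nrow(pairs)), function(i) {
      intron_seg_to_genomic(fl$downstream, pairs$down_start[i],
                            pairs$down_end[i])
    }, numeric(2)))
    pairs$up_gstart <- gu[, 1L]; pairs$up_gend <- gu[, 2L]
    pairs$down_gstart <- gd[, 1L]; pairs$down_gend <- gd[, 2L]
  }
  list(pairs = pairs, flanks = fl)
}

#' Classify a circRNA by RC content of its flanking introns
#'
#' `NonRC` when the flanking introns share no qualifying RC pair;
#' `RC-repeats` when at least one pair has a segment overlapping an
#' annotated repeat element; `RC-Nonrepeats` otherwise.
#'
#' @param rc_pairs RC pairs with genomic coordinates (from
#'   [call_rc_pairs()]).
#' @param repeats repeat track data.frame (`chrom`, `start`, `end`,
#'   `family`), possibly empty or NULL.
#' @param chrom chromosome of the call.
#' @param min_overlap minimum bp overlap for a segment to count as repeat.
#' @return one of `"NonRC"`, `"RC-repeats"`, `"RC-Nonrepeats"`.
#' @export
classify_rc <- function(rc_pairs, repeats, chrom, min_overlap = 1L) {
  if (is.null(rc_pairs) || nrow(rc_pairs) == 0L) return("NonRC")
  if (is.null(repeats) || nrow(repeats) == 0L) return("RC-Nonrepeats")
  rr <- repeats[repeats$chrom == chrom, , drop = FALSE]
  overlaps <- function(s, e) {
    any(pmin(e, rr$end) - pmax(s, rr$start) >= min_overlap)
  }
  for (i in seq_len(nrow(rc_pairs))) {
    if (overlaps(rc_pairs$up_gstart[i], rc_pairs$up_gend[i]) ||
        overlaps(rc_pairs$down_gstart[i], rc_pairs$down_gend[i]))
      return("RC-repeats")
  }
  "RC-Nonrepeats"
}

#' Distance of RC pairs to the circRNA splice sites
#'
#' For each pair, the distance from the upstream segment to the acceptor
#' splice site plus the distance from the downstream segment to the donor
#' splice site (both along the intron, in bp; 0 when both segments abut
#' their splice sites). The nearest pair is the minimum over pairs.
#'
#' @param rc_pairs RC pairs from [find_rc_pairs()]/[call_rc_pairs()].
#' @param up_len length of the upstream intron in bp.
#' @return list with `distances` (per pair) and `nearest` (min, or NA when
#'   there are no pairs).
#' @export
rc_distance <- function(rc_pairs, up_len) {
  if (is.null(rc_pairs) || nrow(rc_pairs) == 0L)
    return(list(distances = numeric(0), nearest = NA_real_))
  d <- (up_len - rc_pairs$up_end) + (rc_pairs$down_start - 1)
  list(distances = d, nearest = min(d))
}

#' Repeat-element density over an intron
#'
#' @param intron list with `chrom`, `start`, `end` (0-based half-open).
#' @param repeats repeat track data.frame, possibly empty or NULL.
#' @param family repeat family to count (e.g. "SINE"); NULL counts all.
#' @return repeats per kb (count of overlapping intervals / intron kb).
#' @export
repeat_density <- function(intron, repeats, family = NULL) {
  len_kb <- (intron$end - intron$start) / 1000
  stopifnot_named("intron length must be > 0" = len_kb > 0)
  if (is.null(repeats) || nrow(repeats) == 0L) return(0)
  rr <- repeats[repeats$chrom == intron$chrom, , drop = FALSE]
  if (!is.null(family)) rr <- rr[rr$family == family, , drop = FALSE]
  n <- sum(pmin(intron$end, rr$end) - pmax(intron$start, rr$start) > 0L)
  n / len_kb
}

#' Formation-feature table for a set of circRNA calls
#'
#' Per call: flanking intron lengths, the median length of the transcript's
#' other introns, per-family repeat densities over the flanks, RC
#' classification and the nearest RC-pair distance.
#'
#' @param calls data.frame of calls (from [aggregate_calls()]).
#' @param models a `gene_models` table.
#' @param genome named character vector of chromosome sequences.
#' @param repeats optional repeat track.
#' @param scoring an [rc_scoring()].
#' @return data.frame with one row per call.
#' @export
circ_features <- function(calls, models, genome, repeats = NULL,
                          scoring = rc_scoring()) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    rc <- call_rc_pairs(call, models, genome, scoring)
    fl <- rc$flanks
    up_len <- if (is.null(fl$upstream)) NA_real_ else fl$upstream$length
    down_len <- if (is.null(fl$downstream)) NA_real_ else fl$downstream$length
    dens <- function(intron, fam) {
      if (is.null(intron)) NA_real_ else repeat_density(intron, repeats, fam)
    }
    nearest <- if (is.null(fl$upstream)) NA_real_
               else rc_distance(rc$pairs, fl$upstream$length)$nearest
    data.frame(
      chrom = call$chrom, acceptor_start = call$acceptor_start,
      donor_end = call$donor_end, strand = call$strand,
      gene_id = call$gene_id, transcript_id = call$transcript_id,
      upstream_intron_len = up_len, downstream_intron_len = down_len,
      median_other_intron_len = if (length(fl$other_lengths))
        stats::median(fl$other_lengths) else NA_real_,
      n_rc_pairs = nrow(rc$pairs),
      rc_class = classify_rc(rc$pairs, repeats, call$chrom),
      rc_nearest_distance = nearest,
      sine_density_up = dens(fl$upstream, "SINE"),
      line_density_up = dens(fl$upstream, "LINE"),
      ltr_density_up = dens(fl$upstream, "LTR"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
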