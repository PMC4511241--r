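## Read quality control: adaptor / poly(A) trimming and per-read filters.
##
## Filters implemented (defaults in qc_config()):
##   lowqual  fraction of bases with Phred <= 5 is >= 50%
##   tooN     fraction of undetermined bases (N) > 10%
##   AT       A+T content > 80% (artifactual second-strand products)
##   short    trimmed length < 60 bp (downstream 25-bp anchor extraction
##            needs both termini plus a gap)
## A pair is dropped if either mate is dropped.

#' QC configuration
#'
#' @param min_frac_lowqual_to_drop drop when at least this fraction of bases
#'   is at or below `lowqual_threshold`.
#' @param lowqual_threshold Phred value treated as "low quality".
#' @param max_frac_N maximum tolerated fraction of N bases (exclusive).
#' @param max_AT_frac maximum tolerated A+T fraction (exclusive).
#' @param polyA_min_run minimum homopolymer run length trimmed as an
#'   artificial poly(A)/poly(T) tail.
#' @param min_len minimum read length after trimming; shorter reads are
#'   dropped (anchor extraction precondition).
#' @param adaptors character vector of adaptor sequences to trim.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(min_frac_lowqual_to_drop = 0.50,
                      lowqual_threshold = 5L,
                      max_frac_N = 0.10,
                      max_AT_frac = 0.80,
                      polyA_min_run = 24L,
                      min_len = 60L,
                      adaptors = character(0)) {
  stopifnot_named(
    "fractions must lie in [0,1]" =
      all(c(min_frac_lowqual_to_drop, max_frac_N, max_AT_frac) >= 0) &&
      all(c(min_frac_lowqual_to_drop, max_frac_N, max_AT_frac) <= 1)
  )
  structure(list(min_frac_lowqual_to_drop = min_frac_lowqual_to_drop,
                 lowqual_threshold = as.integer(lowqual_threshold),
                 max_frac_N = max_frac_N,
                 max_AT_frac = max_AT_frac,
                 polyA_min_run = as.integer(polyA_min_run),
                 min_len = as.integer(min_len),
                 adaptors = toupper(adaptors)),
            class = "qc_config")
}

## Vectorised trimming core: returns list(from, to) of 1-based keep bounds.
trim_bounds <- function(seqs, cfg) {
  from <- rep(1L, length(seqs))
  to <- nchar(seqs)
  cur <- function() substring(seqs, from, to)
  for (ad in cfg$adaptors) {
    if (nchar(ad) == 0L) next
    hit <- regexpr(ad, cur(), fixed = TRUE)
    len <- attr(hit, "match.length")
    lead <- hit == 1L
    from <- ifelse(lead, from + len, from)
    to <- ifelse(!lead & hit > 0L, from + hit - 2L, to)
  }
  run <- sprintf("{%d,}", cfg$polyA_min_run)
  ## poly(T) tail at the 5' end: strip the run itself
  t_lead <- regexpr(paste0("^T", run), cur())
  from <- ifelse(t_lead > 0L, from + attr(t_lead, "match.length"), from)
  ## poly(A)/poly(T) runs trim through the 3' end (artificial tails)
  a_hit <- regexpr(paste0("A", run), cur())
  to <- ifelse(a_hit > 0L, from + a_hit - 2L, to)
  t_hit <- regexpr(paste0("T", run), cur())
  to <- ifelse(t_hit > 0L, from + t_hit - 2L, to)
  empty <- to < from
  list(from = ifelse(empty, 1L, from), to = ifelse(empty, 0L, to))
}

#' Trim adaptors and artificial poly(A)/poly(T) tails from one read
#'
#' Adaptor occurrences are removed together with everything 3' of them (and
#' a full adaptor at the 5' end is stripped). Then homopolymer runs of A or
#' T of at least `polyA_min_run` bases are removed together with everything
#' distal to them (a 5'-terminal poly(T) run is stripped from the front).
#' Qualities are trimmed in lockstep. Trimming is idempotent; the result may
#' be an empty read.
#'
#' @param read one-row data.frame with `seq` and `qual` (as from
#'   [read_fastq()]), or a list with those fields.
#' @param cfg a [qc_config()].
#' @return the read with `seq`/`qual` trimmed.
#' @export
trim_read <- function(read, cfg = qc_config()) {
  b <- trim_bounds(read$seq, cfg)
  read$seq <- substring(read$seq, b$from, b$to)
  read$qual <- substring(read$qual, b$from, b$to)
  read
}

## Vectorised filter core: returns "keep" or "drop:<reason>" per read.
filter_verdicts <- function(seqs, quals, cfg) {
  n <- length(seqs)
  verdict <- rep("keep", n)
  len <- nchar(seqs)
  qoff <- cfg$lowqual_threshold + 33L
  chars <- strsplit(seqs, "", fixed = TRUE)
  frac_lowqual <- vapply(quals, function(q) {
    if (nchar(q) == 0L) return(0)
    mean(utf8ToInt(q) <= qoff)
  }, numeric(1), USE.NAMES = FALSE)
  frac_N <- vapply(chars, function(x) {
    if (!length(x)) 0 else mean(x == "N")
  }, numeric(1), USE.NAMES = FALSE)
  frac_AT <- vapply(chars, function(x) {
    if (!length(x)) 0 else mean(x %in% c("A", "T"))
  }, numeric(1), USE.NAMES = FALSE)
  nonempty <- len > 0L
  verdict[len < cfg$min_len] <- "drop:short"
  verdict[nonempty & frac_AT > cfg$max_AT_frac] <- "drop:AT"
  verdict[nonempty & frac_N > cfg$max_frac_N] <- "drop:tooN"
  verdict[nonempty & frac_lowqual >= cfg$min_frac_lowqual_to_drop] <-
    "drop:lowqual"
  verdict
}

#' Filter one trimmed read
#'
#' Rules are evaluated in a fixed precedence and the first violated rule
#' names the drop reason: `lowqual`, `tooN`, `AT`, `short`.
#'
#' @param read one-row data.frame or list with `seq` and `qual`.
#' @param cfg a [qc_config()].
#' @return `"keep"` or `"drop:<reason>"`.
#' @export
filter_read <- function(read, cfg = qc_config()) {
  filter_verdicts(read$seq, read$qual, cfg)
}

#' QC a pair of FASTQ read tables
#'
#' Trims every read, filters both mates, and drops a pair whenever either
#' mate is dropped (the junction caller and the mate-consistency filter need
#' intact pairs).
#'
#' @param reads1,reads2 data.frames from [read_fastq()], row-matched pairs.
#' @param cfg a [qc_config()].
#' @return list with `reads1`, `reads2` (surviving trimmed pairs) and
#'   `report`: a data.frame of dropped pair counts per reason plus kept
#'   pairs.
#' @export
qc_pairs <- function(reads1, reads2, cfg = qc_config()) {
  stopifnot_named("mate files must pair row by row" =
                    nrow(reads1) == nrow(reads2))
  trim_tab <- function(rd) {
    if (nrow(rd) == 0L) return(rd)
    b <- trim_bounds(rd$seq, cfg)
    rd$seq <- substring(rd$seq, b$from, b$to)
    rd$qual <- substring(rd$qual, b$from, b$to)
    rd
  }
  reads1 <- trim_tab(reads1)
  reads2 <- trim_tab(reads2)
  v1 <- if (nrow(reads1)) filter_verdicts(reads1$seq, reads1$qual, cfg)
        else character(0)
  v2 <- if (nrow(reads2)) filter_verdicts(reads2$seq, reads2$qual, cfg)
        else character(0)
  pair_reason <- ifelse(v1 != "keep", v1, v2)
  keep <- pair_reason == "keep"
  reasons <- sub("^drop:", "", pair_reason[!keep])
  tab <- table(factor(reasons, levels = c("lowqual", "tooN", "AT", "short")))
  report <- data.frame(
    reason = c(names(tab), "kept"),
    pairs = c(as.integer(tab), sum(keep)),
    stringsAsFactors = FALSE
  )
  list(reads1 = reads1[keep, , drop = FALSE],
       reads2 = reads2[keep, , drop = FALSE],
       report = report)
}
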