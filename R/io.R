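## I/O for the standard formats used throughout the pipeline.
##
## Coordinate convention: internally everything is 0-based half-open.
## GTF (1-based inclusive), SAM (1-based) and the figure-style
## "chrom:start-end" labels are converted at these I/O boundaries only.

#' Read a genome FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase chromosome sequences
#'   (alphabet A/C/G/T/N).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome <- toupper(as.character(ss))
  names(genome) <- sub("\\s.*$", "", names(ss))
  validate_genome(genome)
  genome
}

#' Write a genome FASTA file
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  validate_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

validate_genome <- function(genome) {
  stopifnot_named(
    "genome must be a named character vector" =
      is.character(genome) && !is.null(names(genome)),
    "chromosome names must be unique" = !anyDuplicated(names(genome)),
    "sequences must be non-empty" = all(nchar(genome) > 0L),
    "alphabet restricted to ACGTN" = !any(grepl("[^ACGTN]", genome))
  )
  invisible(genome)
}

#' Read a FASTQ file of reads
#'
#' Expects 4-line records with Phred+33 qualities. The mate role is taken
#' from the file's role in the pair (argument), not parsed from headers.
#'
#' @param path path to an uncompressed or gzipped FASTQ file.
#' @param mate integer 1 or 2, the mate role of every read in this file.
#' @param offset Phred ASCII offset (default 33).
#' @return data.frame with columns `read_id`, `seq`, `qual` (ASCII string),
#'   `mate`. Qualities can be decoded with [phred_decode()].
#' @export
read_fastq <- function(path, mate = 1L, offset = 33L) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), mate = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at end of ", path, call. = FALSE)
  id <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
  seq <- toupper(lines[seq(2L, length(lines), 4L)])
  qual <- lines[seq(4L, length(lines), 4L)]
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("FASTQ record ", bad[1L], " in ", path,
         ": sequence and quality lengths differ", call. = FALSE)
  data.frame(read_id = id, seq = seq, qual = qual,
             mate = as.integer(mate), stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  stopifnot_named("seq/qual lengths must agree" =
                    all(nchar(reads$seq) == nchar(reads$qual)))
  rec <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses exon features into an exon table grouped by transcript and gene.
#' GTF's 1-based inclusive coordinates are converted to 0-based half-open.
#' Both Ensembl and GENCODE attribute quoting dialects are accepted
#' (rtracklayer handles either). Exons lacking a transcript_id are skipped
#' with a warning; overlapping exons within one transcript are an error.
#'
#' @param path path to a GTF file.
#' @return a `gene_models` data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `gene_id`, `transcript_id`, sorted by
#'   transcript and genomic start.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  tx <- as.character(mc$transcript_id)
  missing_tx <- is.na(tx) | tx == ""
  if (any(missing_tx)) {
    warning(sum(missing_tx), " exon feature(s) lacking transcript_id skipped",
            call. = FALSE)
    gr <- gr[!missing_tx]
    mc <- S4Vectors::mcols(gr)
    tx <- as.character(mc$transcript_id)
  }
  gid <- as.character(mc$gene_id)
  gid[is.na(gid) | gid == ""] <- tx[is.na(gid) | gid == ""]
  models <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gid,
    transcript_id = tx,
    stringsAsFactors = FALSE
  )
  as_gene_models(models)
}

#' Construct and validate a gene-model exon table
#'
#' @param models data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (+/-), `gene_id`, `transcript_id`.
#' @return the validated table, sorted by transcript and genomic start, with
#'   class `gene_models`.
#' @export
as_gene_models <- function(models) {
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  stopifnot_named(
    "missing exon table columns" = all(need %in% names(models)),
    "exon start must be < end" = all(models$start < models$end),
    "strand must be + or -" = all(models$strand %in% c("+", "-"))
  )
  models <- models[order(models$transcript_id, models$start), need,
                   drop = FALSE]
  ## overlapping exons within one transcript are malformed annotation
  by_tx <- split(seq_len(nrow(models)), models$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L) {
      s <- models$start[idx]; e <- models$end[idx]
      if (any(s[-1L] < e[-length(e)]))
        stop("overlapping exons within transcript ",
             models$transcript_id[idx[1L]], call. = FALSE)
      if (length(unique(models$strand[idx])) != 1L ||
          length(unique(models$chrom[idx])) != 1L)
        stop("transcript ", models$transcript_id[idx[1L]],
             " mixes strands or chromosomes", call. = FALSE)
    }
  }
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")
  models
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gtf()]; exon coordinates round-trip exactly.
#'
#' @param models a `gene_models` table.
#' @param path output path.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "circjunct") {
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- models$gene_id
  S4Vectors::mcols(gr)$transcript_id <- models$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Exons of one transcript in transcript (5'-to-3') order
#'
#' @param models a `gene_models` table.
#' @param transcript_id transcript identifier.
#' @return data.frame of the transcript's exons ordered 5' to 3' (genomic
#'   start ascending on +, descending on -).
#' @export
transcript_exons <- function(models, transcript_id) {
  ex <- models[models$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript ", transcript_id, call. = FALSE)
  ex <- ex[order(ex$start), , drop = FALSE]
  if (ex$strand[1L] == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

#' Spliced sequence of a block of exons, on the transcript strand
#'
#' @param genome named character vector of chromosome sequences.
#' @param exons data.frame of exons in transcript order (as returned by
#'   [transcript_exons()]), or a contiguous subset of its rows.
#' @return character scalar: the concatenated exon sequence 5' to 3'.
#' @export
spliced_seq <- function(genome, exons) {
  chrom <- genome[[exons$chrom[1L]]]
  pieces <- substring(chrom, exons$start + 1L, exons$end)
  if (exons$strand[1L] == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

#' Write circRNA calls as an extended BED file
#'
#' BED6 (0-based half-open) with extra columns for the host gene, host
#' transcript, junction read count, and the 1-based "chrom:start-end" label
#' conventional in reports.
#'
#' @param calls data.frame of calls as produced by [aggregate_calls()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_circ_bed <- function(calls, path) {
  header <- paste("#chrom", "start", "end", "name", "score", "strand",
                  "gene_id", "transcript_id", "junction_reads", "label",
                  sep = "\t")
  if (is.null(calls) || nrow(calls) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  stopifnot_named("acceptor_start must be < donor_end" =
                    all(calls$acceptor_start < calls$donor_end))
  label <- span_label(calls$chrom, calls$acceptor_start, calls$donor_end)
  lines <- paste(calls$chrom, calls$acceptor_start, calls$donor_end,
                 paste0("circ_", label), calls$junction_reads, calls$strand,
                 calls$gene_id, calls$transcript_id, calls$junction_reads,
                 label, sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read circRNA calls written by [write_circ_bed()]
#'
#' @param path path to the BED file.
#' @return data.frame of calls.
#' @export
read_circ_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "gene_id",
                                        "transcript_id", "junction_reads",
                                        "label"))
  data.frame(chrom = as.character(df$chrom),
             acceptor_start = as.integer(df$start),
             donor_end = as.integer(df$end),
             strand = df$strand, gene_id = df$gene_id,
             transcript_id = df$transcript_id,
             junction_reads = as.integer(df$junction_reads),
             stringsAsFactors = FALSE)
}

#' Read a repeat-element track from BED4
#'
#' Column 4 carries the repeat family (SINE/LINE/LTR/other).
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `family`
#'   (0-based half-open).
#' @export
read_repeat_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("repeat BED needs 4 columns", call. = FALSE)
  rep <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    family = as.character(df[[4L]]),
                    stringsAsFactors = FALSE)
  stopifnot_named("repeat start must be < end" = all(rep$start < rep$end))
  rep
}

#' Read an ERCC spike-in table
#'
#' Tab-separated with columns `id`, `known_copies`, `length`.
#'
#' @param path path to the TSV file.
#' @return data.frame with those columns.
#' @export
read_ercc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "known_copies", "length")
  stopifnot_named("ERCC table needs id, known_copies, length" =
                    all(need %in% names(df)))
  df[need]
}
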