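## Synthetic data generator.
##
## Emits a toy genome, multi-exon gene annotation, and 100-bp paired-end
## reads with planted circRNAs (junction-spanning fragments), linear
## transcript fragments, trans-splicing decoys (exons of two different genes
## joined at boundaries), ERCC spike-in reads, and QC-failing reads, plus a
## machine-readable truth table. All randomness derives from the config
## seed, so a fixed config reproduces byte-identical output.

#' Default ERCC spike-in mix
#'
#' 24 spike-ins with input copy numbers log-spaced over three orders of
#' magnitude, mirroring the dynamic range of the commercial mix at the copy
#' numbers typical of a single-cell experiment.
#'
#' @param n number of spike-ins.
#' @param copies_range range (min, max) of input molecule counts.
#' @return data.frame with `id` and `true_copies`.
#' @export
ercc_default_mix <- function(n = 24L, copies_range = c(1e2, 1e5)) {
  data.frame(
    id = sprintf("ERCC-%05d", seq_len(n)),
    true_copies = round(10 ^ seq(log10(copies_range[1L]),
                                 log10(copies_range[2L]), length.out = n)),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: 20 multi-exon genes, 8 planted circRNAs with 5 junction-spanning
#' fragments each, error-free 100-bp paired-end reads.
#'
#' @param seed integer seed; every random draw derives from it.
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (min, max) of exons per gene.
#' @param exon_len integer range of exon lengths (bp).
#' @param intron_len integer range of intron lengths (bp).
#' @param n_circ number of planted circRNAs.
#' @param circ_junction_reads integer range of junction-spanning fragments
#'   planted per circle.
#' @param linear_depth mean fragments per linear transcript (Poisson).
#' @param read_len read length in bp (>= 60: anchors need 25 bp at each
#'   terminus plus a gap).
#' @param frag_len fragment length mean and sd, `c(mean, sd)`.
#' @param n_trans_decoys number of trans-splicing decoy fragments.
#' @param n_qc_fail number of planted QC-failing read pairs.
#' @param ercc data.frame of spike-ins (`id`, `true_copies`), or NULL.
#' @param ercc_capture capture efficiency: expected sequenced fragments per
#'   molecule and per kb of spike-in length.
#' @param error_rate per-base substitution probability.
#' @param junction_overhang_min minimum bases a junction read keeps on each
#'   side of the back-splice. The default 25 makes every planted junction
#'   read recoverable by 25-bp anchors; 1 reproduces the physical minimum
#'   and makes planted and recoverable counts differ.
#' @param single_exon_frac fraction of circles formed by a single exon
#'   (about 9 percent of circles in single-cell data).
#' @param genome_len optional fixed genome length; an error is raised if the
#'   genes do not fit.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exons_per_gene = c(4L, 8L),
                       exon_len = c(150L, 400L),
                       intron_len = c(500L, 8000L),
                       n_circ = 8L,
                       circ_junction_reads = c(5L, 5L),
                       linear_depth = 50,
                       read_len = 100L,
                       frag_len = c(250, 30),
                       n_trans_decoys = 50L,
                       n_qc_fail = 20L,
                       ercc = ercc_default_mix(),
                       ercc_capture = 0.005,
                       error_rate = 0,
                       junction_overhang_min = 25L,
                       single_exon_frac = 0.1,
                       genome_len = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              n_circ = as.integer(n_circ),
              circ_junction_reads = as.integer(circ_junction_reads),
              linear_depth = linear_depth, read_len = as.integer(read_len),
              frag_len = frag_len, n_trans_decoys = as.integer(n_trans_decoys),
              n_qc_fail = as.integer(n_qc_fail), ercc = ercc,
              ercc_capture = ercc_capture, error_rate = error_rate,
              junction_overhang_min = as.integer(junction_overhang_min),
              single_exon_frac = single_exon_frac, genome_len = genome_len)
  stopifnot_named(
    "read_len must be >= 60 (anchor extraction)" = cfg$read_len >= 60L,
    "frag_len mean must be >= read_len" = cfg$frag_len[1L] >= cfg$read_len,
    "error_rate must lie in [0,1]" =
      cfg$error_rate >= 0 && cfg$error_rate <= 1
  )
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rint <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

#' Generate a toy genome and gene annotation
#'
#' Genes are placed non-overlapping with at least 10 kb between them,
#' alternating over two chromosomes and both strands; one transcript per
#' gene with exon/intron sizes drawn from the configured ranges. ERCC
#' spike-ins are appended as their own single-exon contigs with ids
#' `ERCC-NNNNN`. Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named character vector) and `models`
#'   (`gene_models` table).
#' @export
make_genome_and_annotation <- function(cfg) {
  with_seed(cfg$seed, {
    chroms <- c("chr1", "chr2")
    cursor <- stats::setNames(rep(1000L, length(chroms)), chroms)
    exon_rows <- list()
    for (g in seq_len(cfg$n_genes)) {
      chrom <- chroms[(g - 1L) %% length(chroms) + 1L]
      strand <- if ((g - 1L) %/% length(chroms) %% 2L == 0L) "+" else "-"
      n_ex <- rint(cfg$exons_per_gene)
      ex_len <- rint(cfg$exon_len, n_ex)
      in_len <- if (n_ex > 1L) rint(cfg$intron_len, n_ex - 1L) else integer(0)
      start <- cursor[[chrom]]
      pos <- start
      for (e in seq_len(n_ex)) {
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + ex_len[e],
          strand = strand, gene_id = sprintf("gene%02d", g),
          transcript_id = sprintf("gene%02d_t1", g),
          stringsAsFactors = FALSE)
        pos <- pos + ex_len[e] + if (e < n_ex) in_len[e] else 0L
      }
      cursor[[chrom]] <- pos + 10000L + sample(0:2000, 1L)
    }
    models <- do.call(rbind, exon_rows)
    chrom_len <- cursor + 1000L
    if (!is.null(cfg$genome_len) && any(chrom_len > cfg$genome_len))
      stop("genome too small to place the requested genes: need ",
           max(chrom_len), " bp per chromosome", call. = FALSE)
    genome <- vapply(chroms, function(ch) rand_dna(chrom_len[[ch]]),
                     character(1))
    if (!is.null(cfg$ercc) && nrow(cfg$ercc)) {
      ercc_len <- rint(c(250L, 2000L), nrow(cfg$ercc))
      for (i in seq_len(nrow(cfg$ercc))) {
        id <- cfg$ercc$id[i]
        genome[[id]] <- rand_dna(ercc_len[i])
        models <- rbind(models, data.frame(
          chrom = id, start = 0L, end = ercc_len[i], strand = "+",
          gene_id = id, transcript_id = paste0(id, "_t1"),
          stringsAsFactors = FALSE))
      }
    }
    list(genome = genome, models = as_gene_models(models))
  })
}

#' Plant circRNAs on simulated gene models
#'
#' Each circle is a contiguous block of exons of one transcript,
#' circularised: the donor end of the last block exon joins the acceptor
#' start of the first. Internal exon blocks are preferred, a configured
#' fraction of circles uses a single exon, and among candidate internal
#' blocks the one with the longest flanking introns is chosen (long
#' flanking introns favour circularisation).
#'
#' @param models a `gene_models` table from [make_genome_and_annotation()].
#' @param cfg a [sim_config()].
#' @return data.frame of circle definitions: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `i_up`, `i_down` (transcript-order exon indices),
#'   `acceptor_start`, `donor_end` (genomic, start < end), `circ_len`.
#' @export
plant_circles <- function(models, cfg) {
  with_seed(cfg$seed + 1L, {
    tx <- unique(models$transcript_id[!grepl("^ERCC-", models$gene_id)])
    ## enumerate internal candidate blocks per transcript
    blocks <- list()
    for (t in tx) {
      exons <- transcript_exons(models, t)
      n <- nrow(exons)
      if (n < 3L) next
      for (i in 2:(n - 1L)) {
        for (j in i:(n - 1L)) {
          blocks[[length(blocks) + 1L]] <- list(t = t, i = i, j = j,
                                                exons = exons)
        }
      }
    }
    if (cfg$n_circ > length(blocks))
      stop("requested ", cfg$n_circ, " circles but only ", length(blocks),
           " internal exon blocks are available", call. = FALSE)
    ## total length of the two introns immediately outside the circle
    flank_len <- function(b) {
      g <- b$exons[order(b$exons$start), , drop = FALSE]
      block <- rank(b$exons$start)[b$i:b$j]  # genomic ranks of block exons
      lo <- min(block); hi <- max(block)
      (g$start[lo] - g$end[lo - 1L]) + (g$start[hi + 1L] - g$end[hi])
    }
    chosen <- list()
    used <- character(0)
    for (k in seq_len(cfg$n_circ)) {
      single <- stats::runif(1) < cfg$single_exon_frac
      avail <- Filter(function(b) {
        key <- paste(b$t, b$i, b$j)
        !(key %in% used) && ((b$j == b$i) == single)
      }, blocks)
      if (!length(avail))
        avail <- Filter(function(b) !(paste(b$t, b$i, b$j) %in% used), blocks)
      ## sample a few candidates, keep the one with longest flanking introns
      cand <- avail[sample.int(length(avail), min(5L, length(avail)))]
      fl <- vapply(cand, flank_len, numeric(1))
      b <- cand[[which.max(fl)]]
      used <- c(used, paste(b$t, b$i, b$j))
      block <- b$exons[b$i:b$j, , drop = FALSE]
      chosen[[k]] <- data.frame(
        transcript_id = b$t, gene_id = block$gene_id[1L],
        chrom = block$chrom[1L], strand = block$strand[1L],
        i_up = b$i, i_down = b$j,
        acceptor_start = min(block$start), donor_end = max(block$end),
        circ_len = sum(block$end - block$start),
        stringsAsFactors = FALSE)
    }
    circles <- do.call(rbind, chosen)
    rownames(circles) <- NULL
    circles
  })
}

## Substitution errors at a flat per-base rate.
add_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (p in hit) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired-end reads with planted circRNAs and a truth table
#'
#' Fragments are FR-oriented (inward-facing Illumina geometry): read 1 is
#' the fragment's leading `read_len` bases and read 2 the reverse
#' complement of its trailing bases; the sequenced strand of each fragment
#' is random (the library is unstranded). For every planted circle the
#' configured number of junction fragments is emitted, each with one read
#' crossing the back-splice at a split point drawn uniformly while keeping
#' at least `junction_overhang_min` bases on each side, and its mate inside
#' the circle. Linear fragments are drawn from spliced transcripts, decoy
#' fragments join exon boundaries of two different genes, ERCC fragments
#' are emitted in proportion to input molecules, and QC-fail pairs violate
#' exactly one QC rule each.
#'
#' @param genome named character vector of chromosome sequences.
#' @param models a `gene_models` table.
#' @param circles circle definitions from [plant_circles()].
#' @param cfg a [sim_config()].
#' @return list with `reads1`, `reads2` (row-matched read tables) and
#'   `truth` (circ/linear/decoy/ercc/qc_fail tables).
#' @export
simulate_reads <- function(genome, models, circles, cfg) {
  with_seed(cfg$seed + 2L, {
    L <- cfg$read_len
    q_good <- strrep("I", L)  # Phred 40
    r1 <- list(); r2 <- list()
    emit <- function(id, s1, s2) {
      r1[[length(r1) + 1L]] <<- c(id = id, seq = s1)
      r2[[length(r2) + 1L]] <<- c(id = id, seq = s2)
    }
    ## fragment -> FR pair with random sequenced strand
    pair_from_fragment <- function(frag) {
      f <- nchar(frag)
      if (stats::runif(1) < 0.5) frag <- revcomp(frag)
      list(s1 = substring(frag, 1L, L),
           s2 = revcomp(substring(frag, f - L + 1L, f)))
    }
    draw_frag_len <- function(lo, hi) {
      f <- round(stats::rnorm(1L, cfg$frag_len[1L], cfg$frag_len[2L]))
      min(max(f, lo), hi)
    }

    ## --- junction fragments -------------------------------------------
    circ_truth <- NULL
    if (!is.null(circles) && nrow(circles)) {
      circ_truth <- circles
      circ_truth$planted_junction_reads <- 0L
      circ_truth$recoverable_junction_reads <- 0L
      for (ci in seq_len(nrow(circles))) {
        cc <- circles[ci, ]
        exons <- transcript_exons(models, cc$transcript_id)
        S <- spliced_seq(genome, exons[cc$i_up:cc$i_down, , drop = FALSE])
        nS <- nchar(S)
        S3 <- strrep(S, max(3L, ceiling((cfg$frag_len[1L] + L) / nS) + 1L))
        n_j <- rint(cfg$circ_junction_reads)
        ov <- cfg$junction_overhang_min
        for (n in seq_len(n_j)) {
          k <- sample(seq(ov, L - ov), 1L)       # bases on the donor side
          k <- min(k, nS); k <- max(k, L - nS)   # short circles
          start0 <- nS - k                       # 0-based on the circle
          f <- draw_frag_len(L, min(nS, cfg$frag_len[1L] + 3 * cfg$frag_len[2L]))
          frag <- substring(S3, start0 + 1L, start0 + f)
          p <- pair_from_fragment(frag)
          ## the junction-crossing read is the fragment's leading read;
          ## after the random strand flip it is read 1 or read 2
          emit(sprintf("junc_c%02d_%03d", ci, n), p$s1, p$s2)
          circ_truth$planted_junction_reads[ci] <-
            circ_truth$planted_junction_reads[ci] + 1L
          if (min(k, L - k) >= ANCHOR_LEN)
            circ_truth$recoverable_junction_reads[ci] <-
              circ_truth$recoverable_junction_reads[ci] + 1L
        }
      }
    }

    ## --- linear fragments ---------------------------------------------
    tx_ids <- unique(models$transcript_id[!grepl("^ERCC-", models$gene_id)])
    linear_truth <- data.frame(transcript_id = tx_ids, fragments = 0L,
                               stringsAsFactors = FALSE)
    for (ti in seq_along(tx_ids)) {
      t <- tx_ids[ti]
      Tseq <- spliced_seq(genome, transcript_exons(models, t))
      nT <- nchar(Tseq)
      if (nT < L) next
      n_f <- stats::rpois(1L, cfg$linear_depth)
      linear_truth$fragments[ti] <- n_f
      for (n in seq_len(n_f)) {
        f <- draw_frag_len(L, nT)
        s0 <- sample.int(nT - f + 1L, 1L) - 1L
        p <- pair_from_fragment(substring(Tseq, s0 + 1L, s0 + f))
        emit(sprintf("lin_%s_%04d", t, n), p$s1, p$s2)
      }
    }

    ## --- trans-splicing decoys ----------------------------------------
    decoy_truth <- character(0)
    gene_ids <- unique(models$gene_id[!grepl("^ERCC-", models$gene_id)])
    if (cfg$n_trans_decoys > 0L && length(gene_ids) >= 2L) {
      gi <- tx_index(models)
      gi <- gi[!grepl("^ERCC-", gi$gene_id), , drop = FALSE]
      for (n in seq_len(cfg$n_trans_decoys)) {
        ## join the donor end of an exon of one gene to the acceptor start
        ## of an exon of another gene (genomically upstream when possible,
        ## so the decoy mimics the reversed-order signature)
        repeat {
          two <- gi[sample.int(nrow(gi), 2L), ]
          if (two$gene_id[1L] != two$gene_id[2L]) break
        }
        two <- two[order(two$start), ]
        donor_tx <- two$transcript_id[2L]   # downstream gene donates the end
        accep_tx <- two$transcript_id[1L]
        dex <- transcript_exons(models, donor_tx)
        aex <- transcript_exons(models, accep_tx)
        de <- dex[sample.int(nrow(dex), 1L), ]
        ae <- aex[sample.int(nrow(aex), 1L), ]
        k <- sample(seq(ANCHOR_LEN, L - ANCHOR_LEN), 1L)
        donor_part <- substring(genome[[de$chrom]], de$end - k + 1L, de$end)
        accep_part <- substring(genome[[ae$chrom]], ae$start + 1L,
                                ae$start + (L - k))
        s1 <- paste0(donor_part, accep_part)
        ## mate: a linear read inside the acceptor gene's exon
        mstart <- ae$start
        mate <- substring(genome[[ae$chrom]], mstart + 1L, mstart + L)
        if (nchar(mate) < L)
          mate <- substring(strrep(genome[[ae$chrom]], 2L), mstart + 1L,
                            mstart + L)
        id <- sprintf("decoy_%03d", n)
        emit(id, s1, revcomp(mate))
        decoy_truth <- c(decoy_truth, id)
      }
    }

    ## --- ERCC spike-in fragments --------------------------------------
    ercc_truth <- NULL
    if (!is.null(cfg$ercc) && nrow(cfg$ercc)) {
      ercc_truth <- cfg$ercc
      ercc_truth$length <- nchar(genome[ercc_truth$id])
      ercc_truth$fragments <- 0L
      for (i in seq_len(nrow(ercc_truth))) {
        id <- ercc_truth$id[i]
        Eseq <- genome[[id]]
        nE <- nchar(Eseq)
        if (nE < L) next
        n_f <- round(cfg$ercc_capture * ercc_truth$true_copies[i] *
                       ercc_truth$length[i] / 1000)
        ercc_truth$fragments[i] <- n_f
        for (n in seq_len(n_f)) {
          f <- draw_frag_len(L, nE)
          s0 <- sample.int(nE - f + 1L, 1L) - 1L
          p <- pair_from_fragment(substring(Eseq, s0 + 1L, s0 + f))
          emit(sprintf("ercc_%s_%04d", id, n), p$s1, p$s2)
        }
      }
    }

    n_real <- length(r1)  # reads subject to sequencing errors

    ## --- QC-fail pairs (each violates exactly one rule) ----------------
    qc_truth <- NULL
    if (cfg$n_qc_fail > 0L) {
      reasons <- rep(c("lowqual", "tooN", "AT", "polyA"),
                     length.out = cfg$n_qc_fail)
      host <- tx_ids[1L]
      Tseq <- spliced_seq(genome, transcript_exons(models, host))
      rows <- list()
      for (n in seq_len(cfg$n_qc_fail)) {
        s0 <- sample.int(max(nchar(Tseq) - 2L * L, 1L), 1L) - 1L
        clean1 <- substring(Tseq, s0 + 1L, s0 + L)
        clean2 <- revcomp(substring(Tseq, s0 + L + 1L, s0 + 2L * L))
        reason <- reasons[n]
        bad <- clean1
        badq <- q_good
        if (reason == "lowqual") {
          nlow <- ceiling(L * 0.6)
          badq <- paste0(strrep("#", nlow), strrep("I", L - nlow))  # Phred 2
        } else if (reason == "tooN") {
          pos <- sample.int(L, ceiling(L * 0.15))
          ch <- strsplit(bad, "")[[1L]]; ch[pos] <- "N"
          bad <- paste(ch, collapse = "")
        } else if (reason == "AT") {
          bad <- paste(sample(c("A", "T", "G", "C"), L, replace = TRUE,
                              prob = c(0.46, 0.46, 0.04, 0.04)),
                       collapse = "")
        } else if (reason == "polyA") {
          ## poly(A) tail trims the read below the length cutoff
          bad <- paste0(substring(clean1, 1L, L - 60L), strrep("A", 60L))
        }
        id <- sprintf("qcfail_%s_%03d", reason, n)
        r1[[length(r1) + 1L]] <- c(id = id, seq = bad, qual = badq)
        r2[[length(r2) + 1L]] <- c(id = id, seq = clean2, qual = q_good)
        rows[[n]] <- data.frame(read_id = id, reason = reason,
                                stringsAsFactors = FALSE)
      }
      qc_truth <- do.call(rbind, rows)
    }

    build <- function(rl, mate) {
      if (!length(rl)) {
        return(data.frame(read_id = character(0), seq = character(0),
                          qual = character(0), mate = integer(0),
                          stringsAsFactors = FALSE))
      }
      id <- vapply(rl, `[[`, character(1), "id")
      seq <- vapply(rl, `[[`, character(1), "seq")
      qual <- vapply(rl, function(x) {
        if (!is.na(x["qual"])) x[["qual"]] else strrep("I", nchar(x[["seq"]]))
      }, character(1))
      data.frame(read_id = id, seq = seq, qual = qual,
                 mate = as.integer(mate), stringsAsFactors = FALSE)
    }
    reads1 <- build(r1, 1L)
    reads2 <- build(r2, 2L)
    if (cfg$error_rate > 0 && n_real > 0L) {
      reads1$seq[seq_len(n_real)] <-
        add_errors(reads1$seq[seq_len(n_real)], cfg$error_rate)
      reads2$seq[seq_len(n_real)] <-
        add_errors(reads2$seq[seq_len(n_real)], cfg$error_rate)
    }
    ## shuffle pairs so file order carries no signal
    perm <- sample.int(nrow(reads1))
    reads1 <- reads1[perm, , drop = FALSE]
    reads2 <- reads2[perm, , drop = FALSE]
    rownames(reads1) <- rownames(reads2) <- NULL

    list(reads1 = reads1, reads2 = reads2,
         truth = list(circ_truth = circ_truth, linear_truth = linear_truth,
                      decoy_truth = decoy_truth, ercc_truth = ercc_truth,
                      qc_fail = qc_truth))
  })
}

#' Run the full simulator and optionally write its artifacts
#'
#' @param cfg a [sim_config()].
#' @param dir if non-NULL, writes `genome.fa`, `annotation.gtf`,
#'   `reads_1.fastq`, `reads_2.fastq` and truth TSV files there.
#' @return list with `genome`, `models`, `circles`, `reads1`, `reads2`,
#'   `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  ga <- make_genome_and_annotation(cfg)
  circles <- if (cfg$n_circ > 0L) plant_circles(ga$models, cfg) else NULL
  rd <- simulate_reads(ga$genome, ga$models, circles, cfg)
  out <- list(genome = ga$genome, models = ga$models, circles = circles,
              reads1 = rd$reads1, reads2 = rd$reads2, truth = rd$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$genome, file.path(dir, "genome.fa"))
    write_gtf(out$models, file.path(dir, "annotation.gtf"))
    write_fastq(out$reads1, file.path(dir, "reads_1.fastq"))
    write_fastq(out$reads2, file.path(dir, "reads_2.fastq"))
    for (nm in names(out$truth)) {
      tt <- out$truth[[nm]]
      if (is.character(tt)) tt <- data.frame(read_id = tt)
      if (!is.null(tt))
        utils::write.table(tt, file.path(dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
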