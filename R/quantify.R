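## Expression-level computations: FPKM, junction reads per million,
## host-normalised circRNA abundance, ERCC spike-in calibration and
## absolute molecule counts, poly(A)- gene detection, and maternal/zygotic
## gene classification.

#' Fragments per kilobase of exon model per million mapped fragments
#'
#' @param count mapped fragments for the feature.
#' @param feature_len_bp exon-model length in bp.
#' @param total_fragments total mapped paired-end fragments in the sample.
#' @return FPKM (vectorised).
#' @export
fpkm <- function(count, feature_len_bp, total_fragments) {
  stopifnot_named("feature length must be > 0" = all(feature_len_bp > 0),
                  "total fragments must be > 0" = all(total_fragments > 0))
  count / (feature_len_bp / 1000) / (total_fragments / 1e6)
}

#' Junction reads per million mapped paired-end fragments
#'
#' Only reads spanning the back-splice are counted as circRNA evidence, so
#' the natural depth normalisation is junction reads per million fragments.
#'
#' @param junction_reads junction-spanning read count.
#' @param total_pe_fragments total mapped paired-end fragments.
#' @return reads per million (vectorised).
#' @export
junction_rpm <- function(junction_reads, total_pe_fragments) {
  stopifnot_named("total fragments must be > 0" = all(total_pe_fragments > 0))
  junction_reads / (total_pe_fragments / 1e6)
}

#' Host-normalised circRNA abundance
#'
#' Junction reads divided by the host gene's FPKM (plus a pseudocount),
#' making circRNAs from differently expressed hosts comparable.
#'
#' @param circ_junction_reads junction reads supporting the circRNA.
#' @param host_fpkm host gene FPKM.
#' @param pseudocount added to the denominator.
#' @return normalised abundance (vectorised).
#' @export
host_normalized <- function(circ_junction_reads, host_fpkm, pseudocount = 0) {
  stopifnot_named("host FPKM must be >= 0" = all(host_fpkm >= 0))
  circ_junction_reads / (host_fpkm + pseudocount)
}

#' Calibrate absolute copy numbers from ERCC spike-ins
#'
#' Spike-in expression is linear in the number of input molecules, so a
#' least-squares fit of log10(known copies) on log10(FPKM) over the
#' detected spike-ins converts expression into molecules. The slope is not
#' forced to 1, absorbing capture-efficiency nonlinearity.
#'
#' @param spikes data.frame with columns `id`, `known_copies` and `fpkm`
#'   (observed expression); spike-ins with `fpkm` 0 are treated as
#'   undetected.
#' @param min_points minimum detected spike-ins required.
#' @return list of class `ercc_calibration`: `slope`, `intercept`, `r`
#'   (Pearson on the log-log scale), `n`.
#' @export
ercc_calibrate <- function(spikes, min_points = 8L) {
  stopifnot_named(
    "spike table needs known_copies and fpkm" =
      all(c("known_copies", "fpkm") %in% names(spikes)),
    "known copies must be > 0" = all(spikes$known_copies > 0)
  )
  det <- spikes[spikes$fpkm > 0, , drop = FALSE]
  if (nrow(det) < min_points)
    stop("insufficient calibration points: ", nrow(det), " detected spike-ins",
         call. = FALSE)
  x <- log10(det$fpkm)
  y <- log10(det$known_copies)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = stats::cor(x, y), n = nrow(det)),
            class = "ercc_calibration")
}

#' Convert expression values to absolute molecule counts
#'
#' Per-feature copies are `10^(intercept + slope * log10(FPKM))`; features
#' with zero expression get zero copies. For circRNAs, use junction-read
#' derived expression with the circle length as feature length (see
#' [fpkm()]).
#'
#' @param expression numeric vector of FPKM values.
#' @param calibration an `ercc_calibration` from [ercc_calibrate()].
#' @return list with `copies` (per feature) and `total`.
#' @export
absolute_copies <- function(expression, calibration) {
  stopifnot_named("calibration must come from ercc_calibrate()" =
                    inherits(calibration, "ercc_calibration"))
  copies <- ifelse(expression > 0,
                   10 ^ (calibration$intercept +
                           calibration$slope * log10(pmax(expression, 1e-300))),
                   0)
  list(copies = copies, total = sum(copies))
}

#' Detect poly(A)- genes from rRNA-depletion versus oligo(dT) enrichment
#'
#' A gene is called poly(A)- when it is at least `min_fold`-fold enriched in
#' the rRNA-depleted libraries relative to the oligo(dT)-enriched ones
#' (two-sample Student t-test on log2(FPKM+1), p < `max_p`), is still
#' expressed (mean FPKM > `min_double_dep_fpkm`) in libraries depleted of
#' both rRNA and polyadenylated RNA, and is at least `min_len` bp long.
#'
#' @param rrna_dep,polyA_enr,double_dep numeric FPKM matrices (genes x
#'   replicates) sharing row names.
#' @param gene_lengths named numeric vector of gene lengths (bp).
#' @param min_fold fold-enrichment threshold (inclusive).
#' @param max_p t-test p-value threshold (exclusive).
#' @param min_double_dep_fpkm expression floor in the double-depleted group
#'   (exclusive).
#' @param min_len minimum gene length (inclusive).
#' @return data.frame per gene with `fold`, `p`, `double_dep_fpkm`,
#'   `length`, logical `polyA_minus`, ordered as the input rows.
#' @export
polyA_minus_genes <- function(rrna_dep, polyA_enr, double_dep, gene_lengths,
                              min_fold = 2, max_p = 0.05,
                              min_double_dep_fpkm = 1, min_len = 300) {
  genes <- rownames(rrna_dep)
  stopifnot_named(
    "matrices must share genes (row names)" =
      identical(genes, rownames(polyA_enr)) &&
      identical(genes, rownames(double_dep)),
    "gene_lengths must cover all genes" = all(genes %in% names(gene_lengths))
  )
  mean_r <- rowMeans(rrna_dep)
  mean_p <- rowMeans(polyA_enr)
  fold <- mean_r / mean_p
  pval <- vapply(seq_along(genes), function(i) {
    a <- log2(rrna_dep[i, ] + 1)
    b <- log2(polyA_enr[i, ] + 1)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  dd <- rowMeans(double_dep)
  len <- gene_lengths[genes]
  data.frame(
    gene = genes, fold = fold, p = pval, double_dep_fpkm = dd,
    length = unname(len),
    polyA_minus = fold >= min_fold & pval < max_p &
      dd > min_double_dep_fpkm & len >= min_len,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

## Counts per million, by column.
cpm <- function(counts) {
  sweep(counts, 2L, colSums(counts), "/") * 1e6
}

default_count_test <- function(group_a, group_b) {
  ## two-sample t-test on log2(CPM+1), per gene
  a <- log2(group_a + 1)
  b <- log2(group_b + 1)
  vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
    stats::t.test(x, y)$p.value
  }, numeric(1))
}

#' Classify maternal and zygotic genes across the oocyte-to-two-cell
#' transition
#'
#' Maternal genes are at least `min_fold`-fold enriched in oocytes relative
#' to two-cell embryos with p < `max_p`; zygotic genes are at least
#' `min_fold`-fold enriched in two-cell embryos. Zygotic genes are
#' validated when transcription inhibition (alpha-Amanitine treatment)
#' abolishes their up-regulation: at least `min_fold`-fold higher in normal
#' than in treated two-cell embryos.
#'
#' Fold changes are computed on mean CPM with a pseudocount of 1. The
#' two-group test is pluggable; the default is a per-gene two-sample t-test
#' on log2(CPM+1).
#'
#' @param oocyte_counts,twocell_counts,treated_counts count matrices (genes
#'   x replicates) sharing row names; `treated_counts` may be NULL (then no
#'   validation is computed).
#' @param test_fn function(matrix_a, matrix_b) returning one p-value per
#'   gene, applied to CPM matrices.
#' @param min_fold fold-change threshold (inclusive).
#' @param max_p p-value threshold (exclusive).
#' @return list with `maternal`, `zygotic`, `validated_zygotic` (character
#'   vectors of gene ids) and `table` (per-gene statistics).
#' @export
classify_maternal_zygotic <- function(oocyte_counts, twocell_counts,
                                      treated_counts = NULL, test_fn = NULL,
                                      min_fold = 4, max_p = 0.05) {
  genes <- rownames(oocyte_counts)
  stopifnot_named(
    "count matrices must share genes (row names)" =
      identical(genes, rownames(twocell_counts)),
    "need >= 2 replicates per group" =
      ncol(oocyte_counts) >= 2L && ncol(twocell_counts) >= 2L
  )
  if (is.null(test_fn)) test_fn <- default_count_test
  oo <- cpm(oocyte_counts)
  tc <- cpm(twocell_counts)
  mean_oo <- rowMeans(oo)
  mean_tc <- rowMeans(tc)
  fold_oo <- (mean_oo + 1) / (mean_tc + 1)
  fold_tc <- (mean_tc + 1) / (mean_oo + 1)
  p <- test_fn(oo, tc)
  maternal <- fold_oo >= min_fold & p < max_p
  zygotic <- fold_tc >= min_fold & p < max_p
  validated <- rep(NA, length(genes))
  if (!is.null(treated_counts)) {
    stopifnot_named("treated matrix must share genes" =
                      identical(genes, rownames(treated_counts)))
    tr <- cpm(treated_counts)
    fold_val <- (mean_tc + 1) / (rowMeans(tr) + 1)
    validated <- zygotic & fold_val >= min_fold
  }
  tab <- data.frame(gene = genes, mean_oocyte_cpm = mean_oo,
                    mean_twocell_cpm = mean_tc, fold_oocyte = fold_oo,
                    fold_twocell = fold_tc, p = p, maternal = maternal,
                    zygotic = zygotic, validated_zygotic = validated,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(maternal = genes[maternal],
       zygotic = genes[zygotic],
       validated_zygotic = if (is.null(treated_counts)) character(0)
                           else genes[which(validated)],
       table = tab)
}

#' Count fragments per gene by anchor placement
#'
#' A light-weight fragment counter for simulated or desk-scale data: each
#' fragment is assigned to the gene whose span contains the placement of
#' its first read's head anchor (either orientation); ambiguous or
#' unplaced fragments are unassigned.
#'
#' @param reads1 read table (one row per fragment's read 1).
#' @param genome named character vector of chromosome sequences.
#' @param models a `gene_models` table.
#' @param max_hits anchor multimap cap.
#' @return list with `counts` (named per-gene fragment counts, all genes)
#'   and `total` (assigned fragments).
#' @export
count_gene_fragments <- function(reads1, genome, models, max_hits = 10L) {
  gidx <- tx_index(models)
  gspan <- do.call(rbind, lapply(split(gidx, gidx$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  anchors <- substring(reads1$seq, 1L, ANCHOR_LEN)
  long_enough <- nchar(reads1$seq) >= ANCHOR_LEN
  useq <- unique(anchors[long_enough])
  hits <- align_anchor_batch(useq, genome, max_mismatch = 0L,
                             max_hits = max_hits)
  counts <- stats::setNames(rep(0L, length(unique(gspan$gene_id))),
                            unique(gspan$gene_id))
  if (nrow(hits)) {
    ## gene per hit by interval containment
    hit_gene <- rep(NA_character_, nrow(hits))
    for (gi in seq_len(nrow(gspan))) {
      sel <- hits$chrom == gspan$chrom[gi] & hits$start >= gspan$start[gi] &
        (hits$start + ANCHOR_LEN) <= gspan$end[gi]
      hit_gene[sel] <- gspan$gene_id[gi]
    }
    ## unique gene per anchor sequence, NA when ambiguous
    by_anchor <- split(hit_gene, hits$anchor)
    anchor_gene <- vapply(by_anchor, function(g) {
      g <- unique(g[!is.na(g)])
      if (length(g) == 1L) g else NA_character_
    }, character(1))
    assigned <- anchor_gene[as.character(match(anchors, useq))]
    tb <- table(assigned[!is.na(assigned)])
    counts[names(tb)] <- as.integer(tb)
  }
  list(counts = counts, total = sum(counts))
}
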