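test_that("FPKM follows count / (kb) / (millions of fragments)", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(50, 2000, 5e6), 5)   # 50 / 2 / 5
  expect_error(fpkm(1, 0, 1e6), "> 0")
})

test_that("junction RPM normalises junction reads by total fragments", {
  expect_equal(junction_rpm(30, 15e6), 2)
  expect_equal(junction_rpm(0, 1e6), 0)
  expect_equal(junction_rpm(60, 30e6), junction_rpm(30, 15e6))
})

test_that("depth normalisations are invariant under joint scaling", {
  set.seed(1)
  for (i in 1:10) {
    cnt <- sample(1:500, 1L)
    len <- sample(300:5000, 1L)
    tot <- sample(1e5:1e7, 1L)
    k <- sample(2:20, 1L)
    expect_equal(fpkm(cnt * k, len, tot * k), fpkm(cnt, len, tot))
    expect_equal(junction_rpm(cnt * k, tot * k), junction_rpm(cnt, tot))
  }
})

test_that("host-normalised abundance divides junction reads by host FPKM", {
  expect_equal(host_normalized(4, 2), 2)
  expect_equal(host_normalized(4, 0, pseudocount = 0.1), 40)
  expect_equal(host_normalized(0, 7), 0)
})

test_that("noise-free spike-ins calibrate to slope 1 with perfect correlation", {
  spikes <- data.frame(id = sprintf("ERCC-%05d", 1:12),
                       known_copies = 10 ^ seq(1, 4, length.out = 12))
  spikes$fpkm <- 0.05 * spikes$known_copies  # exactly proportional
  cal <- ercc_calibrate(spikes)
  expect_equal(cal$slope, 1, tolerance = 1e-10)
  expect_equal(cal$r, 1, tolerance = 1e-10)
  ## doubling all copies shifts the intercept by log10(2), slope unchanged
  spikes2 <- spikes
  spikes2$known_copies <- spikes$known_copies * 2
  cal2 <- ercc_calibrate(spikes2)
  expect_equal(cal2$slope, cal$slope, tolerance = 1e-10)
  expect_equal(cal2$intercept - cal$intercept, log10(2), tolerance = 1e-10)
})

test_that("fewer than 8 detected spike-ins aborts calibration", {
  spikes <- data.frame(id = sprintf("ERCC-%05d", 1:10),
                       known_copies = 10 ^ seq(1, 4, length.out = 10),
                       fpkm = c(rep(0, 5), 1, 2, 4, 8, 16))
  expect_error(ercc_calibrate(spikes), "insufficient calibration points")
})

test_that("calibration absorbs multiplicative noise (slope within 10%)", {
  set.seed(42)
  spikes <- data.frame(id = sprintf("ERCC-%05d", 1:24),
                       known_copies = 10 ^ seq(1, 5, length.out = 24))
  spikes$fpkm <- 0.02 * spikes$known_copies * 10 ^ rnorm(24, 0, 0.1)
  cal <- ercc_calibrate(spikes)
  expect_lt(abs(cal$slope - 1), 0.1)
  expect_gt(cal$r, 0.99)
})

test_that("absolute copies interpolate spike-ins exactly when noise-free", {
  spikes <- data.frame(id = sprintf("ERCC-%05d", 1:12),
                       known_copies = 10 ^ seq(1, 4, length.out = 12))
  spikes$fpkm <- 0.05 * spikes$known_copies
  cal <- ercc_calibrate(spikes)
  ac <- absolute_copies(spikes$fpkm, cal)
  expect_equal(ac$copies, spikes$known_copies, tolerance = 1e-8)
  expect_equal(absolute_copies(0, cal)$copies, 0)
})

test_that("planted total molecule count is recovered within 20% under noise", {
  set.seed(7)
  spikes <- data.frame(id = sprintf("ERCC-%05d", 1:24),
                       known_copies = 10 ^ seq(1, 5, length.out = 24))
  spikes$fpkm <- 0.02 * spikes$known_copies * 10 ^ rnorm(24, 0, 0.1)
  cal <- ercc_calibrate(spikes)
  gene_copies <- 10 ^ runif(400, 1, 4.5)
  gene_copies <- gene_copies * 1e6 / sum(gene_copies)  # planted total 1e6
  gene_fpkm <- 0.02 * gene_copies * 10 ^ rnorm(400, 0, 0.1)
  ac <- absolute_copies(gene_fpkm, cal)
  expect_lt(abs(ac$total - 1e6) / 1e6, 0.20)
})

test_that("poly(A)- rules apply thresholds on fold, p, expression and length", {
  ## one gene exactly at the inclusive 2.0-fold boundary, clearly significant
  rr <- matrix(rep(c(8, 8.02, 7.98, 8), 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("gBoundary", "gShort"), NULL))
  pe <- rr / 2
  dd <- matrix(5, 2, 3, dimnames = list(rownames(rr), NULL))
  lens <- c(gBoundary = 1000, gShort = 250)
  res <- polyA_minus_genes(rr, pe, dd, lens)
  expect_true(res$polyA_minus[res$gene == "gBoundary"])
  expect_false(res$polyA_minus[res$gene == "gShort"])  # length < 300 bp
})

test_that("planted poly(A)- genes are recovered with null genes controlled", {
  set.seed(101)
  n_null <- 1000L; n_plant <- 50L
  genes <- c(sprintf("null%04d", seq_len(n_null)),
             sprintf("pos%03d", seq_len(n_plant)))
  ## null genes: same mean in both groups; planted: 4-fold enrichment,
  ## low within-group variance
  logm <- c(rnorm(n_null, 3, 1), rep(5, n_plant))
  sds <- c(rep(0.5, n_null), rep(0.25, n_plant))
  rr <- matrix(2 ^ (rep(logm, 4) + rnorm(length(logm) * 4, 0, sds)),
               ncol = 4, dimnames = list(genes, NULL))
  pe <- matrix(2 ^ (rep(logm - c(rep(0, n_null), rep(2, n_plant)), 4) +
                      rnorm(length(logm) * 4, 0, sds)),
               ncol = 4, dimnames = list(genes, NULL))
  dd <- matrix(2 ^ (rep(logm, 3)), ncol = 3, dimnames = list(genes, NULL))
  lens <- stats::setNames(rep(1000, length(genes)), genes)
  res <- polyA_minus_genes(rr, pe, dd, lens)
  planted <- grepl("^pos", res$gene)
  expect_true(all(res$polyA_minus[planted]))          # 100% recovery
  expect_lte(sum(res$polyA_minus[!planted]), 3L)      # nulls controlled
  ## p < 0.05 alone passes about 5% of null genes
  null_p_rate <- mean(res$p[!planted] < 0.05)
  expect_gt(null_p_rate, 0.03)
  expect_lt(null_p_rate, 0.08)
})

test_that("maternal/zygotic classification applies 4-fold and p rules", {
  set.seed(5)
  genes <- c("mat", "zyg", "flat2x", "none")
  base <- c(mat = 4000, zyg = 500, flat2x = 1000, none = 800)
  mk <- function(means, n_rep) {
    m <- vapply(seq_len(n_rep), function(i)
      round(means * exp(rnorm(length(means), 0, 0.05))), numeric(length(means)))
    rownames(m) <- genes
    m
  }
  oo <- mk(c(4000, 500, 1000, 800), 3)
  tc <- mk(c(500, 4000, 2000, 800), 3)       # mat down 8x, zyg up 8x, 2x up
  tr <- mk(c(500, 4000, 2000, 800), 3)       # treatment does NOT silence zyg
  res <- classify_maternal_zygotic(oo, tc, tr)
  expect_true("mat" %in% res$maternal)
  expect_true("zyg" %in% res$zygotic)
  expect_false("zyg" %in% res$validated_zygotic)  # unchanged under treatment
  expect_false("flat2x" %in% res$maternal)
  expect_false("flat2x" %in% res$zygotic)         # 2-fold is below threshold
  ## a treatment that silences transcription validates the zygotic gene
  tr2 <- mk(c(500, 400, 2000, 800), 3)
  res2 <- classify_maternal_zygotic(oo, tc, tr2)
  expect_true("zyg" %in% res2$validated_zygotic)
})

test_that("fragment counting by anchor placement matches the truth table", {
  sim <- default_sim()
  cnt <- count_gene_fragments(sim$reads1, sim$genome, sim$models)
  truth <- sim$truth$linear_truth
  truth$gene_id <- sub("_t1$", "", truth$transcript_id)
  for (i in seq_len(nrow(truth))) {
    ## fragments whose leading anchor spans a splice junction stay
    ## unassigned, so per-gene counts track the truth within that loss
    slack <- ceiling(0.3 * truth$fragments[i]) + 2L
    expect_gte(cnt$counts[[truth$gene_id[i]]] + slack, truth$fragments[i])
  }
  expect_gte(cnt$total, 0.7 * sum(truth$fragments))
})
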