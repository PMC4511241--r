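test_that("flanking introns are the ones immediately outside the circle", {
  loc <- toy_locus()
  call <- data.frame(chrom = "chr1", acceptor_start = 2500L,
                     donor_end = 4500L, transcript_id = "gA_t1",
                     stringsAsFactors = FALSE)
  fl <- flanking_introns(call, loc$models)
  expect_equal(fl$i_up, 2L)
  expect_equal(fl$i_down, 3L)
  ## upstream intron = intron 1 (between exons 1 and 2)
  expect_equal(fl$upstream$start, 1300)
  expect_equal(fl$upstream$end, 2500)
  expect_equal(fl$upstream$length, 1200)
  ## downstream intron = intron 3 (between exons 3 and 4)
  expect_equal(fl$downstream$start, 4500)
  expect_equal(fl$downstream$end, 6000)
  ## other introns: the one inside the circle (exons 2-3) and intron 4
  expect_equal(fl$other_lengths, c(4200 - 2800, 8000 - 6350))
})

test_that("a circle starting at the first exon has no upstream flank", {
  loc <- toy_locus()
  call <- data.frame(chrom = "chr1", acceptor_start = 1000L,
                     donor_end = 2800L, transcript_id = "gA_t1",
                     stringsAsFactors = FALSE)
  fl <- flanking_introns(call, loc$models)
  expect_null(fl$upstream)
  expect_false(is.null(fl$downstream))
})

test_that("minus-strand flanks follow transcript order, not genomic order", {
  loc <- toy_locus()
  ## circle over the middle exon of gB (transcript order index 2)
  call <- data.frame(chrom = "chr1", acceptor_start = 18000L,
                     donor_end = 18350L, transcript_id = "gB_t1",
                     stringsAsFactors = FALSE)
  fl <- flanking_introns(call, loc$models)
  ## upstream (transcript 5') intron lies genomically RIGHT of the exon
  expect_equal(fl$upstream$start, 18350)
  expect_equal(fl$upstream$end, 21000)
  ## downstream intron lies genomically LEFT
  expect_equal(fl$downstream$start, 15400)
  expect_equal(fl$downstream$end, 18000)
})

test_that("a planted 30-bp reverse-complement segment is found", {
  set.seed(10)
  up <- rand_seq(800)
  down <- rand_seq(800)
  seg <- substring(up, 200, 229)
  substr(down, 501, 530) <- rc_oracle_str(seg)
  pairs <- find_rc_pairs(up, down)
  expect_gte(nrow(pairs), 1L)
  expect_gte(pairs$aln_len[1L], 30L)
  expect_equal(pairs$down_start[1L], 501L)
  expect_equal(pairs$up_start[1L], 200L)
  expect_equal(pairs$up_end[1L], 229L)
})

test_that("a 24-bp exact RC match is below the length threshold", {
  set.seed(11)
  repeat {  # a background pair with no chance 11-mer seed of its own
    up <- rand_seq(300)
    down <- rand_seq(300)
    if (nrow(find_rc_pairs(up, down)) == 0L) break
  }
  seg <- substring(up, 100, 123)  # 24 bp
  substr(down, 150, 173) <- rc_oracle_str(seg)
  pairs <- find_rc_pairs(up, down)
  expect_true(all(pairs$aln_len >= 25L))
  ## the planted 24-mer alone must not be reported
  expect_false(any(pairs$down_start >= 145 & pairs$down_end <= 178))
})

test_that("RC search is symmetric under swapping introns with reverse complement", {
  set.seed(12)
  for (i in 1:5) {
    up <- rand_seq(600)
    down <- rand_seq(600)
    seg <- substring(up, 50, 50 + sample(27:45, 1L))
    at <- sample(200:400, 1L)
    substr(down, at, at + nchar(seg) - 1L) <- rc_oracle_str(seg)
    a <- find_rc_pairs(up, down)
    b <- find_rc_pairs(rc_oracle_str(down), rc_oracle_str(up))
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      ## the swap maps segment coordinates through the length reversal
      expect_setequal(nchar(down) - a$down_end + 1L, b$up_start)
      expect_setequal(nchar(up) - a$up_end + 1L, b$down_start)
      expect_equal(sort(a$score), sort(b$score))
    }
  }
})

test_that("seeded RC search equals the full-DP oracle on random intron pairs", {
  set.seed(13)
  for (i in 1:12) {
    up <- rand_seq(sample(400:1500, 1L))
    down <- rand_seq(sample(400:1500, 1L))
    if (i %% 3 == 0) {  # plant one RC segment
      seg <- substring(up, 30, 30 + sample(26:60, 1L))
      at <- sample(100:300, 1L)
      substr(down, at, at + nchar(seg) - 1L) <- rc_oracle_str(seg)
    }
    mine <- find_rc_pairs(up, down)
    oracle <- rc_finder_oracle(up, down)
    expect_true(rc_sets_agree(mine, oracle),
                info = paste("instance", i))
  }
})

test_that("RC classification distinguishes NonRC / RC-repeats / RC-Nonrepeats", {
  repeats <- data.frame(chrom = "chr1", start = 5000L, end = 5300L,
                        family = "SINE", stringsAsFactors = FALSE)
  none <- data.frame()[0, ]
  expect_equal(classify_rc(NULL, repeats, "chr1"), "NonRC")
  pair_in <- data.frame(up_gstart = 5100, up_gend = 5140,
                        down_gstart = 9000, down_gend = 9040)
  expect_equal(classify_rc(pair_in, repeats, "chr1"), "RC-repeats")
  pair_out <- data.frame(up_gstart = 7000, up_gend = 7040,
                         down_gstart = 9000, down_gend = 9040)
  expect_equal(classify_rc(pair_out, repeats, "chr1"), "RC-Nonrepeats")
  expect_equal(classify_rc(pair_out, NULL, "chr1"), "RC-Nonrepeats")
})

test_that("RC distance sums the gaps to both splice sites", {
  up_len <- 6000L
  ## both segments abutting their splice sites
  abut <- data.frame(up_start = 5971L, up_end = 6000L,
                     down_start = 1L, down_end = 30L)
  expect_equal(rc_distance(abut, up_len)$nearest, 0)
  ## 2 kb and 4 kb away
  far <- data.frame(up_start = 3971L, up_end = 4000L,
                    down_start = 4001L, down_end = 4030L)
  expect_equal(rc_distance(far, up_len)$nearest, 6000)
  ## nearest pair = minimum of sums (brute force over pairs)
  pairs <- rbind(abut, far,
                 data.frame(up_start = 5001L, up_end = 5030L,
                            down_start = 501L, down_end = 530L))
  brute <- min((up_len - pairs$up_end) + (pairs$down_start - 1))
  expect_equal(rc_distance(pairs, up_len)$nearest, brute)
})

test_that("repeat density counts overlapping elements per kb", {
  intron <- list(chrom = "chr1", start = 1000L, end = 2000L)
  reps <- data.frame(chrom = "chr1",
                     start = c(1100L, 1500L, 900L, 3000L, 1200L),
                     end = c(1160L, 1560L, 1050L, 3100L, 1260L),
                     family = c("SINE", "SINE", "SINE", "SINE", "LINE"),
                     stringsAsFactors = FALSE)
  ## two inside + one half-overlapping the boundary = 3 SINEs per kb
  expect_equal(repeat_density(intron, reps, "SINE"), 3)
  expect_equal(repeat_density(intron, reps, "LINE"), 1)
  expect_equal(repeat_density(intron, data.frame(), "SINE"), 0)
})

test_that("flanking introns are longer than other introns on planted structure", {
  sim <- default_sim()
  res <- call_circrnas(sim$reads1, sim$reads2, sim$genome, sim$models)
  feats <- circ_features(res$calls, sim$models, sim$genome)
  flank <- c(feats$upstream_intron_len, feats$downstream_intron_len)
  other <- feats$median_other_intron_len
  expect_gt(stats::median(flank, na.rm = TRUE),
            stats::median(other, na.rm = TRUE))
})

test_that("feature table classifies simulated calls end to end", {
  sim <- default_sim()
  res <- call_circrnas(sim$reads1, sim$reads2, sim$genome, sim$models)
  repeats <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), family = character(0))
  feats <- circ_features(res$calls, sim$models, sim$genome, repeats)
  expect_equal(nrow(feats), nrow(res$calls))
  expect_true(all(feats$rc_class %in% c("NonRC", "RC-repeats",
                                        "RC-Nonrepeats")))
  ## random intron pairs almost never share a qualifying RC alignment
  expect_gte(sum(feats$rc_class == "NonRC"), nrow(feats) - 2L)
})
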