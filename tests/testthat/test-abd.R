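genes1 <- geneDF("G1", chrom = "chr1", tss = 1e6)

test_that("a 150 bp peak becomes a 500 bp feature centred on its summit", {
  pk <- peakGR("chr1", 999925, 1000075, strength = 4, summit = 75)
  f <- buildHistoneFeatures(list(H3K27ac = pk), GenomicRanges::GRanges(),
                            genes1)
  expect_length(f, 1)
  expect_equal(GenomicRanges::width(f), 500)
  # summit at BED offset 75 -> 1-based position 1000001; the 500 bp
  # window is [summit - 250, summit + 249]
  expect_equal(GenomicRanges::start(f), 1000001 - 250)
  expect_equal(f$activity, 4)  # geometric mean of one mark
  expect_equal(f$kind, "histone")
})

test_that("blacklisted features are removed after extension", {
  pk <- peakGR("chr1", c(999925, 1100000), c(1000075, 1100150),
               strength = 4)
  # blacklist overlaps the second peak's extended footprint only
  bl <- bedGR("chr1", 1100300, 1100400)
  f <- buildHistoneFeatures(list(H3K27ac = pk), bl, genes1)
  expect_length(f, 1)
  expect_lt(GenomicRanges::start(f), 1050000)
})

test_that("cross-mark activity is the geometric mean over present marks", {
  mk <- function(mark, strength) peakGR("chr1", 999925, 1000075,
                                        strength = strength, summit = 75,
                                        mark = mark)
  f <- buildHistoneFeatures(list(H3K27ac = mk("H3K27ac", 2),
                                 H3K4me1 = mk("H3K4me1", 8)),
                            GenomicRanges::GRanges(), genes1)
  expect_length(f, 1)
  expect_equal(f$activity, 4)  # sqrt(2 * 8); third mark absent
  expect_equal(unname(f$s_H3K27ac), 2)
  expect_equal(unname(f$s_H3K4me1), 8)
  expect_true(is.na(f$s_H3K4me3))
})

test_that("merged features are non-overlapping, blacklist-free, and stable", {
  set.seed(61)
  st <- sort(sample(seq(900000, 1100000, by = 40), 60)) + 0
  pk <- peakGR("chr1", st, st + 150,
               strength = rlnorm(60, 1, 0.5),
               summit = sample(0:149, 60, replace = TRUE))
  bl <- bedGR("chr1", c(950000, 1050000), c(951000, 1051000))
  f <- buildHistoneFeatures(list(H3K27ac = pk), bl, genes1)
  expect_gt(length(f), 0)
  self <- IRanges::findOverlaps(f, drop.self = TRUE, ignore.strand = TRUE)
  expect_length(self, 0)
  expect_false(any(IRanges::overlapsAny(f, bl, ignore.strand = TRUE)))
  expect_true(all(f$activity > 0))

  # idempotence on non-merging 500 bp output: re-processing the features
  # as summit-less 500 bp peaks reproduces them exactly
  single <- peakGR("chr1", c(999925, 1050000), c(1000075, 1050150),
                   strength = c(3, 5))
  f1 <- buildHistoneFeatures(list(H3K27ac = single),
                             GenomicRanges::GRanges(), genes1)
  asPeaks <- f1
  asPeaks$strength <- f1$activity
  asPeaks$summit <- -1
  asPeaks$mark <- "H3K27ac"
  f2 <- suppressWarnings(buildHistoneFeatures(list(H3K27ac = asPeaks),
                                              GenomicRanges::GRanges(),
                                              genes1))
  expect_equal(GenomicRanges::start(f2), GenomicRanges::start(f1))
  expect_equal(GenomicRanges::end(f2), GenomicRanges::end(f1))
  expect_equal(f2$activity, f1$activity)

  # non-150 bp inputs warn but are processed
  odd <- peakGR("chr1", 999900, 1000100, strength = 2)
  expect_warning(buildHistoneFeatures(list(H3K27ac = odd),
                                      GenomicRanges::GRanges(), genes1),
                 "non-150")
})

test_that("DHS features honor the TSS window, 350 bp recentering, and mean activity", {
  dhs <- peakGR("chr1", 1049900, 1050200, strength = 6, summit = 150,
                mark = "DHS")  # 50 kb from the TSS
  f <- buildDhsFeatures(dhs, genes1)
  expect_length(f, 1)
  expect_equal(GenomicRanges::width(f), 350)
  expect_equal(f$activity, 6)

  far <- peakGR("chr1", 1150000, 1150300, strength = 6, mark = "DHS")
  expect_length(buildDhsFeatures(far, genes1), 0)

  # two overlapping DHS merge with arithmetic-mean activity
  two <- peakGR("chr1", c(1049900, 1050000), c(1050200, 1050300),
                strength = c(3, 5), summit = c(150, 150), mark = "DHS")
  f2 <- buildDhsFeatures(two, genes1)
  expect_length(f2, 1)
  expect_equal(f2$activity, 4)
})

test_that("ABD scores normalize, scale-invariate, and decay with distance", {
  feat <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1009750, 1019750), width = 500))
  feat$activity <- c(2, 2)
  gene <- list(chrom = "chr1", tss = 1e6)
  # midpoints ~10 kb and ~20 kb from the TSS
  sc <- abdScores(feat, gene)
  expect_equal(sc$score, c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(sum(sc$score), 1, tolerance = 1e-9)

  feat2 <- feat; feat2$activity <- feat$activity * 7
  expect_equal(abdScores(feat2, gene)$score, sc$score, tolerance = 1e-12)

  one <- feat[1]
  expect_equal(abdScores(one, gene)$score, 1)

  none <- GenomicRanges::GRanges()
  expect_equal(nrow(abdScores(none, gene)), 0)
  offwin <- feat
  expect_equal(nrow(abdScores(offwin, list(chrom = "chr1", tss = 9e9))), 0)

  # the distance floor caps the proximity advantage of TSS-spanning features
  span <- GenomicRanges::GRanges("chr1", IRanges::IRanges(999751, 1000250))
  span$activity <- 1
  expect_equal(abdScores(span, gene)$d, 250)

  # strictly decreasing in d at fixed activity and competitor set
  set.seed(62)
  mids <- seq(1005000, 1100000, by = 5000)
  f3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(mids - 250,
                                                        width = 500))
  f3$activity <- 1
  sc3 <- abdScores(f3, gene)
  expect_true(all(diff(sc3$score[order(sc3$d)]) < 0))
})

test_that("variant annotation respects categories and the half-open edge", {
  hist <- bedGR("chr1", 1000, 1500); hist$activity <- 1
  dhs <- bedGR("chr1", 5000, 5350); dhs$activity <- 1
  hmm <- c(GenomicRanges::GRanges("chr1", IRanges::IRanges(9001, 10000),
                                  state = "7_Enh"),
           GenomicRanges::GRanges("chr1", IRanges::IRanges(12001, 13000),
                                  state = "9_Het"))
  v <- data.frame(id = paste0("v", 1:5), chrom = "chr1",
                  pos = c(1200, 5100, 9500, 12500, 1500),
                  pip = c(0.9, 0.8, 0.95, 0.99, 0.75))
  ann <- annotateVariants(v, hist, dhs, hmm)
  expect_equal(ann$in_histone, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(ann$in_dhs, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(ann$in_chromhmm_enhancer,
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(ann$in_any_regulatory,
               c(TRUE, TRUE, TRUE, FALSE, TRUE))

  # BED end coordinate is exclusive: position 1500 is in [1000,1500),
  # position 1501 is not
  v2 <- data.frame(id = "x", chrom = "chr1", pos = 1501, pip = 1)
  expect_false(annotateVariants(v2, hist, dhs, hmm)$in_histone)
})

test_that("top-ABD implication requires a high-PIP variant in the top feature", {
  feat <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1009750, 1019750), width = 500))
  feat$activity <- c(5, 1)
  gene <- list(chrom = "chr1", tss = 1e6)
  sc <- abdScores(feat, gene)

  inTop <- data.frame(id = "a", chrom = "chr1", pos = 1009900, pip = 0.9)
  inOther <- data.frame(id = "b", chrom = "chr1", pos = 1019900,
                        pip = 0.9)
  expect_true(topAbdImplication(gene, sc, inTop)$implicated)
  expect_false(topAbdImplication(gene, sc, inOther)$implicated)
  expect_false(topAbdImplication(gene, sc,
                                 inTop[0, , drop = FALSE])$implicated)
  expect_false(topAbdImplication(gene, sc[0, ], inTop)$implicated)

  # score ties break by smaller distance
  tied <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1009750, 1019750), width = 500))
  tied$activity <- c(1, 2)  # activity ratio == distance ratio -> tie
  scT <- abdScores(tied, gene)
  expect_equal(scT$score[1], scT$score[2], tolerance = 1e-12)
  top <- topAbdImplication(gene, scT, inTop)$topFeature
  expect_equal(top$d, min(scT$d))
})
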