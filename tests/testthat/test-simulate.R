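test_that("AR(1) LD has the closed form and stays PSD over random draws", {
  expect_equal(unname(corMatrix(simulateLD(5, 0))), diag(5))
  ld <- simulateLD(10, 0.5)
  expect_equal(corMatrix(ld)["v1", "v3"], 0.25)
  expect_error(simulateLD(5, 1), "rho")

  set.seed(101)
  for (i in 1:25) {
    n <- sample(2:40, 1); rho <- runif(1, 0, 0.99)
    r <- corMatrix(simulateLD(n, rho))   # constructor runs validity
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_equal(max(abs(diag(r) - 1)), 0)
  }
})

test_that("null loci give standard-normal marginals and nominal type-I", {
  set.seed(202)
  z <- unlist(lapply(1:2000, function(i) {
    assocStats(simulateLocusPair(simLocusSpec(10, 0.5))$gwas)$z
  }))
  expect_lt(abs(mean(z)), 3 / sqrt(2000))
  expect_lt(abs(var(z) - 1), 0.1)
  p <- 2 * pnorm(-abs(z))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("simulated tables satisfy the summary-statistic invariants", {
  set.seed(303)
  lp <- simulateLocusPair(simLocusSpec(30, 0.8, nGwas = 5000, nEqtl = 400,
                                       gwasCausal = 10, eqtlCausal = 10,
                                       ncpGwas = 5, ncpEqtl = 5))
  for (tb in list(lp$gwas, lp$eqtl)) {
    st <- assocStats(tb)
    expect_true(all(abs(st$z - st$beta / st$se) < 1e-6))
    expect_true(all(abs(st$p - 2 * pnorm(-abs(st$z))) < 1e-12))
  }
  expect_equal(assocStats(lp$gwas)$se, rep(1 / sqrt(5000), 30))
  expect_equal(assocStats(lp$eqtl)$se, rep(1 / sqrt(400), 30))
  # truth is consistent with the locus
  expect_true(lp$truth$gwas_causal_id %in% variantIds(lp$gwas))
  expect_true(lp$truth$shared)
})

test_that("a strong shared causal variant is usually the lead", {
  set.seed(404)
  rec <- replicate(500, {
    lp <- simulateLocusPair(simLocusSpec(50, 0.9, gwasCausal = 25,
                                         eqtlCausal = 25, ncpGwas = 8,
                                         ncpEqtl = 8))
    c(which.max(abs(assocStats(lp$gwas)$z)) == 25,
      which.max(abs(assocStats(lp$eqtl)$z)) == 25)
  })
  expect_gte(mean(rec[1, ]), 0.6)
  expect_gte(mean(rec[2, ]), 0.6)
})

test_that("distinct causals at near-zero LD give uncorrelated leads", {
  set.seed(505)
  # moderate signal so the leads vary from seed to seed
  leads <- replicate(300, {
    lp <- simulateLocusPair(simLocusSpec(40, 0.05, gwasCausal = 10,
                                         eqtlCausal = 30, ncpGwas = 2,
                                         ncpEqtl = 2))
    c(which.max(abs(assocStats(lp$gwas)$z)),
      which.max(abs(assocStats(lp$eqtl)$z)))
  })
  expect_gt(sd(leads[1, ]), 0)
  expect_lt(abs(cor(leads[1, ], leads[2, ])), 0.2)
})

test_that("chromatin tracks honor density, determinism, and coverage", {
  genes <- geneDF(c("G1", "G2"), chrom = c("chr1", "chr2"),
                  tss = c(1e6, 2e6))
  none <- simulateChromatin(genes, list(peaksPerGene = 0,
                                        blacklistFraction = 0), seed = 1)
  expect_length(none$histone$H3K27ac, 0)
  expect_length(none$dhs, 0)
  expect_gt(length(none$chromhmm), 0)

  a <- simulateChromatin(genes, seed = 9)
  b <- simulateChromatin(genes, seed = 9)
  expect_identical(as.data.frame(a$histone$H3K4me1),
                   as.data.frame(b$histone$H3K4me1))
  expect_identical(as.data.frame(a$dhs), as.data.frame(b$dhs))

  # histone peaks are 150 bp; DHS widths within 100-400
  expect_true(all(GenomicRanges::width(a$histone$H3K27ac) == 150))
  expect_true(all(GenomicRanges::width(a$dhs) >= 100 &
                  GenomicRanges::width(a$dhs) <= 400))

  cv <- data.frame(chrom = c("chr1", "chr1"), pos = c(1000500, 1001700))
  cov <- simulateChromatin(genes, list(coverVariants = cv,
                                       coverFraction = 1), seed = 2)
  for (m in names(cov$histone))
    expect_true(all(pointsInRanges(cv$chrom, cv$pos, cov$histone[[m]])))
})

test_that("pext simulation respects the coding-fraction dial", {
  v <- data.frame(id = paste0("v", 1:200))
  px0 <- simulatePext(v, "G1", "liver", codingFraction = 0, seed = 3)
  expect_true(all(px0$isoform_frac < 0.25))
  sel <- selectCodingVariants(px0, "G1", "liver")
  expect_length(sel$selected, 0)

  px1 <- simulatePext(v, "G1", "liver", codingFraction = 1, seed = 3)
  expect_true(all(px1$isoform_frac >= 0.25))
  expect_identical(simulatePext(v, "G1", "liver", seed = 5),
                   simulatePext(v, "G1", "liver", seed = 5))
  # designated non-coding ids never pass the variant filter
  px <- simulatePext(v, "G1", "liver", codingFraction = 1,
                     nonCoding = c("v1", "v2"), seed = 4)
  expect_true(all(px$isoform_frac[px$variant %in% c("v1", "v2")] < 0.25))
})

test_that("a study bundle is internally consistent and reproducible", {
  study <- simulateStudy(list(nGenes = 10, colocFraction = 0.5), seed = 6)
  expect_equal(nrow(study$genes), 10)
  expect_equal(sum(study$truth$shared), 5)
  expect_setequal(study$truth$gene, study$genes$symbol)
  for (g in study$genes$symbol) {
    tr <- study$truth[study$truth$gene == g, ]
    expect_true(tr$gwas_causal_id %in% variantIds(study$loci[[g]]$gwas))
  }

  empty <- simulateStudy(list(nGenes = 0), seed = 6)
  expect_equal(nrow(empty$genes), 0)
  expect_length(empty$loci, 0)

  expect_error(simulateStudy(list(colocFraction = 1.5)), "inconsistent")

  # same seed -> byte-identical written directory
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStudy(simulateStudy(list(nGenes = 3), seed = 8), d1)
  writeStudy(simulateStudy(list(nGenes = 3), seed = 8), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
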