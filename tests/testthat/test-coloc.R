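test_that("Wakefield log-ABF matches its closed form and a quadrature oracle", {
  # z = 0: labf = 0.5 log(V/(V+W)) < 0
  expect_equal(wakefieldLABF(0, 1, priorSd = 0.15),
               0.5 * log(1 / 1.0225))
  expect_lt(wakefieldLABF(0, 1), 0)

  # numerical-integration oracle of the normal-normal Bayes factor:
  # BF = int N(betahat; b, V) N(b; 0, W) db / N(betahat; 0, V)
  quadLABF <- function(z, se, w) {
    bh <- z * se
    num <- integrate(function(b) dnorm(bh, b, se) * dnorm(b, 0, sqrt(w)),
                     -Inf, Inf, rel.tol = 1e-12)$value
    log(num) - dnorm(bh, 0, se, log = TRUE)
  }
  expect_equal(wakefieldLABF(5, 1, priorSd = 0.15),
               quadLABF(5, 1, 0.0225), tolerance = 1e-6)
  expect_equal(wakefieldLABF(2.5, 0.05, priorSd = 0.15),
               quadLABF(2.5, 0.05, 0.0225), tolerance = 1e-6)

  # strictly increasing in |z| at fixed V, W
  zs <- seq(0, 8, by = 0.5)
  expect_true(all(diff(wakefieldLABF(zs, 0.1)) > 0))
  expect_error(wakefieldLABF(1, 0), "se")
})

test_that("single-effect PIPs are softmax of ABFs with the right shape", {
  # all z equal -> uniform
  fm <- finemapPIPs(zTable(rep(2, 8)))
  expect_equal(unname(fm$pip), rep(1 / 8, 8))
  expect_equal(sum(fm$pip), 1, tolerance = 1e-6)

  # one dominant variant at low LD -> PIP > 0.99
  fm <- finemapPIPs(zTable(c(10, rep(0, 19))))
  expect_gt(fm$pip[["v1"]], 0.99)
  expect_true("v1" %in% fm$credibleSet)

  expect_error(finemapPIPs(zTable(c(1, 2)), L = 3), "L exceeds")
})

test_that("stepwise multi-effect PIPs bound sums and find both causals", {
  set.seed(51)
  ld <- simulateLD(40, 0.5)
  # two well-separated strong effects
  r <- corMatrix(ld)
  lambda <- numeric(40); lambda[c(10, 30)] <- 7
  z <- drop(r %*% lambda) + drop(crossprod(chol(r), rnorm(40)))
  tb <- zTable(z)
  fm <- finemapPIPs(tb, ld, L = 2)
  expect_lte(sum(fm$pip), 2 + 1e-6)
  expect_true(all(fm$pip >= 0 & fm$pip <= 1))
  top2 <- names(sort(fm$pip, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("v10", "v30"))
})

test_that("fine-mapping recovers a simulated single causal variant", {
  set.seed(52)
  ld <- simulateLD(50, 0.5)
  hit <- replicate(500, {
    lp <- simulateLocusPair(simLocusSpec(50, 0.5, gwasCausal = 25,
                                         ncpGwas = 7), ld = ld)
    names(which.max(finemapPIPs(lp$gwas)$pip)) == "v25"
  })
  expect_gte(mean(hit), 0.95)  # oracle-fixed: 1.000 over 500 seeds
})

test_that("ABF colocalization posteriors normalize and obey symmetries", {
  set.seed(53)
  # normalization on random loci
  for (i in 1:300) {
    n <- sample(1:60, 1)
    g <- zTable(rnorm(n, sd = sample(1:4, 1)))
    e <- zTable(rnorm(n, sd = sample(1:4, 1)), n = 500)
    pp <- colocPP(colocABF(g, e))
    expect_lt(abs(sum(pp) - 1), 1e-9)
    expect_true(all(pp >= 0 & pp <= 1))
  }

  # swapping inputs swaps pp1/pp2, fixes pp0, pp3, pp4
  g <- zTable(c(5, 1, 0.3, -2)); e <- zTable(c(0.1, 4, -1, 2), n = 500)
  a <- colocPP(colocABF(g, e)); b <- colocPP(colocABF(e, g))
  expect_equal(a[["pp1"]], b[["pp2"]], tolerance = 1e-12)
  expect_equal(a[["pp2"]], b[["pp1"]], tolerance = 1e-12)
  expect_equal(a[c("pp0", "pp3", "pp4")], b[c("pp0", "pp3", "pp4")],
               tolerance = 1e-12)

  # single-variant locus: no distinct-variant pair exists
  pp1v <- colocPP(colocABF(zTable(3), zTable(2, n = 500)))
  expect_identical(unname(pp1v[["pp3"]]), 0)

  # misaligned variant lists are an error, not an intersection
  g4 <- zTable(rnorm(4)); e5 <- zTable(rnorm(5), n = 500)
  expect_error(colocABF(g4, e5), "alignment")
})

test_that("coloc matches brute-force configuration enumeration on tiny loci", {
  enumColoc <- function(g, e, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
    s1 <- assocStats(g); s2 <- assocStats(e)
    bf1 <- exp(wakefieldLABF(s1$z, s1$se))
    bf2 <- exp(wakefieldLABF(s2$z, s2$se))
    n <- length(bf1)
    s <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
    for (i in seq_len(n)) {
      s["h1"] <- s["h1"] + p1 * bf1[i]
      s["h2"] <- s["h2"] + p2 * bf2[i]
      s["h4"] <- s["h4"] + p12 * bf1[i] * bf2[i]
      for (j in seq_len(n))
        if (i != j) s["h3"] <- s["h3"] + p1 * p2 * bf1[i] * bf2[j]
    }
    unname(s / sum(s))
  }
  set.seed(54)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    g <- zTable(rnorm(n, sd = 2))
    e <- zTable(rnorm(n, sd = 2), n = 500)
    expect_equal(unname(colocPP(colocABF(g, e))), enumColoc(g, e),
                 tolerance = 1e-9)
  }
})

test_that("CLPP is the per-variant posterior product with its documented bounds", {
  mkPips <- function(p) list(pip = p)
  u <- setNames(rep(1 / 10, 10), paste0("v", 1:10))
  other <- setNames(c(0.9, rep(0.1 / 9, 9)), paste0("v", 1:10))
  res <- clpp(mkPips(u), mkPips(other))
  expect_lte(res$clppMax, max(other) / 10 + 1e-12)

  conc <- setNames(c(0.96, rep(0.04 / 9, 9)), paste0("v", 1:10))
  res <- clpp(mkPips(conc), mkPips(conc))
  expect_gt(res$clppMax, 0.9)
  expect_true(res$hit)

  a <- setNames(c(1, 0, 0), paste0("v", 1:3))
  b <- setNames(c(0, 1, 0), paste0("v", 1:3))
  expect_equal(clpp(mkPips(a), mkPips(b))$clppMax, 0)

  names(b) <- c("x", "y", "z")
  expect_error(clpp(mkPips(a), mkPips(b)), "alignment")
})

test_that("shared-causal loci colocalize far more often than distinct-causal", {
  set.seed(55)
  ld <- simulateLD(50, 0.9)
  rate <- function(gi, ei) mean(replicate(200, {
    lp <- simulateLocusPair(simLocusSpec(50, 0.9, gwasCausal = gi,
                                         eqtlCausal = ei, ncpGwas = 8,
                                         ncpEqtl = 8), ld = ld)
    colocPP(colocABF(lp$gwas, lp$eqtl))[["pp4"]] > 0.8
  }))
  shared <- rate(25, 25)
  distinct <- rate(15, 40)
  expect_gte(shared, 0.9)    # oracle-fixed: 0.995
  expect_lte(distinct, 0.1)  # oracle-fixed: 0.000
  expect_gt(shared, distinct)

  # distinct causals at low LD: pp3 is the modal hypothesis
  ldLow <- simulateLD(50, 0.3)
  modal <- replicate(200, {
    lp <- simulateLocusPair(simLocusSpec(50, 0.3, gwasCausal = 10,
                                         eqtlCausal = 40, ncpGwas = 8,
                                         ncpEqtl = 8), ld = ldLow)
    names(which.max(colocPP(colocABF(lp$gwas, lp$eqtl))))
  })
  expect_gte(mean(modal == "pp3"), 0.9)  # oracle-fixed: 0.995
})

test_that("high-PIP variant selection applies both the PIP and distance cuts", {
  tb <- zTable(c(10, 9.8, 0.1), spacing = 60000)  # positions 1e6, 1.06e6, 1.12e6
  fm <- list(pip = setNames(c(0.95, 0.8, 0.001), c("v1", "v2", "v3")))
  hp <- highPipVariants(tb, fm, tss = 1e6, pipThreshold = 0.7,
                        window = 1e5)
  expect_setequal(hp$id, c("v1", "v2"))
  hp2 <- highPipVariants(tb, fm, tss = 1e6, window = 5e4)
  expect_identical(hp2$id, "v1")
  hp3 <- highPipVariants(tb, fm, tss = 1e6, pipThreshold = 0.99)
  expect_equal(nrow(hp3), 0)
})
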