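# Small builders shared across the suite.

# AssocTable directly from a z vector (standardized scale, se = 1/sqrt(n))
zTable <- function(z, n = 10000, chrom = "chr1", start = 1e6,
                   spacing = 1000, trait = "trait", tissue = "",
                   prefix = "v") {
  k <- length(z)
  se <- rep(1 / sqrt(n), k)
  AssocTable(trait, data.frame(
    id = paste0(prefix, seq_len(k)), chrom = chrom,
    pos = start + spacing * (seq_len(k) - 1), ref = "A", alt = "G",
    beta = z * se, se = se, p = 2 * pnorm(-abs(z)), n = n),
    tissue = tissue)
}

# narrowPeak GRanges from BED-style 0-based coordinates
peakGR <- function(chrom, start, end, strength = 1, summit = -1,
                   mark = "H3K27ac") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  gr$name <- paste0("pk", seq_along(gr))
  gr$score <- 0
  gr$strand_ <- "."
  gr$strength <- strength
  gr$pval <- -1
  gr$qval <- -1
  gr$summit <- summit
  gr$mark <- mark
  gr
}

bedGR <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

geneDF <- function(symbol = "G1", chrom = "chr1", tss = 1e6,
                   trait = "trait", source = "mendelian") {
  data.frame(symbol = symbol, chrom = chrom, tss = tss, strand = "+",
             trait = trait, source = source, stringsAsFactors = FALSE)
}

# exhaustive two-sided Fisher p: sum of hypergeometric probabilities of
# all tables with the observed margins that are no more probable than
# the observed one (R's near-equality fudge applied)
fisherEnumP <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - n2); hi <- min(k, m)
  x <- lo:hi
  dens <- dhyper(x, m, n2, k)
  sum(dens[dens <= dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# textbook BH step-up by brute force: q_(i) = min_{j>=i} min(1, p_(j)*M/j)
bruteBH <- function(p, M = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * M / (i:m)))
  q[order(ord)]
}
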