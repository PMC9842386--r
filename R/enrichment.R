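#' @importFrom stats fisher.test quantile
NULL

#' Call GWAS loci by greedy clumping
#'
#' Repeatedly takes the smallest-p remaining variant below the
#' significance threshold as a lead and absorbs all variants within the
#' clump radius, until no significant variant remains.  Leads are
#' returned sorted by position.
#'
#' @param sumstats an [AssocTable-class].
#' @param pThreshold genome-wide significance threshold (default 5e-8).
#' @param clumpRadius absorption radius in bp (default 1 Mb).
#' @return data.frame with one row per locus: `trait, chrom, lead_id,
#'   lead_pos, lead_p, n_members`.
#' @export
callGwasLoci <- function(sumstats, pThreshold = 5e-8, clumpRadius = 1e6) {
  if (pThreshold <= 0 || pThreshold >= 1)
    stop("pThreshold must lie in (0, 1)")
  if (clumpRadius <= 0) stop("clumpRadius must be > 0")
  st <- assocStats(sumstats)
  remaining <- st
  loci <- list()
  while (nrow(remaining) && min(remaining$p) < pThreshold) {
    i <- which.min(remaining$p)
    lead <- remaining[i, ]
    member <- remaining$chrom == lead$chrom &
      abs(remaining$pos - lead$pos) <= clumpRadius
    loci[[length(loci) + 1L]] <- data.frame(
      trait = traitName(sumstats), chrom = lead$chrom,
      lead_id = lead$id, lead_pos = lead$pos, lead_p = lead$p,
      n_members = sum(member), stringsAsFactors = FALSE)
    remaining <- remaining[!member, , drop = FALSE]
  }
  if (!length(loci))
    return(data.frame(trait = character(), chrom = character(),
                      lead_id = character(), lead_pos = numeric(),
                      lead_p = numeric(), n_members = integer()))
  out <- do.call(rbind, loci)
  out[order(out$chrom, out$lead_pos), , drop = FALSE]
}

#' Distance from each gene's TSS to the nearest GWAS lead
#'
#' Distance is `|TSS - lead position|` on the same chromosome; genes on
#' chromosomes without any locus get an infinite distance and a FALSE
#' flag.  The near flag is inclusive: `distance <= window`.
#'
#' @param genes gene-record data.frame (`symbol, chrom, tss, trait`).
#' @param loci locus data.frame from [callGwasLoci()].
#' @param window near/far cut in bp.
#' @return data.frame `symbol, trait, distance, near`.
#' @export
genesNearLoci <- function(genes, loci, window) {
  if (window <= 0) stop("window must be > 0")
  dist <- vapply(seq_len(nrow(genes)), function(i) {
    onChrom <- loci$chrom == genes$chrom[i]
    if (!any(onChrom)) return(Inf)
    min(abs(loci$lead_pos[onChrom] - genes$tss[i]))
  }, numeric(1))
  data.frame(symbol = genes$symbol, trait = genes$trait,
             distance = dist, near = dist <= window,
             stringsAsFactors = FALSE)
}

#' Proximity enrichment of candidate genes near GWAS loci
#'
#' Builds the 2x2 near/far table of candidate vs non-candidate genes,
#' tests it with a two-sided Fisher exact test, and calibrates the
#' observed near count against a resampled random-gene null: the near
#' counts of `nResamples` draws of `|candidates|` genes taken uniformly
#' without replacement from the full gene list.  The odds ratio is the
#' sample odds ratio of the 2x2 table.
#'
#' @param candidates candidate gene-record data.frame.
#' @param background non-candidate gene-record data.frame (same schema).
#' @param loci locus data.frame from [callGwasLoci()].
#' @param window near/far cut in bp.
#' @param nResamples number of null draws (>= 100).
#' @return list with `window`, `observed`, `table` (2x2), `fisherP`,
#'   `oddsRatio`, `nullMean`, `nullCI` (2.5th/97.5th percentile),
#'   `nullDraws`.
#' @export
enrichmentTest <- function(candidates, background, loci, window,
                           nResamples = 1000) {
  if (nResamples < 100) stop("nResamples must be >= 100")
  all <- rbind(candidates[, c("symbol", "chrom", "tss", "trait")],
               background[, c("symbol", "chrom", "tss", "trait")])
  if (nrow(candidates) > nrow(all))
    stop("validation error: more candidates than genes")
  nf <- genesNearLoci(all, loci, window)
  isCand <- seq_len(nrow(all)) <= nrow(candidates)
  tab <- matrix(c(sum(nf$near & isCand), sum(!nf$near & isCand),
                  sum(nf$near & !isCand), sum(!nf$near & !isCand)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("candidate", "background"),
                                c("near", "far")))
  fisherP <- fisher.test(tab)$p.value
  oddsRatio <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  draws <- vapply(seq_len(nResamples), function(i)
    sum(nf$near[sample(nrow(all), nrow(candidates))]), numeric(1))
  list(window = window, observed = tab[1, 1], table = tab,
       fisherP = fisherP, oddsRatio = oddsRatio,
       nullMean = mean(draws),
       nullCI = unname(quantile(draws, c(0.025, 0.975))),
       nullDraws = draws)
}

#' Mismatched-trait enrichment controls
#'
#' Re-runs the proximity enrichment for rotated (gene-set trait, GWAS
#' trait) pairs, e.g. Crohn genes against breast-cancer loci.  The
#' rotation must be a fixed-point-free permutation of the traits.
#'
#' @param geneSets named list of candidate gene data.frames by trait.
#' @param lociByTrait named list of locus data.frames by trait.
#' @param rotation named character vector: `rotation[trait]` is the GWAS
#'   trait whose loci the gene set is tested against.
#' @param background background gene data.frame shared by all tests.
#' @param window,nResamples as in [enrichmentTest()].
#' @return named list of [enrichmentTest()] results, one per pair.
#' @export
mismatchedControls <- function(geneSets, lociByTrait, rotation,
                               background, window = 1e6,
                               nResamples = 1000) {
  if (any(names(rotation) == rotation))
    stop("validation error: rotation must have no fixed point")
  out <- list()
  for (g in names(rotation)) {
    t <- rotation[[g]]
    out[[paste(g, "vs", t)]] <-
      enrichmentTest(geneSets[[g]], background, lociByTrait[[t]],
                     window, nResamples)
  }
  out
}
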