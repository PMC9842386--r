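#' @importFrom stats rnorm rlnorm runif pnorm setNames
#' @importFrom utils modifyList
NULL

#' Simulate an AR(1) LD matrix
#'
#' Pairwise correlation `r[i, j] = rho^|i - j|`, positive semi-definite
#' by construction.  Variant ids are synthesized (`v1..vn`) with evenly
#' spaced positions; positions are attached as the `"pos"` attribute of
#' the returned matrix's variant vector by downstream locus builders.
#'
#' @param nVariants number of variants.
#' @param rho AR(1) decay parameter in [0, 1).
#' @param prefix variant-id prefix.
#' @return An [LDMatrix-class].
#' @export
simulateLD <- function(nVariants, rho, prefix = "v") {
  if (rho < 0 || rho >= 1)
    stop("validation error: rho must lie in [0, 1)")
  idx <- seq_len(nVariants)
  r <- rho ^ abs(outer(idx, idx, "-"))
  LDMatrix(paste0(prefix, idx), r)
}

# Cholesky with diagonal jitter fallback: AR(1) is PSD, but merged or
# edited matrices may not be numerically so.
.cholJitter <- function(r, jitter = 1e-8) {
  u <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(u)) u <- chol(r + diag(jitter, nrow(r)))
  u
}

#' Locus-pair simulation spec
#'
#' @param nVariants variants per locus.
#' @param ldDecay AR(1) rho.
#' @param nGwas,nEqtl sample sizes (se = 1/sqrt(n) on the standardized
#'   scale).
#' @param gwasCausal,eqtlCausal causal variant index (1-based) or NA for
#'   a null trait.
#' @param ncpGwas,ncpEqtl non-centrality of the causal z-score (>= 0).
#' @return a validated list of class `SimLocusSpec`.
#' @export
simLocusSpec <- function(nVariants = 50, ldDecay = 0.9,
                         nGwas = 10000, nEqtl = 500,
                         gwasCausal = NA, eqtlCausal = NA,
                         ncpGwas = 0, ncpEqtl = 0) {
  spec <- list(nVariants = nVariants, ldDecay = ldDecay, nGwas = nGwas,
               nEqtl = nEqtl, gwasCausal = gwasCausal,
               eqtlCausal = eqtlCausal, ncpGwas = ncpGwas,
               ncpEqtl = ncpEqtl)
  if (ncpGwas < 0 || ncpEqtl < 0)
    stop("validation error: non-centrality must be >= 0")
  for (f in c("gwasCausal", "eqtlCausal")) {
    v <- spec[[f]]
    if (!is.na(v) && (v < 1 || v > nVariants))
      stop("validation error: causal index out of range")
  }
  spec$shared <- !is.na(gwasCausal) && !is.na(eqtlCausal) &&
    gwasCausal == eqtlCausal
  class(spec) <- "SimLocusSpec"
  spec
}

.zToStats <- function(z, n, ids, chrom, pos, ref = "A", alt = "G") {
  se <- rep(1 / sqrt(n), length(z))
  data.frame(id = ids, chrom = chrom, pos = pos, ref = ref, alt = alt,
             beta = z * se, se = se, z = z, p = 2 * pnorm(-abs(z)),
             n = n, stringsAsFactors = FALSE)
}

#' Simulate a paired GWAS/eQTL locus
#'
#' Joint z-scores are drawn from a multivariate normal with mean
#' `R %*% lambda` and covariance `R`, where `lambda` carries the stated
#' non-centrality at the causal index and zero elsewhere.  On the
#' standardized scale se = 1/sqrt(n), beta = z * se, p two-sided normal.
#'
#' @param spec a [simLocusSpec()].
#' @param chrom chromosome label.
#' @param start first variant position; variants are spaced `spacing`
#'   bp apart.
#' @param spacing inter-variant spacing in bp.
#' @param prefix variant-id prefix.
#' @param trait,tissue labels for the two tables.
#' @param ld optional pre-built [LDMatrix-class] (must match
#'   `spec$nVariants`); rebuilt from the spec when NULL.
#' @return list with elements `gwas`, `eqtl` ([AssocTable-class]), `ld`
#'   ([LDMatrix-class]) and `truth` (1-row data.frame).
#' @export
simulateLocusPair <- function(spec, chrom = "chr1", start = 1e6,
                              spacing = 2000, prefix = "v",
                              trait = "trait", tissue = "tissue",
                              ld = NULL) {
  stopifnot(inherits(spec, "SimLocusSpec"))
  n <- spec$nVariants
  if (is.null(ld)) ld <- simulateLD(n, spec$ldDecay, prefix = prefix)
  r <- corMatrix(ld)
  u <- .cholJitter(r)
  lambdaG <- lambdaE <- numeric(n)
  if (!is.na(spec$gwasCausal)) lambdaG[spec$gwasCausal] <- spec$ncpGwas
  if (!is.na(spec$eqtlCausal)) lambdaE[spec$eqtlCausal] <- spec$ncpEqtl
  zG <- drop(r %*% lambdaG) + drop(crossprod(u, rnorm(n)))
  zE <- drop(r %*% lambdaE) + drop(crossprod(u, rnorm(n)))
  pos <- start + spacing * (seq_len(n) - 1)
  ids <- variantIds(ld)
  gwas <- AssocTable(trait, .zToStats(zG, spec$nGwas, ids, chrom, pos),
                     tissue = "", chrom = chrom, start = min(pos),
                     end = max(pos) + 1)
  eqtl <- AssocTable(trait, .zToStats(zE, spec$nEqtl, ids, chrom, pos),
                     tissue = tissue, chrom = chrom, start = min(pos),
                     end = max(pos) + 1)
  truth <- data.frame(
    shared = spec$shared,
    gwas_causal_id = if (is.na(spec$gwasCausal)) NA_character_
                     else ids[spec$gwasCausal],
    eqtl_causal_id = if (is.na(spec$eqtlCausal)) NA_character_
                     else ids[spec$eqtlCausal],
    stringsAsFactors = FALSE)
  list(gwas = gwas, eqtl = eqtl, ld = ld, truth = truth)
}

#' Simulate chromatin tracks around candidate genes
#'
#' Produces histone narrowPeak-style tracks (peaks exactly 150 bp wide,
#' matching the imputed Roadmap peak width the feature builder extends),
#' DHS peaks of width 100-400 bp, a ChromHMM tiling that partitions each
#' gene's locus, and blacklist intervals placed to hit a stated fraction
#' of peaks.
#'
#' @param genes gene-record data.frame (`symbol, chrom, tss, ...`).
#' @param config list: `peaksPerGene` (per mark; default 12),
#'   `strengthMeanlog`/`strengthSdlog` (log-normal signal, default 1 and
#'   0.5), `lociHalfWidth` bp around each TSS peaks are placed in
#'   (default 100000), `coverVariants` data.frame (`chrom, pos`) of
#'   designated variants, `coverFraction` of those variants that must be
#'   contained in >= 1 peak per mark (default 0), `blacklistFraction` of
#'   peaks hit by a blacklist interval (default 0.05), `tileWidth` for
#'   ChromHMM (default 5000), `enhancerFraction` of tiles labelled as an
#'   enhancer state (default 0.2).
#' @param seed optional integer; when given, seeds the RNG so repeated
#'   calls yield identical tracks.
#' @return list with `histone` (named list of GRanges per mark), `dhs`
#'   (GRanges), `chromhmm` (GRanges), `blacklist` (GRanges).
#' @export
simulateChromatin <- function(genes, config = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- modifyList(list(peaksPerGene = 12, strengthMeanlog = 1,
                         strengthSdlog = 0.5, lociHalfWidth = 1e5,
                         coverVariants = NULL, coverFraction = 0,
                         blacklistFraction = 0.05, tileWidth = 5000,
                         enhancerFraction = 0.2), config)
  marks <- c("H3K27ac", "H3K4me1", "H3K4me3")
  states <- c("1_TssA", "5_TxWk", "6_EnhG", "7_Enh", "9_Het", "15_Quies",
              "10_EnhBiv")
  enhStates <- c("6_EnhG", "7_Enh", "10_EnhBiv")
  histone <- setNames(vector("list", 3), marks)
  dhsList <- list(); tiles <- list()
  for (m in marks) histone[[m]] <- list()
  for (i in seq_len(nrow(genes))) {
    lo <- max(1, genes$tss[i] - cfg$lociHalfWidth)
    hi <- genes$tss[i] + cfg$lociHalfWidth
    chrom <- genes$chrom[i]
    for (m in marks) {
      k <- cfg$peaksPerGene
      if (k > 0) {
        st <- floor(runif(k, lo, hi - 150))
        gr <- GenomicRanges::GRanges(chrom, IRanges(st, width = 150))
        gr$name <- sprintf("%s_%s_pk%d", genes$symbol[i], m, seq_len(k))
        gr$score <- 0; gr$strand_ <- "."
        gr$strength <- rlnorm(k, cfg$strengthMeanlog, cfg$strengthSdlog)
        gr$pval <- -1; gr$qval <- -1
        gr$summit <- floor(runif(k, 0, 150))
        gr$mark <- m
        histone[[m]][[length(histone[[m]]) + 1L]] <- gr
      }
    }
    k <- cfg$peaksPerGene
    if (k > 0) {
      w <- floor(runif(k, 100, 401))
      st <- floor(runif(k, lo, hi - max(w)))
      gr <- GenomicRanges::GRanges(chrom, IRanges(st, width = w))
      gr$name <- sprintf("%s_DHS%d", genes$symbol[i], seq_len(k))
      gr$score <- 0; gr$strand_ <- "."
      gr$strength <- rlnorm(k, cfg$strengthMeanlog, cfg$strengthSdlog)
      gr$pval <- -1; gr$qval <- -1
      gr$summit <- floor(w / 2)
      gr$mark <- "DHS"
      dhsList[[length(dhsList) + 1L]] <- gr
    }
    # ChromHMM tiles partition the locus
    brk <- seq(lo, hi, by = cfg$tileWidth)
    if (brk[length(brk)] < hi) brk <- c(brk, hi)
    ts <- brk[-length(brk)]; te <- brk[-1]
    isEnh <- runif(length(ts)) < cfg$enhancerFraction
    lab <- ifelse(isEnh, sample(enhStates, length(ts), replace = TRUE),
                  sample(setdiff(states, enhStates), length(ts),
                         replace = TRUE))
    tiles[[length(tiles) + 1L]] <-
      GenomicRanges::GRanges(chrom, IRanges(ts, te - 1), state = lab)
  }
  catGR <- function(lst) {
    if (!length(lst)) return(GenomicRanges::GRanges())
    suppressWarnings(do.call(c, lst))  # differing seqlevels are expected
  }
  histone <- lapply(histone, catGR)
  dhs <- catGR(dhsList)
  chromhmm <- catGR(tiles)
  # peaks forced to cover designated variants
  cv <- cfg$coverVariants
  if (!is.null(cv) && nrow(cv) && cfg$coverFraction > 0) {
    keep <- seq_len(max(1, ceiling(cfg$coverFraction * nrow(cv))))
    if (cfg$coverFraction >= 1) keep <- seq_len(nrow(cv))
    for (j in keep) {
      for (m in marks) {
        st <- cv$pos[j] - 75
        gr <- GenomicRanges::GRanges(cv$chrom[j], IRanges(st, width = 150))
        gr$name <- sprintf("cover_%s_%d", m, j)
        gr$score <- 0; gr$strand_ <- "."
        gr$strength <- rlnorm(1, cfg$strengthMeanlog, cfg$strengthSdlog)
        gr$pval <- -1; gr$qval <- -1; gr$summit <- 75; gr$mark <- m
        histone[[m]] <- suppressWarnings(c(histone[[m]], gr))
      }
      gr <- GenomicRanges::GRanges(cv$chrom[j],
                                   IRanges(cv$pos[j] - 100, width = 200))
      gr$name <- sprintf("cover_DHS_%d", j)
      gr$score <- 0; gr$strand_ <- "."
      gr$strength <- rlnorm(1, cfg$strengthMeanlog, cfg$strengthSdlog)
      gr$pval <- -1; gr$qval <- -1; gr$summit <- 100; gr$mark <- "DHS"
      dhs <- suppressWarnings(c(dhs, gr))
    }
  }
  # blacklist intervals centred on a fraction of histone peaks
  allHist <- catGR(unname(histone))
  blacklist <- GenomicRanges::GRanges()
  if (length(allHist) && cfg$blacklistFraction > 0) {
    nbl <- ceiling(cfg$blacklistFraction * length(allHist))
    pick <- sample(length(allHist), nbl)
    blacklist <- GenomicRanges::granges(allHist[pick])
  }
  list(histone = histone, dhs = dhs, chromhmm = chromhmm,
       blacklist = blacklist)
}

#' Simulate a pext annotation table
#'
#' A configured fraction of variants is made "commonly coding"
#' (`expr_frac >= 0.5` and `isoform_frac >= 0.25`); the rest straddle
#' the two filter thresholds so the coding-variant selection has work to
#' do in both directions.
#'
#' @param variants data.frame with at least an `id` column.
#' @param gene,tissue labels.
#' @param codingFraction fraction of variants made commonly coding.
#' @param exprFrac the gene's tissue-expression fraction written to every
#'   row (the gene-level filter input).
#' @param nonCoding variant ids that must come out non-coding (e.g. the
#'   simulated causal variants and their strong LD proxies, so that the
#'   association signal survives conditioning as a non-coding signal).
#' @param seed optional integer RNG seed for reproducibility.
#' @return pext data.frame.
#' @export
simulatePext <- function(variants, gene, tissue, codingFraction = 0.2,
                         exprFrac = 0.8, nonCoding = character(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(variants)
  coding <- runif(nv) < codingFraction
  coding[variants$id %in% nonCoding] <- FALSE
  isoform <- ifelse(coding, runif(nv, 0.25, 1), runif(nv, 0, 0.25))
  data.frame(variant = variants$id, gene = gene, tissue = tissue,
             expr_frac = exprFrac, isoform_frac = isoform,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Bundles genes, per-gene paired GWAS/eQTL loci with controllable
#' colocalization structure, an LD matrix per locus, chromatin tracks,
#' a pext table, and a truth table recording which gene-trait pairs
#' share a causal variant.
#'
#' @param config list: `nGenes` (default 10), `colocFraction` of genes
#'   whose GWAS and eQTL share the causal variant (default 0.5),
#'   `nullFraction` genes with no GWAS signal at all (default 0),
#'   `nVariants`, `ldDecay`, `nGwas`, `nEqtl`, `ncp` (shared by both
#'   traits, default 8), `trait`, `tissue`, `spacing`, plus any
#'   [simulateChromatin()] config entries under `chromatin`.
#' @param seed integer RNG seed; one stream per call.
#' @return list of class `SimStudy` with elements `genes`, `loci`
#'   (per-gene list of `simulateLocusPair()` outputs), `tracks`, `pext`,
#'   `truth`.
#' @export
simulateStudy <- function(config = list(), seed = 1) {
  cfg <- modifyList(list(nGenes = 10, colocFraction = 0.5,
                         nullFraction = 0, nVariants = 50, ldDecay = 0.9,
                         nGwas = 10000, nEqtl = 500, ncp = 8,
                         trait = "trait1", tissue = "tissue1",
                         spacing = 2000, chromatin = list()), config)
  if (cfg$colocFraction < 0 || cfg$colocFraction > 1 ||
      cfg$nullFraction < 0 || cfg$nullFraction + cfg$colocFraction > 1)
    stop("validation error: inconsistent fractions in study config")
  set.seed(seed)
  nG <- cfg$nGenes
  if (nG == 0) {
    return(structure(list(genes = data.frame(), loci = list(),
                          tracks = NULL, pext = data.frame(),
                          truth = data.frame()), class = "SimStudy"))
  }
  locusSpan <- cfg$nVariants * cfg$spacing
  tssOffset <- floor(locusSpan / 2)
  genes <- data.frame(symbol = sprintf("GENE%02d", seq_len(nG)),
                      chrom = sprintf("chr%d", seq_len(nG)),
                      tss = 1e6 + tssOffset, strand = "+",
                      trait = cfg$trait, source = "mendelian",
                      stringsAsFactors = FALSE)
  nShared <- round(cfg$colocFraction * nG)
  nNull <- round(cfg$nullFraction * nG)
  kind <- c(rep("shared", nShared), rep("null", nNull),
            rep("distinct", nG - nShared - nNull))
  loci <- vector("list", nG)
  truth <- vector("list", nG)
  pext <- vector("list", nG)
  for (i in seq_len(nG)) {
    causal <- floor(cfg$nVariants / 2)
    spec <- switch(kind[i],
      shared = simLocusSpec(cfg$nVariants, cfg$ldDecay, cfg$nGwas,
                            cfg$nEqtl, gwasCausal = causal,
                            eqtlCausal = causal, ncpGwas = cfg$ncp,
                            ncpEqtl = cfg$ncp),
      distinct = simLocusSpec(cfg$nVariants, cfg$ldDecay, cfg$nGwas,
                              cfg$nEqtl, gwasCausal = causal,
                              eqtlCausal = min(cfg$nVariants, causal + 15),
                              ncpGwas = cfg$ncp, ncpEqtl = cfg$ncp),
      null = simLocusSpec(cfg$nVariants, cfg$ldDecay, cfg$nGwas,
                          cfg$nEqtl))
    lp <- simulateLocusPair(spec, chrom = genes$chrom[i], start = 1e6,
                            spacing = cfg$spacing,
                            prefix = sprintf("g%d_v", i),
                            trait = cfg$trait, tissue = cfg$tissue)
    loci[[i]] <- lp
    truth[[i]] <- cbind(data.frame(gene = genes$symbol[i],
                                   trait = cfg$trait,
                                   tissue = cfg$tissue,
                                   stringsAsFactors = FALSE),
                        lp$truth)
    # the trait signal is non-coding by construction: the causal
    # variants and their strong AR(1) LD proxies (within 10 positions)
    # never pass the coding filter, so conditioning removes coding
    # effects without erasing the locus
    st <- assocStats(lp$gwas)
    prox <- unique(unlist(lapply(
      c(spec$gwasCausal, spec$eqtlCausal), function(ci) {
        if (is.na(ci)) return(character())
        st$id[max(1, ci - 10):min(cfg$nVariants, ci + 10)]
      })))
    pext[[i]] <- simulatePext(st, genes$symbol[i], cfg$tissue,
                              nonCoding = prox)
  }
  names(loci) <- genes$symbol
  chromCfg <- cfg$chromatin
  if (is.null(chromCfg$coverVariants)) {
    # designate each locus's causal variant for peak coverage
    cv <- do.call(rbind, lapply(seq_len(nG), function(i) {
      st <- assocStats(loci[[i]]$gwas)
      cid <- truth[[i]]$gwas_causal_id
      if (is.na(cid)) return(NULL)
      data.frame(chrom = genes$chrom[i], pos = st$pos[st$id == cid])
    }))
    chromCfg$coverVariants <- cv
    if (is.null(chromCfg$coverFraction)) chromCfg$coverFraction <- 0.8
  }
  tracks <- simulateChromatin(genes, chromCfg)
  structure(list(genes = genes, loci = loci, tracks = tracks,
                 pext = do.call(rbind, pext),
                 truth = do.call(rbind, truth)),
            class = "SimStudy")
}

#' Write a SimStudy to a directory of plain-text files
#'
#' Emits exactly the package's external formats: per-gene summary
#' statistics and LD matrices, narrowPeak tracks, ChromHMM and blacklist
#' BEDs, pext and gene tables, and a `truth.tsv`.
#'
#' @param study a `SimStudy`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGeneTable(study$genes, file.path(dir, "genes.tsv"))
  writePextTable(study$pext, file.path(dir, "pext.tsv"))
  .writeTsv(study$truth, file.path(dir, "truth.tsv"))
  for (g in names(study$loci)) {
    lp <- study$loci[[g]]
    writeSumstats(lp$gwas, file.path(dir, paste0(g, "_gwas.tsv")))
    writeSumstats(lp$eqtl, file.path(dir, paste0(g, "_eqtl.tsv")))
    writeLDMatrix(lp$ld, file.path(dir, paste0(g, "_ld.txt")),
                  file.path(dir, paste0(g, "_ld.vars")))
  }
  if (!is.null(study$tracks)) {
    for (m in names(study$tracks$histone))
      writeNarrowPeak(study$tracks$histone[[m]],
                      file.path(dir, paste0(m, ".narrowPeak")))
    writeNarrowPeak(study$tracks$dhs, file.path(dir, "DHS.narrowPeak"))
    writeChromHMM(study$tracks$chromhmm, file.path(dir, "chromhmm.bed"))
    writeBedIntervals(study$tracks$blacklist,
                      file.path(dir, "blacklist.bed"))
  }
  invisible(dir)
}
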