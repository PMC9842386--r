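#' @importFrom GenomicRanges GRanges granges resize reduce
#' @importFrom IRanges IRanges overlapsAny findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

HISTONE_MARKS <- c("H3K27ac", "H3K4me1", "H3K4me3")

#' Configured ChromHMM enhancer-state labels
#'
#' Substring patterns mapping the verbal categories enhancer, genic
#' enhancer and bivalent enhancer onto 15-state model labels, robust to
#' spelling variation across model releases.
#' @export
ENHANCER_STATES <- c("Enh", "EnhG", "EnhBiv")

# midpoint position (1-based) of each range; defined so that
# re-centering a width-w window on its own midpoint reproduces it
.midpoint <- function(gr) floor((start(gr) + end(gr) + 1) / 2)

# re-center a fixed-width window on the summit (midpoint if summit < 0).
# summit is the offset from the 0-based BED start of gr, i.e. the summit
# position (1-based) is start(gr) + summit.
.recenter <- function(gr, width) {
  summit <- if (is.null(gr$summit)) rep(-1, length(gr)) else gr$summit
  centre <- ifelse(summit >= 0, start(gr) + summit, .midpoint(gr))
  GenomicRanges::GRanges(seqnames(gr),
                         IRanges(centre - floor(width / 2), width = width))
}

# restrict gr to ranges within +/- flank of any gene TSS
.nearGenes <- function(gr, genes, flank) {
  if (!length(gr)) return(gr)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges(pmax(1, genes$tss - flank),
                                        genes$tss + flank))
  gr[overlapsAny(gr, win, ignore.strand = TRUE)]
}

#' Build candidate histone regulatory features
#'
#' Per mark: restrict peaks to +/-5 Mb of the candidate genes, extend
#' the 150 bp narrow peaks by 175 bp on both sides to 500 bp candidate
#' features, drop any feature overlapping a blacklisted region by >= 1
#' bp, re-center a 500 bp window on the peak summit (midpoint when the
#' summit is absent), and merge overlapping features within the mark.
#' The three marks' merged features are then unioned and overlapping
#' ones merged across marks.  A merged feature's activity `A_F` is the
#' geometric mean, over marks with at least one overlapping peak, of
#' that mark's maximum overlapping signalValue.
#'
#' @param peaksByMark named list of narrowPeak GRanges (see
#'   [readNarrowPeak()]) for `H3K27ac`, `H3K4me1`, `H3K4me3`.
#' @param blacklist GRanges of excluded regions.
#' @param genes gene-record data.frame.
#' @param geneFlank restriction window around gene TSSs (default 5 Mb).
#' @return GRanges of features with metadata `activity` and per-mark
#'   strengths `s_<mark>` (NA where the mark contributed no peak).
#' @export
buildHistoneFeatures <- function(peaksByMark, blacklist, genes,
                                 geneFlank = 5e6) {
  perMark <- list()
  for (m in intersect(HISTONE_MARKS, names(peaksByMark))) {
    pk <- peaksByMark[[m]]
    if (!length(pk)) next
    if (any(GenomicRanges::width(pk) != 150))
      warning("non-150 bp input peak(s) for ", m,
              "; extended by 175 bp anyway")
    pk <- .nearGenes(pk, genes, geneFlank)
    if (!length(pk)) next
    ext <- GenomicRanges::GRanges(seqnames(pk),
                                  IRanges(start(pk) - 175, end(pk) + 175))
    mcols(ext) <- mcols(pk)
    # the summit offset is relative to the BED start, which just moved
    ext$summit <- ifelse(pk$summit >= 0, pk$summit + 175, -1)
    keep <- !overlapsAny(ext, blacklist, ignore.strand = TRUE)
    ext <- ext[keep]
    if (!length(ext)) next
    rec <- .recenter(ext, 500)
    mcols(rec) <- mcols(ext)
    merged <- reduce(rec, ignore.strand = TRUE)
    perMark[[m]] <- list(features = merged, peaks = rec)
  }
  if (!length(perMark)) {
    out <- GenomicRanges::GRanges()
    mcols(out) <- DataFrame(activity = numeric())
    return(out)
  }
  union <- reduce(do.call(c, lapply(unname(perMark),
                                    function(x) x$features)),
                  ignore.strand = TRUE)
  strengths <- matrix(NA_real_, nrow = length(union),
                      ncol = length(HISTONE_MARKS),
                      dimnames = list(NULL, HISTONE_MARKS))
  for (m in names(perMark)) {
    pk <- perMark[[m]]$peaks
    hits <- findOverlaps(union, pk, ignore.strand = TRUE)
    if (length(hits)) {
      mx <- tapply(pk$strength[subjectHits(hits)], queryHits(hits), max)
      strengths[as.integer(names(mx)), m] <- mx
    }
  }
  activity <- apply(strengths, 1, function(s) {
    s <- s[!is.na(s)]
    if (!length(s)) return(0)
    exp(mean(log(s)))
  })
  keep <- activity > 0
  out <- union[keep]
  md <- DataFrame(activity = activity[keep])
  for (m in HISTONE_MARKS) md[[paste0("s_", m)]] <- strengths[keep, m]
  md$kind <- "histone"
  mcols(out) <- md
  out
}

#' Build DHS regulatory features
#'
#' Keeps DHS within +/-100 kb of any candidate gene TSS, re-centers each
#' in a 350 bp window on its summit (midpoint if absent), merges
#' overlapping sites, and sets a merged feature's activity `A_F` to the
#' arithmetic mean of its merged sites' strengths.
#'
#' @param dhs narrowPeak GRanges of DHS.
#' @param genes gene-record data.frame.
#' @param tssFlank selection window (default 100 kb).
#' @return GRanges of features with metadata `activity`.
#' @export
buildDhsFeatures <- function(dhs, genes, tssFlank = 1e5) {
  empty <- function() {
    out <- GenomicRanges::GRanges()
    mcols(out) <- DataFrame(activity = numeric(), kind = character())
    out
  }
  if (!length(dhs)) return(empty())
  sel <- .nearGenes(dhs, genes, tssFlank)
  if (!length(sel)) return(empty())
  rec <- .recenter(sel, 350)
  mcols(rec) <- mcols(sel)
  merged <- reduce(rec, ignore.strand = TRUE)
  hits <- findOverlaps(merged, rec, ignore.strand = TRUE)
  act <- tapply(rec$strength[subjectHits(hits)], queryHits(hits), mean)
  merged$activity <- as.numeric(act[as.character(seq_along(merged))])
  merged$kind <- "DHS"
  merged
}

#' Activity-by-distance scores of features against one gene
#'
#' For every feature F within `window` of gene G's TSS,
#' \deqn{ABD_{F,G} = \frac{A_F / d_{F,G}}
#'       {\sum_{f\ within\ window} A_f / d_{f,G}}}
#' with d the TSS-to-feature-midpoint distance in bp, floored at 250 bp
#' (half the feature width) so a TSS-spanning feature cannot blow up the
#' ratio.  Scores over the denominator window sum to 1.
#'
#' @param features feature GRanges with an `activity` column.
#' @param gene one gene record (list/1-row data.frame with `chrom`,
#'   `tss`).
#' @param window denominator window in bp (default 5 Mb; use the
#'   selected-set convention for DHS by passing the DHS selection
#'   window).
#' @param dFloor distance floor in bp (default 250).
#' @return data.frame `feature_chrom, feature_start, feature_end,
#'   activity, d, score`, empty when no feature is in the window.
#' @export
abdScores <- function(features, gene, window = 5e6, dFloor = 250) {
  empty <- data.frame(feature_chrom = character(),
                      feature_start = numeric(),
                      feature_end = numeric(), activity = numeric(),
                      d = numeric(), score = numeric())
  if (!length(features)) return(empty)
  onChrom <- as.character(seqnames(features)) == gene$chrom
  d <- abs(.midpoint(features) - gene$tss)
  keep <- onChrom & d <= window
  if (!any(keep)) return(empty)
  f <- features[keep]
  d <- pmax(d[keep], dFloor)
  wgt <- f$activity / d
  data.frame(feature_chrom = as.character(seqnames(f)),
             feature_start = start(f), feature_end = end(f),
             activity = f$activity, d = d, score = wgt / sum(wgt),
             stringsAsFactors = FALSE)
}

#' Annotate fine-mapped variants against chromatin tracks
#'
#' Point-in-interval tests (package coordinate convention, see
#' [pointsInRanges()]) of each high-PIP variant against histone
#' features, DHS features, and ChromHMM segments whose state label
#' matches any configured enhancer pattern.  A variant may satisfy
#' several categories.
#'
#' @param variants data.frame `id, chrom, pos, pip` (e.g. from
#'   [highPipVariants()]).
#' @param histoneFeatures,dhsFeatures feature GRanges.
#' @param chromhmm segment GRanges with a `state` column.
#' @param enhancerStates substring patterns of enhancer state labels.
#' @return data.frame `id, chrom, pos, pip, in_histone, in_dhs,
#'   in_chromhmm_enhancer, in_any_regulatory`.
#' @export
annotateVariants <- function(variants, histoneFeatures, dhsFeatures,
                             chromhmm, enhancerStates = ENHANCER_STATES) {
  enh <- chromhmm[grepl(paste(enhancerStates, collapse = "|"),
                        chromhmm$state)]
  inH <- pointsInRanges(variants$chrom, variants$pos, histoneFeatures)
  inD <- pointsInRanges(variants$chrom, variants$pos, dhsFeatures)
  inE <- pointsInRanges(variants$chrom, variants$pos, enh)
  data.frame(variants, in_histone = inH, in_dhs = inD,
             in_chromhmm_enhancer = inE,
             in_any_regulatory = inH | inD | inE,
             stringsAsFactors = FALSE)
}

#' Top-ABD gene implication
#'
#' A gene is implicated iff at least one high-PIP variant lies inside
#' the single feature with the maximum ABD score for that gene.  Ties on
#' the score break by smaller distance, then leftmost start.
#'
#' @param gene one gene record.
#' @param abd [abdScores()] data.frame for the gene.
#' @param variants high-PIP variant data.frame (`chrom`, `pos`).
#' @return list with `implicated` (logical) and `topFeature` (1-row
#'   data.frame or NULL when no feature is in the window).
#' @export
topAbdImplication <- function(gene, abd, variants) {
  if (!nrow(abd)) return(list(implicated = FALSE, topFeature = NULL))
  ord <- order(-abd$score, abd$d, abd$feature_start)
  top <- abd[ord[1], , drop = FALSE]
  if (!nrow(variants))
    return(list(implicated = FALSE, topFeature = top))
  gr <- GenomicRanges::GRanges(top$feature_chrom,
                               IRanges(top$feature_start,
                                       top$feature_end))
  hit <- any(pointsInRanges(variants$chrom, variants$pos, gr))
  list(implicated = hit, topFeature = top)
}
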