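#' @importFrom stats pnorm
NULL

#' Select commonly coding variants from a pext table
#'
#' Two filters, applied per gene-tissue pair: (1) the gene is excluded
#' outright if its expression in the trait-relevant tissue is below 50%
#' of its maximum across tissues (`expr_frac < 0.5`); (2) among variants
#' of a retained gene, a variant is selected iff it falls within the
#' coding sequence of at least 25% of splice isoforms in that tissue
#' (`isoform_frac >= 0.25`; "less than 25%" is a strict exclusion, so
#' the 0.25 boundary is kept).
#'
#' @param pext pext data.frame (see [readPextTable()]).
#' @param gene,tissue the pair to select for.
#' @return list with `gene`, `tissue`, `selected` (character variant
#'   ids), `excludedGene` (logical).
#' @export
selectCodingVariants <- function(pext, gene, tissue) {
  rows <- pext[pext$gene == gene & pext$tissue == tissue, , drop = FALSE]
  if (!nrow(rows))
    stop("lookup error: (", gene, ", ", tissue, ") absent from pext table")
  excluded <- rows$expr_frac[1] < 0.5
  selected <- if (excluded) character() else
    rows$variant[rows$isoform_frac >= 0.25]
  list(gene = gene, tissue = tissue, selected = as.character(selected),
       excludedGene = excluded)
}

#' Condition summary statistics on a set of variants
#'
#' COJO-style conditioning from summary statistics and an LD reference:
#' for each target variant t outside the conditioning set C,
#' \deqn{z_{t|C} = (z_t - R_{tC} R_{CC}^{-1} z_C) /
#'       \sqrt{1 - R_{tC} R_{CC}^{-1} R_{Ct}}}
#' `R_CC` gets a ridge term `lambda` on its diagonal before inversion;
#' targets whose residual variance falls below `epsilon` are dropped as
#' collinear with the conditioning set (ids returned in the
#' `"dropped"` attribute).  On the standardized scale the per-variant
#' se is unchanged and beta is recomputed as `z * se`, with p from the
#' two-sided normal.
#'
#' @param locus an [AssocTable-class].
#' @param ld an [LDMatrix-class] whose variants cover the locus in
#'   matching order.
#' @param conditioningSet character ids, a subset of the locus variants.
#' @param lambda ridge regularization added to diag(R_CC); default 1e-4.
#' @param epsilon residual-variance floor below which a target is
#'   dropped; default 0.01.
#' @return A new [AssocTable-class] over the non-conditioned variants.
#' @export
conditionalZ <- function(locus, ld, conditioningSet, lambda = 1e-4,
                         epsilon = 0.01) {
  st <- assocStats(locus)
  if (!length(conditioningSet)) {
    out <- locus
    attr(out, "dropped") <- character()
    return(out)
  }
  if (!all(conditioningSet %in% st$id))
    stop("conditioning set must be a subset of the locus variants")
  ids <- st$id
  ord <- match(ids, variantIds(ld))
  if (anyNA(ord))
    stop("LD matrix does not cover the locus variants")
  r <- corMatrix(ld)[ord, ord, drop = FALSE]
  ci <- which(ids %in% conditioningSet)
  ti <- setdiff(seq_along(ids), ci)
  rcc <- r[ci, ci, drop = FALSE] + diag(lambda, length(ci))
  sol <- tryCatch(solve(rcc), error = function(e)
    stop("numerical error: R_CC singular beyond regularization for ",
         "variants ", paste(ids[ci], collapse = ", ")))
  rtc <- r[ti, ci, drop = FALSE]
  a <- rtc %*% sol                       # R_tC R_CC^-1
  zc <- st$z[ci]
  num <- st$z[ti] - drop(a %*% zc)
  resvar <- 1 - rowSums(a * rtc)
  keep <- resvar >= epsilon
  dropped <- ids[ti][!keep]
  ti <- ti[keep]
  zNew <- num[keep] / sqrt(resvar[keep])
  newStats <- st[ti, , drop = FALSE]
  newStats$z <- zNew
  newStats$beta <- zNew * newStats$se
  newStats$p <- 2 * pnorm(-abs(zNew))
  rownames(newStats) <- NULL
  out <- AssocTable(traitName(locus), newStats, tissue = tissueName(locus),
                    chrom = locus@chrom, start = locus@start,
                    end = locus@end)
  attr(out, "dropped") <- dropped
  out
}
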