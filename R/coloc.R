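#' @importFrom stats pnorm
NULL

.logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf-safe
.logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  d <- b - a
  if (d >= 0) return(-Inf)             # clamp tiny negatives to zero mass
  a + log1p(-exp(d))
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimated effect with variance `V = se^2` and a normal effect
#' prior with variance `W`:
#' \deqn{\log ABF = \tfrac12 \log\frac{V}{V+W}
#'                + \tfrac12 z^2 \frac{W}{V+W}}
#'
#' @param z z-score(s).
#' @param se standard error(s) (> 0).
#' @param priorSd prior standard deviation sqrt(W); default 0.15, the
#'   quantitative-trait convention.
#' @return log ABF, vectorized.
#' @export
wakefieldLABF <- function(z, se, priorSd = 0.15) {
  if (any(se <= 0)) stop("se must be > 0")
  if (priorSd <= 0) stop("priorSd must be > 0")
  v <- se^2
  w <- priorSd^2
  0.5 * log(v / (v + w)) + 0.5 * z^2 * w / (v + w)
}

#' Stepwise single-effect fine-mapping from summary statistics
#'
#' With `L = 1`, per-variant posterior inclusion probabilities are the
#' softmax of Wakefield log-ABFs (flat prior over variants):
#' `PIP_i = exp(labf_i) / sum_j exp(labf_j)`.  With `L > 1` the
#' single-effect computation is repeated L times, residualizing the
#' z-scores after each round by conditioning ([conditionalZ()]) on the
#' accumulated top variants; the combined per-variant PIP is
#' `1 - prod_l (1 - PIP_il)`.  This is a documented stepwise
#' approximation to a sum-of-single-effects model, not the full
#' variational algorithm.
#'
#' @param locus an [AssocTable-class].
#' @param ld an [LDMatrix-class] covering the locus (required for
#'   `L > 1`).
#' @param L assumed number of causal effects (>= 1).
#' @param priorSd Wakefield prior sd.
#' @param credibleLevel optional level for a credible set over the
#'   final-round combined PIPs (default 0.95).
#' @return list with `pip` (named by variant id), `perEffect` (L x n
#'   matrix of per-round single-effect PIPs), `credibleSet` (ids).
#' @export
finemapPIPs <- function(locus, ld = NULL, L = 1, priorSd = 0.15,
                        credibleLevel = 0.95) {
  st <- assocStats(locus)
  n <- nrow(st)
  if (L < 1) stop("L must be >= 1")
  if (L > n) stop("validation error: L exceeds the variant count")
  if (L > 1 && is.null(ld)) stop("ld is required for L > 1")
  ids <- st$id
  perEffect <- matrix(0, nrow = L, ncol = n, dimnames = list(NULL, ids))
  current <- locus
  conditioningSet <- character()
  for (l in seq_len(L)) {
    cst <- assocStats(current)
    labf <- wakefieldLABF(cst$z, cst$se, priorSd)
    lse <- .logsumexp(labf)
    perEffect[l, cst$id] <- exp(labf - lse)
    if (l < L) {
      top <- cst$id[which.max(labf)]
      conditioningSet <- c(conditioningSet, top)
      current <- conditionalZ(locus, ld, conditioningSet)
      if (!nrow(assocStats(current))) break
    }
  }
  pip <- 1 - apply(1 - perEffect, 2, prod)
  cs <- character()
  if (!is.null(credibleLevel)) {
    ord <- order(pip, decreasing = TRUE)
    cum <- cumsum(pip[ord]) / sum(pip)
    cs <- ids[ord][seq_len(which(cum >= credibleLevel)[1])]
  }
  list(pip = setNames(pip, ids), perEffect = perEffect, credibleSet = cs)
}

.alignCheck <- function(a, b) {
  if (!identical(variantIds(a), variantIds(b)))
    stop("alignment error: the two tables must share an identical ",
         "variant list in identical order")
}

#' ABF colocalization posteriors (PP0-PP4)
#'
#' Per-variant Wakefield log-ABFs for the two traits are combined into
#' the five colocalization hypotheses: H0 neither trait associated, H1
#' trait 1 only, H2 trait 2 only, H3 both via two distinct variants, H4
#' both via one shared variant.  Unnormalized weights (log scale) are
#' `0`, `log p1 + lse(l1)`, `log p2 + lse(l2)`,
#' `log p1 p2 + log sum_{i != j} exp(l1_i + l2_j)`, and
#' `log p12 + lse(l1 + l2)`; H3 excludes same-variant pairs exactly, so
#' a single-variant locus has PP3 = 0.
#'
#' @param gwas,eqtl [AssocTable-class] objects over identical variant
#'   lists in identical order (no silent intersection).
#' @param p1,p2 per-variant prior of association with each single trait
#'   (default 1e-4 each).
#' @param p12 per-variant prior of shared association (default 1e-5).
#' @param priorSd1,priorSd2 Wakefield prior sds (default 0.15).
#' @param ppThreshold PP4 hit threshold (default 0.8).
#' @return A [ColocResult-class] (CLPP fields unset; see [clpp()]).
#' @export
colocABF <- function(gwas, eqtl, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     priorSd1 = 0.15, priorSd2 = 0.15,
                     ppThreshold = 0.8) {
  .alignCheck(gwas, eqtl)
  s1 <- assocStats(gwas); s2 <- assocStats(eqtl)
  n <- nrow(s1)
  if (!n) stop("empty locus")
  l1 <- wakefieldLABF(s1$z, s1$se, priorSd1)
  l2 <- wakefieldLABF(s2$z, s2$se, priorSd2)
  lse1 <- .logsumexp(l1)
  lse2 <- .logsumexp(l2)
  lse12 <- .logsumexp(l1 + l2)
  lh0 <- 0
  lh1 <- log(p1) + lse1
  lh2 <- log(p2) + lse2
  # sum over i != j of exp(l1_i + l2_j) = exp(lse1 + lse2) - exp(lse12)
  lh3 <- log(p1) + log(p2) + .logdiffexp(lse1 + lse2, lse12)
  lh4 <- log(p12) + lse12
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - .logsumexp(lh))
  pp <- pp / sum(pp)
  new("ColocResult", pp = setNames(pp, paste0("pp", 0:4)),
      nVariants = as.integer(n), clpp = numeric(),
      clppMax = NA_real_,
      hits = c(abf = unname(pp[5] >= ppThreshold)))
}

#' eCAVIAR-style colocalization posterior product (CLPP)
#'
#' Per variant, `CLPP_i = PIP_i(gwas) * PIP_i(eqtl)`; the locus summary
#' is the maximum over variants.
#'
#' @param gwasPips,eqtlPips results of [finemapPIPs()] over identical
#'   variant lists.
#' @param threshold hit threshold on `max CLPP` (default 0.01).
#' @return list with `clpp` (named per-variant products), `clppMax`,
#'   `hit`.
#' @export
clpp <- function(gwasPips, eqtlPips, threshold = 0.01) {
  if (!identical(names(gwasPips$pip), names(eqtlPips$pip)))
    stop("alignment error: PIP vectors must share an identical ",
         "variant list in identical order")
  prod <- gwasPips$pip * eqtlPips$pip
  list(clpp = prod, clppMax = max(prod), hit = max(prod) >= threshold)
}

#' Run both colocalization statistics on one locus pair
#'
#' @param gwas,eqtl aligned [AssocTable-class] objects.
#' @param ld [LDMatrix-class] for the locus.
#' @param p1,p2,p12,priorSd1,priorSd2,ppThreshold see [colocABF()].
#' @param clppThreshold see [clpp()].
#' @param L fine-mapper effects inside CLPP (default 1).
#' @return A [ColocResult-class] with both methods' fields populated.
#' @export
colocBoth <- function(gwas, eqtl, ld, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      priorSd1 = 0.15, priorSd2 = 0.15,
                      ppThreshold = 0.8, clppThreshold = 0.01, L = 1) {
  abf <- colocABF(gwas, eqtl, p1, p2, p12, priorSd1, priorSd2,
                  ppThreshold)
  g <- finemapPIPs(gwas, ld, L = L, priorSd = priorSd1)
  e <- finemapPIPs(eqtl, ld, L = L, priorSd = priorSd2)
  cl <- clpp(g, e, clppThreshold)
  new("ColocResult", pp = colocPP(abf), nVariants = abf@nVariants,
      clpp = cl$clpp, clppMax = cl$clppMax,
      hits = c(abf = unname(colocHits(abf)["abf"]), clpp = cl$hit))
}

#' High-confidence fine-mapped variants near a TSS
#'
#' Selects variants with PIP above the confidence threshold whose
#' position lies within `window` bp of the gene TSS.
#'
#' @param locus [AssocTable-class] the PIPs were computed on.
#' @param pips [finemapPIPs()] result.
#' @param tss gene TSS (1-based).
#' @param pipThreshold PIP cut (default 0.7).
#' @param window distance cut in bp (default 1e5).
#' @return data.frame `id, chrom, pos, pip`.
#' @export
highPipVariants <- function(locus, pips, tss, pipThreshold = 0.7,
                            window = 1e5) {
  st <- assocStats(locus)
  pip <- pips$pip[st$id]
  keep <- pip > pipThreshold & abs(st$pos - tss) <= window
  data.frame(id = st$id[keep], chrom = st$chrom[keep],
             pos = st$pos[keep], pip = unname(pip[keep]),
             stringsAsFactors = FALSE)
}
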