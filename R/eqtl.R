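#' Benjamini-Hochberg with an inflated test count
#'
#' Standard BH step-up computed as if the number of tests were `c * m`
#' (m = length of the observed p-value list):
#' \deqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} \cdot c m / j)}
#' with ranks taken over the observed list.  The correction factor `c`
#' accounts for tests performed but not reported (variants tested per
#' gene but absent from the released tables); `c = 1` reduces exactly to
#' textbook BH.
#'
#' @param p numeric p-values in (0, 1].
#' @param correctionFactor c >= 1.
#' @return adjusted q-values in the input order.
#' @export
adjustedBH <- function(p, correctionFactor = 20) {
  if (correctionFactor < 1)
    stop("validation error: correctionFactor must be >= 1")
  if (!length(p)) return(numeric())
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  ranks <- m:1                     # ranks of the sorted-descending list
  q <- pmin(1, p[ord] * correctionFactor * m / ranks)
  q <- cummin(q)                   # enforce step-up monotonicity
  q[order(ord)]
}

#' Call eQTLs per gene-tissue pair under inflated-count BH
#'
#' The unit entering FDR control is the minimum variant p-value of each
#' gene-tissue eQTL table; all pairs enter one joint [adjustedBH()].  A
#' gene is flagged as having an eQTL if it is significant in at least
#' one relevant tissue.
#'
#' @param eqtlTables list of [AssocTable-class] eQTL tables (one per
#'   gene-tissue pair); names are used as gene labels when the tables
#'   carry none.
#' @param genes character gene symbol per table.
#' @param correctionFactor BH inflation factor c (default 20).
#' @param alpha FDR level (default 0.05).
#' @return list with `calls` (data.frame `gene, tissue, min_p, q,
#'   significant`) and `geneFlags` (named logical per gene: significant
#'   in >= 1 tissue).
#' @export
callEqtls <- function(eqtlTables, genes = NULL, correctionFactor = 20,
                      alpha = 0.05) {
  if (!length(eqtlTables))
    return(list(calls = data.frame(gene = character(),
                                   tissue = character(),
                                   min_p = numeric(), q = numeric(),
                                   significant = logical()),
                geneFlags = logical()))
  if (is.null(genes)) genes <- names(eqtlTables)
  minP <- vapply(eqtlTables, function(tb) {
    st <- assocStats(tb)
    if (!nrow(st)) stop("empty eQTL table")
    min(st$p)
  }, numeric(1))
  tissue <- vapply(eqtlTables, tissueName, character(1))
  q <- adjustedBH(minP, correctionFactor)
  calls <- data.frame(gene = genes, tissue = tissue, min_p = minP,
                      q = q, significant = q < alpha,
                      stringsAsFactors = FALSE, row.names = NULL)
  geneFlags <- tapply(calls$significant, calls$gene, any)
  list(calls = calls, geneFlags = geneFlags[unique(genes)])
}
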