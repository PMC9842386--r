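#' @import methods
#' @importFrom stats pnorm
NULL

.REQUIRED_STAT_COLS <- c("id", "chrom", "pos", "ref", "alt", "beta", "se",
                         "p", "n")

#' AssocTable: per-variant association statistics at one locus
#'
#' Container for GWAS or eQTL summary statistics for a single trait (and,
#' for eQTLs, tissue) over one contiguous locus.  The `stats` slot is a
#' data.frame with one row per variant and columns `id`, `chrom`, `pos`
#' (1-based), `ref`, `alt`, `beta`, `se`, `z`, `p`, `n` and optionally
#' `eaf`.  Validity enforces se > 0, z = beta/se, two-sided normal
#' consistency of p with z, variant ids unique, and all positions on the
#' locus chromosome within its span.
#'
#' @slot trait character(1) trait label.
#' @slot tissue character(1) tissue label, `""` for GWAS.
#' @slot chrom character(1) locus chromosome.
#' @slot start,end numeric(1) locus span (1-based, inclusive of start,
#'   exclusive of end, so a variant at `pos` belongs iff
#'   `start <= pos < end`).
#' @slot stats data.frame of per-variant statistics (see above).
#' @exportClass AssocTable
setClass("AssocTable",
  representation(trait = "character", tissue = "character",
                 chrom = "character", start = "numeric", end = "numeric",
                 stats = "data.frame"))

.validAssocTable <- function(object) {
  msg <- character()
  st <- object@stats
  miss <- setdiff(c(.REQUIRED_STAT_COLS, "z"), names(st))
  if (length(miss))
    return(paste("missing stats columns:", paste(miss, collapse = ", ")))
  if (nrow(st)) {
    if (any(st$se <= 0)) msg <- c(msg, "all se must be > 0")
    if (any(st$pos < 1)) msg <- c(msg, "positions must be >= 1")
    if (any(st$ref == st$alt)) msg <- c(msg, "ref and alt alleles must differ")
    if (anyDuplicated(st$id)) msg <- c(msg, "variant ids must be unique")
    if (any(abs(st$z - st$beta / st$se) >= 1e-6))
      msg <- c(msg, "z must equal beta/se within 1e-6")
    pz <- 2 * pnorm(-abs(st$z))
    bad <- abs(st$p - pz) > 1e-6 * pmax(pz, .Machine$double.xmin)
    if (any(bad))
      msg <- c(msg, "p inconsistent with z under the normal approximation")
    if (any(st$p <= 0 | st$p > 1)) msg <- c(msg, "p must lie in (0, 1]")
    if (any(st$chrom != object@chrom))
      msg <- c(msg, "all variants must be on the locus chromosome")
    if (any(st$pos < object@start | st$pos >= object@end))
      msg <- c(msg, "all variant positions must lie within the locus span")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}
setValidity("AssocTable", .validAssocTable)

#' Construct an AssocTable
#'
#' @param trait trait label.
#' @param stats per-variant data.frame; `z` is recomputed from
#'   `beta`/`se` and `p` (if absent) from `z`.
#' @param tissue tissue label (default `""` = not tissue-specific).
#' @param chrom,start,end locus span; derived from `stats` when omitted.
#' @return An [AssocTable-class] object.
#' @export
AssocTable <- function(trait, stats, tissue = "", chrom = NULL,
                       start = NULL, end = NULL) {
  stats <- as.data.frame(stats)
  miss <- setdiff(.REQUIRED_STAT_COLS, names(stats))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (any(stats$se <= 0)) stop("all se must be > 0")
  stats$z <- stats$beta / stats$se
  if (is.null(stats$p) || all(is.na(stats$p)))
    stats$p <- 2 * pnorm(-abs(stats$z))
  if (is.null(chrom)) chrom <- if (nrow(stats)) stats$chrom[1] else "chr0"
  if (is.null(start)) start <- if (nrow(stats)) min(stats$pos) else 1
  if (is.null(end))   end   <- if (nrow(stats)) max(stats$pos) + 1 else 2
  new("AssocTable", trait = trait, tissue = tissue, chrom = chrom,
      start = as.numeric(start), end = as.numeric(end), stats = stats)
}

#' LDMatrix: variant-indexed correlation matrix
#'
#' Square matrix of pairwise LD correlations, row/column order matching
#' the `variants` id vector.  Validity enforces symmetry, unit diagonal,
#' entries in [-1, 1], and positive semi-definiteness within 1e-8.
#'
#' @slot variants character vector of variant ids (row/col order).
#' @slot r numeric correlation matrix.
#' @exportClass LDMatrix
setClass("LDMatrix",
  representation(variants = "character", r = "matrix"))

.validLDMatrix <- function(object) {
  r <- object@r
  msg <- character()
  if (nrow(r) != ncol(r)) return("r must be square")
  if (length(object@variants) != nrow(r))
    return("variants length must match r dimension")
  if (nrow(r)) {
    if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "r must have unit diagonal")
    if (any(r < -1 - 1e-8 | r > 1 + 1e-8))
      msg <- c(msg, "entries must lie in [-1, 1]")
    ev <- eigen((r + t(r)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      msg <- c(msg, "r must be positive semi-definite within 1e-8")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}
setValidity("LDMatrix", .validLDMatrix)

#' Construct an LDMatrix
#'
#' @param variants character vector of variant ids.
#' @param r square correlation matrix in the same order.
#' @return An [LDMatrix-class] object.
#' @export
LDMatrix <- function(variants, r) {
  r <- as.matrix(r)
  dimnames(r) <- list(variants, variants)
  new("LDMatrix", variants = as.character(variants), r = r)
}

#' ColocResult: colocalization posteriors for one gene-tissue locus
#'
#' Holds the five ABF hypothesis posteriors (H0 none, H1 trait-1 only,
#' H2 trait-2 only, H3 two distinct causal variants, H4 one shared causal
#' variant), the per-variant CLPP and its maximum, and hit flags at the
#' configured thresholds.
#'
#' @slot pp named numeric(5), posteriors `pp0`..`pp4` summing to 1.
#' @slot nVariants integer(1).
#' @slot clpp numeric per-variant PIP products (may be empty if CLPP was
#'   not run).
#' @slot clppMax numeric(1), `max(clpp)` or `NA`.
#' @slot hits named logical, e.g. `abf`, `clpp`.
#' @exportClass ColocResult
setClass("ColocResult",
  representation(pp = "numeric", nVariants = "integer", clpp = "numeric",
                 clppMax = "numeric", hits = "logical"))

.validColocResult <- function(object) {
  pp <- object@pp
  msg <- character()
  if (length(pp) != 5 || !identical(names(pp), paste0("pp", 0:4)))
    return("pp must be named pp0..pp4")
  if (any(pp < -1e-12 | pp > 1 + 1e-12)) msg <- c(msg, "pp must lie in [0,1]")
  if (abs(sum(pp) - 1) > 1e-9) msg <- c(msg, "pp must sum to 1 within 1e-9")
  if (!is.na(object@clppMax) &&
      (object@clppMax < 0 || object@clppMax > 1))
    msg <- c(msg, "clppMax must lie in [0,1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}
setValidity("ColocResult", .validColocResult)

setMethod("show", "AssocTable", function(object) {
  cat(sprintf("AssocTable: trait=%s%s, locus %s:%g-%g, %d variants\n",
              object@trait,
              if (nzchar(object@tissue)) paste0(" tissue=", object@tissue)
              else "",
              object@chrom, object@start, object@end, nrow(object@stats)))
  if (nrow(object@stats)) {
    i <- which.min(object@stats$p)
    cat(sprintf("  top variant: %s (z=%.2f, p=%.3g)\n",
                object@stats$id[i], object@stats$z[i], object@stats$p[i]))
  }
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d variants\n", length(object@variants)))
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf(
    "ColocResult (%d variants): pp0=%.3f pp1=%.3f pp2=%.3f pp3=%.3f pp4=%.3f",
    object@nVariants, object@pp[1], object@pp[2], object@pp[3],
    object@pp[4], object@pp[5]))
  if (!is.na(object@clppMax)) cat(sprintf("  clppMax=%.4g", object@clppMax))
  cat("\n")
})

# --- accessors ---------------------------------------------------------

#' @rdname AssocTable
#' @param x an AssocTable or LDMatrix.
#' @export
assocStats <- function(x) x@stats

#' @rdname AssocTable
#' @export
traitName <- function(x) x@trait

#' @rdname AssocTable
#' @export
tissueName <- function(x) x@tissue

#' @rdname AssocTable
#' @export
variantIds <- function(x) {
  if (is(x, "LDMatrix")) x@variants else x@stats$id
}

#' @rdname LDMatrix
#' @param x an LDMatrix.
#' @export
corMatrix <- function(x) x@r

#' Subset an AssocTable to a set of variant ids, preserving order
#'
#' @param x an AssocTable.
#' @param ids variant ids to keep, in the desired order.
#' @return a new AssocTable over exactly `ids`.
#' @export
subsetVariants <- function(x, ids) {
  st <- assocStats(x)
  idx <- match(ids, st$id)
  if (anyNA(idx)) stop("ids absent from the table: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  st <- st[idx, , drop = FALSE]
  rownames(st) <- NULL
  AssocTable(traitName(x), st, tissue = tissueName(x), chrom = x@chrom,
             start = x@start, end = x@end)
}

#' @rdname ColocResult
#' @param x a ColocResult.
#' @export
colocPP <- function(x) x@pp

#' @rdname ColocResult
#' @export
clppMax <- function(x) x@clppMax

#' @rdname ColocResult
#' @export
colocHits <- function(x) x@hits
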