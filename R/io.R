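#' @importFrom GenomicRanges GRanges start end seqnames mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
#' @importFrom utils read.table write.table
NULL

# The single place where BED (0-based, half-open) meets GRanges (1-based,
# closed): BED [start, end) becomes GRanges [start+1, end].  Point
# positions (TSS, variant pos) are 1-based throughout, so a point p lies
# in a BED interval iff start < p <= end, i.e. native GRanges overlap
# after this conversion.
.bed0ToGRanges <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges(start + 1L, end), ...)
}

.grangesToBed0 <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr))
}

#' Test 1-based point positions against genomic intervals
#'
#' The package-wide convention: interval tracks are read from BED
#' (0-based half-open) and held as GRanges (1-based closed); a 1-based
#' point position p lies in a BED interval [start, end) iff
#' start < p <= end, which is exactly GRanges containment after
#' conversion.
#'
#' @param chrom,pos character/numeric vectors of point coordinates
#'   (1-based).
#' @param gr a GRanges of intervals.
#' @return logical vector: does each point fall in any interval?
#' @export
pointsInRanges <- function(chrom, pos, gr) {
  if (length(gr) == 0L) return(rep(FALSE, length(pos)))
  pts <- GenomicRanges::GRanges(chrom, IRanges(pos, pos))
  # points on chromosomes absent from gr are simply non-overlapping
  suppressWarnings(IRanges::overlapsAny(pts, gr, ignore.strand = TRUE))
}

.readTsv <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, ": missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

# --- narrowPeak --------------------------------------------------------

VALID_MARKS <- c("H3K27ac", "H3K4me1", "H3K4me3", "DHS")

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' @param path file path.
#' @param mark one of `"H3K27ac"`, `"H3K4me1"`, `"H3K4me3"`, `"DHS"`.
#' @return A GRanges with metadata columns `name`, `score`, `strength`
#'   (signalValue), `pval`, `qval`, `summit` (offset from the BED start,
#'   -1 if absent) and `mark`.  Coordinates are converted from BED
#'   0-based half-open to GRanges 1-based closed; [writeNarrowPeak()]
#'   inverts the conversion so round-trips are exact.
#' @export
readNarrowPeak <- function(path, mark) {
  mark <- match.arg(mark, VALID_MARKS)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(emptyPeaks(mark))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10))
    stop("narrowPeak parse error at line ", which(nf < 10)[1],
         ": expected >= 10 tab-separated columns, got ", nf[nf < 10][1])
  m <- do.call(rbind, fields)
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  if (any(is.na(start) | is.na(end)))
    stop("narrowPeak parse error at line ",
         which(is.na(start) | is.na(end))[1], ": non-numeric coordinates")
  if (any(end <= start))
    stop("narrowPeak validation error at line ", which(end <= start)[1],
         ": end must exceed start")
  summit <- as.numeric(m[, 10])
  bad <- summit >= 0 & summit >= (end - start)
  if (any(bad))
    stop("narrowPeak validation error at line ", which(bad)[1],
         ": summit offset must be < peak width")
  gr <- .bed0ToGRanges(m[, 1], start, end)
  mcols(gr) <- DataFrame(name = m[, 4], score = as.numeric(m[, 5]),
                         strand_ = m[, 6],
                         strength = as.numeric(m[, 7]),
                         pval = as.numeric(m[, 8]),
                         qval = as.numeric(m[, 9]),
                         summit = summit, mark = mark)
  if (any(gr$strength < 0))
    stop("narrowPeak validation error: signalValue must be >= 0")
  gr
}

#' @rdname readNarrowPeak
#' @param gr GRanges as returned by readNarrowPeak.
#' @export
writeNarrowPeak <- function(gr, path) {
  bed <- .grangesToBed0(gr)
  df <- data.frame(bed$chrom, bed$start, bed$end,
                   if (is.null(gr$name)) "." else gr$name,
                   if (is.null(gr$score)) 0 else gr$score,
                   if (is.null(gr$strand_)) "." else gr$strand_,
                   gr$strength,
                   if (is.null(gr$pval)) -1 else gr$pval,
                   if (is.null(gr$qval)) -1 else gr$qval,
                   if (is.null(gr$summit)) -1 else gr$summit)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname readNarrowPeak
#' @export
emptyPeaks <- function(mark = "H3K27ac") {
  gr <- GenomicRanges::GRanges()
  mcols(gr) <- DataFrame(name = character(), score = numeric(),
                         strand_ = character(), strength = numeric(),
                         pval = numeric(), qval = numeric(),
                         summit = numeric(), mark = character())
  gr
}

# --- summary statistics ------------------------------------------------

.SUMSTAT_COLS <- c("variant", "chrom", "pos", "ref", "alt", "beta", "se",
                   "p", "n")

#' Read/write tab-separated summary statistics
#'
#' The TSV schema is `variant, chrom, pos, ref, alt, beta, se, p, n`
#' (optionally `eaf`); `z` is always recomputed as `beta/se` and the
#' AssocTable validity checks are enforced.
#'
#' @param path file path.
#' @param trait,tissue labels for the resulting table; read from
#'   optional `trait`/`tissue` columns when present.
#' @return An [AssocTable-class].
#' @export
readSumstats <- function(path, trait = NULL, tissue = NULL) {
  df <- .readTsv(path, .SUMSTAT_COLS, "sumstats")
  if (any(df$se <= 0))
    stop("sumstats validation error: se must be > 0 (row ",
         which(df$se <= 0)[1], ")")
  if (is.null(trait))
    trait <- if ("trait" %in% names(df) && nrow(df)) df$trait[1] else "trait"
  if (is.null(tissue))
    tissue <- if ("tissue" %in% names(df) && nrow(df)) df$tissue[1] else ""
  stats <- data.frame(id = as.character(df$variant), chrom = df$chrom,
                      pos = df$pos, ref = df$ref, alt = df$alt,
                      beta = df$beta, se = df$se, p = df$p, n = df$n,
                      stringsAsFactors = FALSE)
  if ("eaf" %in% names(df)) stats$eaf <- df$eaf
  stats$z <- stats$beta / stats$se
  stats$p <- 2 * pnorm(-abs(stats$z))
  AssocTable(trait, stats, tissue = tissue)
}

#' @rdname readSumstats
#' @param x an AssocTable.
#' @export
writeSumstats <- function(x, path) {
  st <- assocStats(x)
  out <- data.frame(variant = st$id, chrom = st$chrom, pos = st$pos,
                    ref = st$ref, alt = st$alt,
                    beta = sprintf("%.17g", st$beta),
                    se = sprintf("%.17g", st$se),
                    p = sprintf("%.17g", st$p), n = st$n,
                    trait = traitName(x), tissue = tissueName(x))
  if (!is.null(st$eaf)) out$eaf <- sprintf("%.17g", st$eaf)
  .writeTsv(out, path)
}

# --- gene tables -------------------------------------------------------

VALID_GENE_SOURCES <- c("mendelian", "backman", "both")

#' Read/write the candidate-gene table
#'
#' TSV schema: `symbol, chrom, tss, strand, trait, source`; one row per
#' (symbol, trait) pair; `source` one of `mendelian`, `backman`, `both`;
#' `tss` 1-based.
#'
#' @param path file path.
#' @return data.frame of gene records.
#' @export
readGeneTable <- function(path) {
  df <- .readTsv(path, c("symbol", "chrom", "tss", "strand", "trait",
                         "source"), "gene table")
  if (nrow(df)) {
    bad <- !df$source %in% VALID_GENE_SOURCES
    if (any(bad))
      stop("gene table schema error: unknown source label '",
           df$source[bad][1], "'")
    if (anyDuplicated(df[, c("symbol", "trait")]))
      stop("gene table validation error: duplicate (symbol, trait) pair")
    if (any(df$tss < 1))
      stop("gene table validation error: tss must be >= 1")
    if (any(!df$strand %in% c("+", "-")))
      stop("gene table schema error: strand must be '+' or '-'")
  }
  df
}

#' @rdname readGeneTable
#' @param df gene record data.frame.
#' @export
writeGeneTable <- function(df, path) .writeTsv(df, path)

# --- pext tables -------------------------------------------------------

#' Read/write pext-style annotation tables
#'
#' TSV schema: `variant, gene, tissue, expr_frac, isoform_frac`, both
#' fractions in [0, 1].  `expr_frac` is the gene's expression in the
#' tissue divided by its maximum across tissues; `isoform_frac` is the
#' fraction of splice isoforms whose coding sequence contains the
#' variant in that tissue.
#'
#' @param path file path.
#' @return data.frame of pext records.
#' @export
readPextTable <- function(path) {
  df <- .readTsv(path, c("variant", "gene", "tissue", "expr_frac",
                         "isoform_frac"), "pext table")
  if (nrow(df) && any(df$expr_frac < 0 | df$expr_frac > 1 |
                      df$isoform_frac < 0 | df$isoform_frac > 1))
    stop("pext validation error: fractions must lie in [0, 1]")
  df
}

#' @rdname readPextTable
#' @param df pext data.frame.
#' @export
writePextTable <- function(df, path) .writeTsv(df, path)

# --- ChromHMM / plain BED ----------------------------------------------

#' Read a 4-column ChromHMM segmentation BED
#'
#' @param path file path to a `chrom start end state` BED.
#' @return GRanges sorted by (chrom, start) with metadata column
#'   `state` (labels preserved verbatim).  Overlapping segments on one
#'   chromosome are tolerated with a warning.
#' @export
readChromHMM <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    mcols(gr) <- DataFrame(state = character())
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("ChromHMM parse error at line ", which(nf < 4)[1],
         ": expected 4 tab-separated columns")
  m <- do.call(rbind, fields)
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  if (any(start < 0) || any(end <= start))
    stop("ChromHMM validation error: need 0 <= start < end")
  gr <- .bed0ToGRanges(m[, 1], start, end, state = m[, 4])
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  if (length(gr) > 1) {
    ov <- IRanges::findOverlaps(gr, drop.self = TRUE,
                                drop.redundant = TRUE,
                                ignore.strand = TRUE)
    if (length(ov))
      warning("ChromHMM: overlapping segments kept (dialect tolerance)")
  }
  gr
}

#' @rdname readChromHMM
#' @param gr GRanges with a `state` column.
#' @export
writeChromHMM <- function(gr, path) {
  bed <- .grangesToBed0(gr)
  write.table(data.frame(bed, gr$state), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a minimal 3-column BED of intervals (e.g. a blacklist)
#'
#' @param path file path.
#' @return GRanges.
#' @export
readBedIntervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("BED parse error at line ", which(lengths(fields) < 3)[1])
  m <- do.call(rbind, lapply(fields, `[`, 1:3))
  .bed0ToGRanges(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]))
}

#' @rdname readBedIntervals
#' @param gr GRanges.
#' @export
writeBedIntervals <- function(gr, path) {
  write.table(.grangesToBed0(gr), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

# --- LD matrices -------------------------------------------------------

#' Read/write an LD matrix with its sidecar variant index
#'
#' The matrix is a whitespace-delimited square text matrix; the sidecar
#' file holds one variant id per line in row/column order.
#'
#' @param path matrix file path.
#' @param indexPath sidecar variant-id file path.
#' @return An [LDMatrix-class].
#' @export
readLDMatrix <- function(path, indexPath) {
  variants <- readLines(indexPath)
  variants <- variants[nzchar(variants)]
  r <- as.matrix(read.table(path, header = FALSE))
  if (nrow(r) != length(variants))
    stop("LD matrix dimension (", nrow(r),
         ") does not match variant index length (", length(variants), ")")
  LDMatrix(variants, r)
}

#' @rdname readLDMatrix
#' @param x an LDMatrix.
#' @export
writeLDMatrix <- function(x, path, indexPath) {
  write.table(format(corMatrix(x), digits = 17, trim = TRUE,
                     scientific = FALSE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  writeLines(variantIds(x), indexPath)
  invisible(path)
}

# --- bundled gene list --------------------------------------------------

#' The bundled Mendelian gene-trait list
#'
#' Returns the curated table of genes whose large-effect coding variants
#' cause a Mendelian (or, for breast cancer, somatic-driver) form of one
#' of the seven study traits, as shipped in `inst/extdata`.  One row per
#' gene-trait pair; a gene may appear under several traits.
#'
#' @return data.frame with columns `symbol` and `trait`.
#' @export
mendelianGenePairs <- function() {
  path <- system.file("extdata", "mendelian_gene_trait_pairs.tsv",
                      package = "regaudit", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
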