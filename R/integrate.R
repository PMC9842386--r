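#' @importFrom utils modifyList
NULL

#' Per-gene verdicts across all pipeline stages
#'
#' Collapses tissue-level results to gene level ("any relevant tissue")
#' and assembles, for each gene-trait pair, the proximity, eQTL,
#' colocalization, fine-mapping and chromatin flags that make up the
#' integrated result surface.  Logical invariants (a coloc or CLPP hit
#' implies an eQTL and a nearby locus; a top-ABD hit implies a high-PIP
#' variant) are verified and violations raise an error rather than being
#' silently repaired.
#'
#' @param genes gene-record data.frame.
#' @param near1mb,near100kb [genesNearLoci()] outputs at 1 Mb and 100 kb.
#' @param eqtlFlags named logical per gene (from [callEqtls()]).
#' @param colocResults named list (per gene) of [ColocResult-class].
#' @param highPip named list (per gene) of high-PIP variant data.frames.
#' @param annotations named list (per gene) of [annotateVariants()]
#'   outputs.
#' @param topAbd named list (per gene) of [topAbdImplication()] outputs.
#' @return data.frame of verdicts, one row per gene-trait pair, with a
#'   `missing_stages` column naming any stage that lacked output for the
#'   gene.
#' @export
geneVerdicts <- function(genes, near1mb, near100kb, eqtlFlags,
                         colocResults, highPip, annotations, topAbd) {
  n <- nrow(genes)
  getFlag <- function(lst, g, f) {
    x <- lst[[g]]
    if (is.null(x)) NA else f(x)
  }
  rows <- lapply(seq_len(n), function(i) {
    g <- genes$symbol[i]
    near1 <- near1mb$near[near1mb$symbol == g &
                          near1mb$trait == genes$trait[i]][1]
    near0 <- near100kb$near[near100kb$symbol == g &
                            near100kb$trait == genes$trait[i]][1]
    hasEqtl <- if (g %in% names(eqtlFlags)) unname(eqtlFlags[g]) else NA
    # colocalization is only attempted for genes near a locus with an
    # eQTL; absent results are FALSE when upstream gates failed, NA when
    # genuinely missing
    cr <- colocResults[[g]]
    abfHit <- clppHit <- FALSE
    if (!is.null(cr)) {
      h <- colocHits(cr)
      abfHit <- isTRUE(unname(h["abf"]))
      clppHit <- isTRUE(unname(h["clpp"]))
    }
    hp <- highPip[[g]]
    hasHighPip <- !is.null(hp) && nrow(hp) > 0
    ann <- annotations[[g]]
    inReg <- !is.null(ann) && nrow(ann) > 0 && any(ann$in_any_regulatory)
    ta <- topAbd[[g]]
    abdHit <- !is.null(ta) && isTRUE(ta$implicated)
    missing <- c(
      if (is.null(cr)) "coloc",
      if (is.null(hp)) "finemap",
      if (is.null(ann)) "annotation",
      if (is.null(ta)) "abd")
    data.frame(gene = g, trait = genes$trait[i],
               source = genes$source[i],
               near_gwas_1mb = near1, near_gwas_100kb = near0,
               has_eqtl = hasEqtl,
               coloc_abf_hit = abfHit, clpp_hit = clppHit,
               has_highpip_variant = hasHighPip,
               variant_in_regulatory = inReg,
               top_abd_hit = abdHit,
               missing_stages = paste(missing, collapse = ","),
               stringsAsFactors = FALSE)
  })
  v <- do.call(rbind, rows)
  bad <- (v$coloc_abf_hit | v$clpp_hit) &
    (!isTRUE_vec(v$has_eqtl) | !isTRUE_vec(v$near_gwas_1mb))
  if (any(bad, na.rm = TRUE))
    stop("verdict invariant violated: coloc/clpp hit without eQTL or ",
         "nearby locus for ", paste(v$gene[bad], collapse = ", "))
  bad2 <- v$top_abd_hit & !v$has_highpip_variant
  if (any(bad2))
    stop("verdict invariant violated: top-ABD hit without a high-PIP ",
         "variant for ", paste(v$gene[bad2], collapse = ", "))
  v
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Summarize gene verdicts
#'
#' Deterministic tabulation of every flag's count and fraction over the
#' gene-trait pairs, with explicit denominators, plus the key
#' cross-tabulations (eQTL among near-GWAS genes, any-coloc among
#' near-GWAS genes).
#'
#' @param verdicts [geneVerdicts()] data.frame.
#' @return data.frame `quantity, count, denominator, fraction`.
#' @export
summarizeVerdicts <- function(verdicts) {
  n <- nrow(verdicts)
  cnt <- function(x) sum(x, na.rm = TRUE)
  row <- function(quantity, count, denom)
    data.frame(quantity = quantity, count = count, denominator = denom,
               fraction = if (denom > 0) count / denom else NA_real_,
               stringsAsFactors = FALSE)
  near1 <- cnt(verdicts$near_gwas_1mb)
  anyColoc <- isTRUE_vec(verdicts$coloc_abf_hit) |
    isTRUE_vec(verdicts$clpp_hit)
  rbind(
    row("gene_trait_pairs", n, n),
    row("near_gwas_1mb", near1, n),
    row("near_gwas_100kb", cnt(verdicts$near_gwas_100kb), n),
    row("has_eqtl", cnt(verdicts$has_eqtl), n),
    row("eqtl_among_near", cnt(verdicts$has_eqtl &
                               isTRUE_vec(verdicts$near_gwas_1mb)), near1),
    row("coloc_abf_hit", cnt(verdicts$coloc_abf_hit), n),
    row("clpp_hit", cnt(verdicts$clpp_hit), n),
    row("any_coloc_hit", cnt(anyColoc), n),
    row("any_coloc_among_near",
        cnt(anyColoc & isTRUE_vec(verdicts$near_gwas_1mb)), near1),
    row("has_highpip_variant", cnt(verdicts$has_highpip_variant), n),
    row("variant_in_regulatory", cnt(verdicts$variant_in_regulatory), n),
    row("top_abd_hit", cnt(verdicts$top_abd_hit), n))
}

.defaultPipelineConfig <- function() {
  list(seed = 1,
       study = list(),
       pThreshold = 5e-8, clumpRadius = 1e6,
       windowNear = 1e6, windowClose = 1e5,
       eqtlFactor = 20, eqtlAlpha = 0.05,
       priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, priorSd = 0.15),
       ppThreshold = 0.8, clppThreshold = 0.01,
       finemapL = 3, pipThreshold = 0.7, pipWindow = 1e5,
       nResamples = 1000,
       tissueMap = NULL)
}

#' Run the full audit pipeline on a synthetic study
#'
#' Stages, in order: simulate the study; select coding variants from the
#' pext table and condition the GWAS on them; call loci and run the
#' proximity enrichment; call eQTLs under inflated-count BH; fine-map
#' and colocalize each gene's locus pair (ABF posteriors and CLPP);
#' build chromatin features, ABD scores and variant annotations; and
#' assemble per-gene verdicts with summary counts.  Every stage's table
#' is written to `outDir` as TSV alongside a `manifest.json`-style run
#' manifest (config, seed, package version).  Any stage failure aborts
#' with the stage name and cause.
#'
#' @param config either a list or a path to a YAML file; entries
#'   override [.defaultPipelineConfig()].  The `tissueMap` entry, when
#'   given, must name at least one tissue per trait present in the
#'   study; validation happens before any compute.
#' @param outDir output directory.
#' @return list with `verdicts`, `summary`, `enrichment`, `eqtl`,
#'   `coloc` tables and the `study`, invisibly also written to `outDir`.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("regaudit_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(.defaultPipelineConfig(), config)
  stage <- "config validation"
  run <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  study <- run("simulate", simulateStudy(cfg$study, seed = cfg$seed))
  traits <- unique(study$genes$trait)
  if (!is.null(cfg$tissueMap)) {
    miss <- setdiff(traits, names(cfg$tissueMap))
    if (length(miss))
      stop("config validation error: no tissue configured for trait(s) ",
           paste(miss, collapse = ", "))
  }
  genes <- study$genes
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  # conditioning: remove commonly coding variants from each gene's GWAS
  conditioned <- run("condition", lapply(names(study$loci), function(g) {
    lp <- study$loci[[g]]
    sel <- selectCodingVariants(study$pext, g, tissueName(lp$eqtl))
    if (sel$excludedGene || !length(sel$selected)) return(lp$gwas)
    conditionalZ(lp$gwas, lp$ld, sel$selected)
  }))
  names(conditioned) <- names(study$loci)

  # loci + enrichment
  lociList <- run("loci", lapply(conditioned, callGwasLoci,
                                 pThreshold = cfg$pThreshold,
                                 clumpRadius = cfg$clumpRadius))
  loci <- do.call(rbind, c(lociList, list(make.row.names = FALSE)))
  near1 <- genesNearLoci(genes, loci, cfg$windowNear)
  near0 <- genesNearLoci(genes, loci, cfg$windowClose)

  # eQTL FDR
  eqtlTables <- lapply(study$loci, function(lp) lp$eqtl)
  eq <- run("eqtl-fdr", callEqtls(eqtlTables, genes = names(eqtlTables),
                                  correctionFactor = cfg$eqtlFactor,
                                  alpha = cfg$eqtlAlpha))

  # colocalization + fine-mapping per gene
  colocResults <- list(); highPip <- list()
  pri <- cfg$priors
  for (g in names(study$loci)) {
    lp <- study$loci[[g]]
    # colocalization is only attempted where the audit can interpret it:
    # a gene near a called locus (1 Mb) with an eQTL in a relevant
    # tissue; other genes keep FALSE coloc flags with the stage marked
    # as not run
    i <- which(near1$symbol == g)[1]
    gated <- isTRUE(near1$near[i]) && isTRUE(unname(eq$geneFlags[g]))
    if (gated) {
      # colocalize the conditioned GWAS against the eQTL restricted to
      # the surviving variants; fine-mapping uses unconditional stats
      gwasC <- conditioned[[g]]
      eqtlC <- subsetVariants(lp$eqtl, variantIds(gwasC))
      colocResults[[g]] <- run("coloc",
        colocBoth(gwasC, eqtlC, lp$ld, p1 = pri$p1, p2 = pri$p2,
                  p12 = pri$p12, priorSd1 = pri$priorSd,
                  priorSd2 = pri$priorSd, ppThreshold = cfg$ppThreshold,
                  clppThreshold = cfg$clppThreshold))
    }
    fm <- run("finemap", finemapPIPs(lp$gwas, lp$ld, L = 1,
                                     priorSd = pri$priorSd))
    highPip[[g]] <- highPipVariants(lp$gwas, fm,
                                    genes$tss[genes$symbol == g],
                                    pipThreshold = cfg$pipThreshold,
                                    window = cfg$pipWindow)
  }

  # chromatin features, ABD, annotation
  tracks <- study$tracks
  histF <- run("abd", buildHistoneFeatures(tracks$histone,
                                           tracks$blacklist, genes))
  dhsF <- run("abd", buildDhsFeatures(tracks$dhs, genes))
  annotations <- list(); topAbd <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$symbol[i]
    gene <- genes[i, ]
    annotations[[g]] <- annotateVariants(highPip[[g]], histF, dhsF,
                                         tracks$chromhmm)
    abd <- abdScores(histF, gene)
    topAbd[[g]] <- topAbdImplication(gene, abd, highPip[[g]])
  }

  verdicts <- run("verdicts",
    geneVerdicts(genes, near1, near0, eq$geneFlags, colocResults,
                 highPip, annotations, topAbd))
  summary <- summarizeVerdicts(verdicts)

  colocTab <- do.call(rbind, lapply(names(colocResults), function(g) {
    cr <- colocResults[[g]]
    data.frame(gene = g, t(colocPP(cr)), clpp_max = clppMax(cr),
               abf_hit = unname(colocHits(cr)["abf"]),
               clpp_hit = unname(colocHits(cr)["clpp"]),
               stringsAsFactors = FALSE)
  }))

  .writeTsv(verdicts, file.path(outDir, "verdicts.tsv"))
  .writeTsv(summary, file.path(outDir, "summary.tsv"))
  .writeTsv(eq$calls, file.path(outDir, "eqtl_calls.tsv"))
  .writeTsv(colocTab, file.path(outDir, "coloc.tsv"))
  if (nrow(loci)) .writeTsv(loci, file.path(outDir, "loci.tsv"))
  manifest <- list(seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "tissueMap")],
                   package_version =
                     as.character(utils::packageVersion("regaudit")))
  writeLines(.toJson(manifest), file.path(outDir, "manifest.json"))

  invisible(list(verdicts = verdicts, summary = summary,
                 eqtl = eq, coloc = colocResults, colocTable = colocTab,
                 loci = loci, study = study, outDir = outDir))
}

# minimal JSON serializer for the run manifest (scalars, lists, vectors)
.toJson <- function(x) {
  if (is.list(x)) {
    if (is.null(names(x)))
      paste0("[", paste(vapply(x, .toJson, ""), collapse = ","), "]")
    else
      paste0("{", paste(sprintf('"%s":%s', names(x),
                                vapply(x, .toJson, "")),
                        collapse = ","), "}")
  } else if (is.null(x)) "null"
  else if (length(x) != 1)
    paste0("[", paste(vapply(x, .toJson, ""), collapse = ","), "]")
  else if (is.character(x)) sprintf('"%s"', x)
  else if (is.logical(x)) tolower(as.character(x))
  else sprintf("%.17g", x)
}
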