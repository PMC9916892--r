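## End-to-end orchestration with a single config object and deterministic
## outputs. The exported functions/scripts are the interface; the thin
## command-line wrapper in inst/scripts/agv.R simply forwards to these.

#' Pipeline configuration with paper-default thresholds
#'
#' Returns the full tunable set with defaults equal to the published
#' values where stated: 21 bp hotspot windows at alpha 0.001, per-base
#' CNVR p < 0.05, Hi-C interaction p < 0.01 with >= 10 reads and a
#' strict 5 kb - 10 Mb distance band, 10% anchor-gene overlap, GWAS
#' genome-wide significance 5e-8, WGS QUAL > 30 / DP > 10, and an
#' enrichment report cutoff of 0.05.
#'
#' @param ... named overrides of any default.
#' @return named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(seed = 1L, windowSize = 21L, hotspotAlpha = 0.001,
                bonferroni = FALSE, minK = 1L, excludedChroms = "chrY",
                cnvrPThreshold = 0.05, dbscanEps = 0.5, dbscanMinPts = 1L,
                interactionPMax = 0.01, interactionMinReads = 10L,
                interactionMinDist = 5000L, interactionMaxDist = 1e7,
                anchorGeneMinFrac = 0.10, promoterUpstream = 2000L,
                promoterDownstream = 2000L, gwasPThreshold = 5e-8,
                vcfMinQual = 30, vcfMinDp = 10, enrichmentCutoff = 0.05)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
        stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    structure(cfg, class = "PipelineConfig")
}

#' Run the full pipeline on a synthetic scenario
#'
#' Generates the synthetic cohort for `config$seed`, then runs every
#' stage: hotspot detection, CNVR association (both directions), gene
#' annotation, EPI calling with condition-specific filtering, variant ->
#' enhancer -> target-gene integration with WGS replication, and
#' hypergeometric enrichment of the target genes. Stage outputs and a
#' manifest (config echo plus stage tallies) are written under `outDir`
#' as deterministic text tables; reruns with identical config are
#' byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param spec optional [fixtureSpec()]; defaults to the standard
#'   synthetic world at `config$seed`.
#' @return invisibly, a list with every stage result.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        spec = fixtureSpec(seed = config$seed)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outDir, f)
    mut <- simulateMutations(spec)
    cnv <- simulateCnvs(spec)
    reg <- simulateRegulatoryScenario(spec)

    scan <- detectHotspots(mut$mutations, spec$chromSizes,
                           w = config$windowSize,
                           alpha = config$hotspotAlpha,
                           minK = config$minK,
                           excludedChroms = config$excludedChroms,
                           bonferroni = config$bonferroni)
    hot <- hotspots(scan)
    cnvrSets <- lapply(c("duplication", "deletion"), function(d) {
        runPeakCnv(cnv$cnvs[mcols(cnv$cnvs)$cohort == "case"],
                   cnv$cnvs[mcols(cnv$cnvs)$cohort == "control"],
                   spec$chromSizes, d,
                   pThreshold = config$cnvrPThreshold,
                   eps = config$dbscanEps, minPts = config$dbscanMinPts,
                   nCase = spec$nCase, nControl = spec$nControl)
    })
    names(cnvrSets) <- c("duplication", "deletion")
    reps <- lapply(cnvrSets, representatives)

    genes <- buildReferenceGenes(reg$genes)
    varParts <- list(reg$variants)
    if (length(hot)) {
        g <- granges(hot)
        mcols(g) <- DataFrame(class = "hotspot",
                              id = sprintf("hot%03d", seq_along(hot)))
        varParts <- c(varParts, list(g))
    }
    for (d in names(reps)) {
        r <- reps[[d]]
        if (length(r) == 0L) next
        g <- granges(r)
        mcols(g) <- DataFrame(
            class = if (d == "duplication") "cnvr_dup" else "cnvr_del",
            id = sprintf("%s%03d", substr(d, 1L, 3L), seq_along(r)))
        varParts <- c(varParts, list(g))
    }
    variantList <- suppressWarnings(do.call(c, varParts))
    hits <- annotateVariants(variantList, genes)
    annotation <- summarizeAnnotation(hits, variantList)

    filt <- function(df) filterInteractions(
        df, pMax = config$interactionPMax,
        minReads = config$interactionMinReads,
        minDist = config$interactionMinDist,
        maxDist = config$interactionMaxDist)
    proms <- promoterRegions(genes, config$promoterUpstream,
                             config$promoterDownstream, spec$chromSizes)
    episCancer <- callEpis(filt(reg$interactionsCancer), reg$peaks, proms)
    episNormal <- callEpis(filt(reg$interactionsNormal), reg$peaks, proms)
    specific <- conditionSpecificEpis(episCancer, episNormal)

    candidates <- overlapVariantsWithEnhancers(variantList, specific)
    candidates <- replicateCandidates(candidates, reg$wgsSnvs,
                                      reg$wgsCnvSegments, "cellline1")
    report <- reportCandidates(candidates)

    targetGenes <- unique(unlist(strsplit(candidates$targetGenes, ";")))
    enrich <- if (length(targetGenes))
        hypergeometricOra(targetGenes, reg$geneSets, reg$universe)
    else data.frame()

    writeBed(hot, p("hotspots.bed"))
    write.table(as.data.frame(report$report), p("candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report$geneIndex, p("gene_index.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(enrich))
        write.table(enrich, p("enrichment.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    manifest <- list(
        config = unclass(config),
        stages = list(
            nHotspots = length(hot),
            nCnvrRepresentatives = vapply(reps, length, 0L),
            nEpisCancer = nrow(episCancer),
            nEpisNormal = nrow(episNormal),
            nEpisCancerSpecific = nrow(specific),
            nCandidates = nrow(candidates),
            nTargetGenes = length(targetGenes)))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(scan = scan, hotspots = hot, cnvrSets = cnvrSets,
                   annotation = annotation, episCancer = episCancer,
                   episNormal = episNormal, specificEpis = specific,
                   candidates = candidates, report = report,
                   enrichment = enrich, manifest = manifest))
}
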