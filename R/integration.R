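## Cross-referencing variants with cancer-specific EPIs (enhancer side
## only) and flagging WGS replication.

#' Link variants to target genes through enhancer anchors
#'
#' A variant becomes a regulatory candidate only when its span overlaps
#' the ENHANCER anchor of at least one (condition-specific) EPI by >= 1
#' bp; variants overlapping only promoter anchors are deliberately not
#' candidates. Target genes are the union over all supporting EPIs.
#'
#' @param variants `GRanges` with metadata columns `class` (one of
#'   `gwas_snp`, `hotspot`, `cnvr_dup`, `cnvr_del`) and optionally `id`.
#' @param epis EPI data.frame from [callEpis()] /
#'   [conditionSpecificEpis()].
#' @return data.frame with one row per candidate: `variantId`, `class`,
#'   `chrom`, `start`, `end` (1-based), `nEpis`, `targetGenes`
#'   (semicolon-joined, sorted), `replicatedIn` (empty until
#'   [replicateCandidates()]).
#' @export
overlapVariantsWithEnhancers <- function(variants, epis) {
    ids <- if ("id" %in% names(mcols(variants))) mcols(variants)$id
           else paste0("v", seq_along(variants))
    empty <- data.frame(variantId = character(), class = character(),
                        chrom = character(), start = integer(),
                        end = integer(), nEpis = integer(),
                        targetGenes = character(),
                        replicatedIn = character())
    if (length(variants) == 0L || nrow(epis) == 0L) return(empty)
    enh <- GRanges(
        ifelse(epis$enhancer_side == 1L, epis$chrom1, epis$chrom2),
        IRanges(ifelse(epis$enhancer_side == 1L, epis$start1, epis$start2),
                ifelse(epis$enhancer_side == 1L, epis$end1, epis$end2)))
    hits <- intersectIntervals(variants, enh)
    if (nrow(hits) == 0L) return(empty)
    byVar <- split(hits$bIndex, hits$aIndex)
    vi <- as.integer(names(byVar))
    data.frame(
        variantId = ids[vi],
        class = as.character(mcols(variants)$class)[vi],
        chrom = as.character(seqnames(variants))[vi],
        start = start(variants)[vi],
        end = end(variants)[vi],
        nEpis = lengths(byVar),
        targetGenes = vapply(byVar, function(e) {
            paste(sort(unique(unlist(
                strsplit(epis$target_genes[e], ";", fixed = TRUE)))),
                collapse = ";")
        }, ""),
        replicatedIn = "",
        row.names = NULL)
}

#' Quality-filter minimal VCF records
#'
#' Keeps records with `QUAL > minQual` and `DP > minDp` (both strict);
#' records with absent depth are dropped. This realizes the usual
#' "remove QUAL <= 30 && DP <= 10" call-set cleanup.
#'
#' @param records `GRanges` from [readVcfMinimal()].
#' @param minQual,minDp strict lower bounds (defaults 30 and 10).
#' @return filtered `GRanges`.
#' @export
vcfQualityFilter <- function(records, minQual = 30, minDp = 10) {
    qual <- mcols(records)$qual
    dp <- mcols(records)$dp
    keep <- !is.na(qual) & qual > minQual & !is.na(dp) & dp > minDp
    records[keep]
}

#' Flag candidate replication in cell-line WGS calls
#'
#' Class-specific rules: a GWAS SNP replicates when a WGS SNV exists at
#' the identical position (allele-agnostic); a hotspot replicates when at
#' least one WGS SNV falls inside its span; a CNVR replicates when a
#' same-direction WGS copy-number segment overlaps it by >= 1 bp
#' (or by `minRecip` reciprocal fraction when set).
#'
#' @param candidates data.frame from [overlapVariantsWithEnhancers()].
#' @param wgsSnvs `GRanges` of quality-filtered WGS SNVs/indels.
#' @param wgsCnvSegments `GRanges` of WGS copy-number segments with a
#'   `direction` metadata column.
#' @param cellLine name appended to `replicatedIn` for replicating
#'   candidates.
#' @param minRecip minimum reciprocal overlap fraction for CNV
#'   replication (default 0 = any overlap).
#' @return `candidates` with `replicatedIn` updated.
#' @export
replicateCandidates <- function(candidates, wgsSnvs = GRanges(),
                                wgsCnvSegments = GRanges(), cellLine,
                                minRecip = 0) {
    if (nrow(candidates) == 0L) return(candidates)
    spans <- GRanges(candidates$chrom,
                     IRanges(candidates$start, candidates$end))
    rep_ <- logical(nrow(candidates))
    isSnp <- candidates$class == "gwas_snp"
    isHot <- candidates$class == "hotspot"
    isCnv <- candidates$class %in% c("cnvr_dup", "cnvr_del")
    if (length(wgsSnvs)) {
        snvKey <- paste(as.character(seqnames(wgsSnvs)), start(wgsSnvs))
        rep_[isSnp] <- paste(candidates$chrom,
                             candidates$start)[isSnp] %in% snvKey
        rep_[isHot] <- rep_[isHot] |
            overlapsAny(spans[isHot], wgsSnvs, minoverlap = 1L)
    }
    if (length(wgsCnvSegments) && any(isCnv)) {
        dirOf <- c(cnvr_dup = "duplication", cnvr_del = "deletion")
        hits <- intersectIntervals(spans, wgsCnvSegments)
        if (nrow(hits)) {
            segDir <- mcols(wgsCnvSegments)$direction[hits$bIndex]
            okDir <- segDir == dirOf[candidates$class[hits$aIndex]]
            recip <- hits$overlapBp >= minRecip *
                pmax(width(spans)[hits$aIndex],
                     width(wgsCnvSegments)[hits$bIndex])
            good <- unique(hits$aIndex[okDir & recip &
                                       isCnv[hits$aIndex]])
            rep_[good] <- TRUE
        }
    }
    upd <- rep_ & !vapply(strsplit(candidates$replicatedIn, ";"),
                          function(x) cellLine %in% x, TRUE)
    candidates$replicatedIn[upd] <- ifelse(
        candidates$replicatedIn[upd] == "", cellLine,
        paste(candidates$replicatedIn[upd], cellLine, sep = ";"))
    candidates
}

#' Deterministic candidate report and per-gene index
#'
#' Orders candidates by variant class, chromosome and start so repeated
#' runs on identical inputs emit byte-identical tables, builds an index
#' of candidates per target gene, and tallies counts per class.
#'
#' @param candidates data.frame from [overlapVariantsWithEnhancers()].
#' @return list with `report` (ordered candidates), `geneIndex`
#'   (data.frame `gene`, `nCandidates`, `candidates` semicolon-joined)
#'   and `summary` (data.frame `class`, `n`, `nReplicated`).
#' @export
reportCandidates <- function(candidates) {
    ord <- order(candidates$class, candidates$chrom, candidates$start)
    report <- candidates[ord, , drop = FALSE]
    rownames(report) <- NULL
    genes <- strsplit(report$targetGenes, ";", fixed = TRUE)
    long <- data.frame(gene = unlist(genes),
                       variantId = rep(report$variantId, lengths(genes)))
    geneIndex <- if (nrow(long)) {
        byGene <- split(long$variantId, long$gene)
        data.frame(gene = names(byGene),
                   nCandidates = lengths(byGene),
                   candidates = vapply(byGene, function(v)
                       paste(sort(unique(v)), collapse = ";"), ""),
                   row.names = NULL)
    } else {
        data.frame(gene = character(), nCandidates = integer(),
                   candidates = character())
    }
    classes <- c("gwas_snp", "hotspot", "cnvr_dup", "cnvr_del")
    summary <- data.frame(
        class = classes,
        n = vapply(classes, function(cl) sum(report$class == cl), 0L),
        nReplicated = vapply(classes, function(cl)
            sum(report$class == cl & report$replicatedIn != ""), 0L),
        row.names = NULL)
    list(report = report, geneIndex = geneIndex, summary = summary)
}
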