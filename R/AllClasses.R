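## S4 containers for the two stage results that carry real state beyond a
## plain table: the genome-wide hotspot scan and the CNVR candidate set.

#' HotspotScan: result of a genome-wide somatic hotspot scan
#'
#' Holds every tiled window with at least `minK` mutated samples, its
#' distinct-sample count `k`, Poisson-binomial tail p-value, and filter
#' status, together with the null model used.
#'
#' @slot candidates `GRanges` of windows with metadata columns `k`,
#'   `p_value`, `filtered_reason` (`none`, `masked`, `repeat`,
#'   `excluded_chrom`) and `hotspot` (logical).
#' @slot windowSize tile width in bp.
#' @slot nSamples number of cohort samples.
#' @slot nTested number of windows with `k >= 1` on non-excluded
#'   chromosomes (the multiple-testing family size).
#' @slot alpha significance threshold on the tail p-value.
#' @slot bonferroni whether `alpha` was divided by `nTested`.
#' @slot genomeSize usable genome length G (bp, non-excluded chromosomes).
#' @slot nullProbs per-sample window-hit probabilities p_i.
#' @export
setClass("HotspotScan",
    representation(candidates = "GRanges", windowSize = "integer",
                   nSamples = "integer", nTested = "integer",
                   alpha = "numeric", bonferroni = "logical",
                   genomeSize = "numeric", nullProbs = "numeric"),
    validity = function(object) {
        msg <- character()
        mc <- mcols(object@candidates)
        if (!all(c("k", "p_value", "filtered_reason", "hotspot") %in%
                 names(mc)))
            msg <- c(msg, "candidates must carry k, p_value, filtered_reason, hotspot")
        else {
            if (any(mc$k < 0) || any(mc$k > object@nSamples))
                msg <- c(msg, "k must lie in [0, nSamples]")
            p <- mc$p_value[!is.na(mc$p_value)]
            if (any(p < 0 | p > 1)) msg <- c(msg, "p_value outside [0,1]")
        }
        if (object@windowSize < 1L) msg <- c(msg, "windowSize must be >= 1")
        if (any(object@nullProbs < 0 | object@nullProbs > 1))
            msg <- c(msg, "null probabilities outside [0,1]")
        if (length(msg)) msg else TRUE
    })

#' CnvrSet: candidate CNV regions from a case/control association scan
#'
#' @slot cnvrs `GRanges` with metadata columns `direction`,
#'   `case_samples` (`CharacterList`), `min_p`, `uniqueness`,
#'   `cluster_id`, `ir_score`, `is_representative`.
#' @slot nCase,nControl cohort sizes used in the per-base Fisher tests.
#' @slot pThreshold per-base significance threshold.
#' @export
setClass("CnvrSet",
    representation(cnvrs = "GRanges", nCase = "integer",
                   nControl = "integer", pThreshold = "numeric"),
    validity = function(object) {
        msg <- character()
        mc <- mcols(object@cnvrs)
        need <- c("direction", "case_samples", "min_p", "uniqueness",
                  "cluster_id", "ir_score", "is_representative")
        if (!all(need %in% names(mc)))
            msg <- c(msg, paste("cnvrs must carry:",
                                paste(need, collapse = ", ")))
        else if (length(object@cnvrs)) {
            if (any(lengths(mc$case_samples) == 0L))
                msg <- c(msg, "emitted CNVRs must have case support")
            if (any(mc$min_p >= object@pThreshold))
                msg <- c(msg, "emitted CNVRs must satisfy min_p < pThreshold")
        }
        if (length(msg)) msg else TRUE
    })

#' Hotspot windows passing the significance threshold
#'
#' @param x a [HotspotScan-class] object.
#' @param ... unused.
#' @return `GRanges` of unfiltered significant windows, sorted by p-value
#'   then genomic coordinate.
#' @export
setGeneric("hotspots", function(x, ...) standardGeneric("hotspots"))

#' All candidate windows of a scan
#'
#' @param x a [HotspotScan-class] object.
#' @param ... unused.
#' @export
setGeneric("windowCandidates",
           function(x, ...) standardGeneric("windowCandidates"))

#' Representative CNVRs (one per cluster)
#'
#' @param x a [CnvrSet-class] object.
#' @param ... unused.
#' @export
setGeneric("representatives",
           function(x, ...) standardGeneric("representatives"))

#' All candidate CNVRs of a scan (the audit table)
#'
#' @param x a [CnvrSet-class] object.
#' @param ... unused.
#' @export
setGeneric("cnvrCandidates",
           function(x, ...) standardGeneric("cnvrCandidates"))

#' @rdname hotspots
#' @export
setMethod("hotspots", "HotspotScan", function(x, ...) {
    gr <- x@candidates[mcols(x@candidates)$hotspot]
    ord <- order(mcols(gr)$p_value, as.character(seqnames(gr)), start(gr))
    gr[ord]
})

#' @rdname windowCandidates
#' @export
setMethod("windowCandidates", "HotspotScan", function(x, ...) x@candidates)

#' @rdname representatives
#' @export
setMethod("representatives", "CnvrSet", function(x, ...) {
    x@cnvrs[mcols(x@cnvrs)$is_representative]
})

#' @rdname cnvrCandidates
#' @export
setMethod("cnvrCandidates", "CnvrSet", function(x, ...) x@cnvrs)

setMethod("show", "HotspotScan", function(object) {
    nHot <- sum(mcols(object@candidates)$hotspot)
    cat("HotspotScan:", object@windowSize, "bp windows,",
        object@nSamples, "samples\n")
    cat("  windows with k >= 1 (tested):", object@nTested, "\n")
    cat("  alpha:", object@alpha,
        if (object@bonferroni) "(Bonferroni-corrected)" else "(raw)", "\n")
    cat("  hotspots passing filters:", nHot, "\n")
})

setMethod("show", "CnvrSet", function(object) {
    cat("CnvrSet:", length(object@cnvrs), "candidate CNVRs (",
        sum(mcols(object@cnvrs)$is_representative), "representatives )\n")
    cat("  cohorts: ", object@nCase, " cases vs ", object@nControl,
        " controls; per-base p < ", object@pThreshold, "\n", sep = "")
})
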